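test_that("associate_genes uses the oriented -1/+5 kb TSS window", {
  genes <- genes_at(c(10000, 10000), c("+", "-"), body_len = 2000)
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  # plus strand: window [9000, 15000)
  expect_equal(associate_genes(pk(11000, 11200), genes), c("g01"))
  expect_false("g01" %in% associate_genes(pk(8000, 8900), genes))
  # minus strand: window [5000, 11000)
  expect_true("g02" %in% associate_genes(pk(6000, 6100), genes))
  expect_false("g02" %in% associate_genes(pk(11500, 12000), genes))
})

test_that("TSS profile of a constant track is flat at the constant", {
  g <- tiny_genome(1e5)
  tr <- uniform_track(g, 2.5)
  genes <- genes_at(c(20000, 50000, 80000), c("+", "-", "+"))
  pr <- tss_profile(tr, genes)
  expect_equal(pr$signal, rep(2.5, nrow(pr)))
  expect_equal(range(pr$position), c(-1000, 4950))
})

test_that("a single peak at the TSS maximizes the profile at zero", {
  v <- rep(0, 2000); v[401] <- 10   # window covering [20000, 20050)
  tr <- track_from(v)
  genes <- genes_at(20000, "+")
  pr <- tss_profile(tr, genes)
  expect_equal(pr$position[which.max(pr$signal)], 0)
})

test_that("profiles are invariant under genome reflection with strand flip", {
  g <- tiny_genome(1e5)
  set.seed(42)
  v <- rpois(2000, 3)
  tr <- track_from(v, len = 1e5)
  genes <- genes_at(c(20000, 57000, 81000), c("+", "-", "-"),
                    body_len = 3000)
  L <- 1e5
  mirr_tr <- track_from(rev(v), len = L)
  mirr_genes <- gene_models(data.frame(
    gene_id = genes$gene_id, chrom = "chr1",
    start = L - genes$end, end = L - genes$start,
    strand = ifelse(genes$strand == "+", "-", "+"),
    stringsAsFactors = FALSE))
  expect_equal(tss_profile(tr, genes), tss_profile(mirr_tr, mirr_genes))
  expect_equal(metagene(tr, genes)$signal,
               metagene(mirr_tr, mirr_genes)$signal)
})

test_that("metagene body scaling is exact for aligned genes", {
  g <- tiny_genome(1e5)
  # constant track -> flat metagene regardless of gene length mix
  genes <- genes_at(c(20000, 50000, 80000), c("+", "-", "+"),
                    body_len = c(2000, 4500, 3000))
  mgc <- metagene(uniform_track(g, 1.7), genes)
  expect_equal(mgc$signal, rep(1.7, nrow(mgc)))
  # a gene of exactly 3 kb: scaled body equals the raw binned signal
  v <- rep(0, 2000)
  body_windows <- 401:460                      # [20000, 23000)
  v[body_windows] <- seq_along(body_windows)
  tr <- track_from(v, len = 1e5)
  g3 <- genes_at(20000, "+", body_len = 3000)
  mg <- metagene(tr, g3)
  body_part <- mg$signal[mg$position >= 0 & mg$position < 3000]
  expect_equal(body_part, as.numeric(seq_along(body_windows)))
  # 6-kb gene with a step: first half h, second half 0
  v2 <- rep(0, 2000)
  v2[401:460] <- 7                             # [20000, 23000) = first half
  tr2 <- track_from(v2, len = 1e5)
  g6 <- genes_at(20000, "+", body_len = 6000)
  mg6 <- metagene(tr2, g6)
  body6 <- mg6$signal[mg6$position >= 0 & mg6$position < 3000]
  expect_equal(body6, rep(c(7, 0), each = 30))
})

test_that("metagene skips and reports sub-bin genes", {
  g <- tiny_genome(1e5)
  genes <- gene_models(data.frame(
    gene_id = c("ok", "short"), chrom = "chr1",
    start = c(20000, 50000), end = c(23000, 50030),
    strand = c("+", "+"), stringsAsFactors = FALSE))
  expect_warning(mg <- metagene(uniform_track(g, 1), genes), "skipped")
  expect_equal(attr(mg, "n_genes_used"), 1L)
  expect_equal(attr(mg, "n_skipped"), 1L)
})

test_that("heat-map matrix is consistent with the average profile", {
  g <- tiny_genome(1e5)
  set.seed(7)
  tr <- track_from(rpois(2000, 2), len = 1e5)
  genes <- genes_at(c(15000, 40000, 62000, 88000),
                    c("+", "-", "+", "-"))
  m <- heatmap_matrix(tr, genes)
  pr <- tss_profile(tr, genes)
  expect_equal(unname(colMeans(m)), pr$signal)
  # descending row means; sorting is stable under reapplication
  expect_true(all(diff(rowMeans(m)) <= 1e-12))
  m2 <- heatmap_matrix(tr, genes, order_by = rownames(m))
  expect_identical(rownames(m2), rownames(m))
  expect_equal(m2, m)
})

test_that("differential tracks are RPM-normalized and antisymmetric", {
  a <- track_from(c(4, 0, 6, 2))
  b <- track_from(c(2, 2, 6, 2))
  z <- differential_track(a, a)
  expect_true(all(unlist(z$values) == 0))
  d_ab <- differential_track(a, b)
  d_ba <- differential_track(b, a)
  expect_equal(d_ab$values$chr1, -d_ba$values$chr1)
  # one extra count on equal-depth tracks: positive only at that window
  base <- c(5, 5, 5, 5)
  d1 <- differential_track(track_from(base + c(0, 1, 0, 0)),
                           track_from(base))
  expect_equal(which(d1$values$chr1 > 0), 2L)
  expect_true(all(d1$values$chr1[-2] < 0))
  big <- track_from(c(1, 1, 1, 1, 1))
  expect_error(differential_track(a, big), "grid")
})

test_that("polysome_ratio enforces its region contract", {
  tr <- simulate_polysome_trace(1, 2, seed = 3)
  expect_error(polysome_ratio(tr, mono_region = c(100, 900),
                              poly_region = c(800, 1500)), "disjoint")
  flat <- data.frame(position = seq(0, 1, length.out = 100),
                     absorbance = rep(0, 100))
  expect_error(polysome_ratio(flat, c(10, 30), c(50, 90)), "zero")
})
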