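test_that("make_genes handles the empty case and is seeded", {
  g <- tiny_genome(1e5)
  expect_equal(nrow(make_genes(g, 0)), 0L)
  a <- make_genes(g, 10, 1000, 4000, seed = 1)
  b <- make_genes(g, 10, 1000, 4000, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_genes(g, 10, 1000, 4000, seed = 2)))
  expect_setequal(unique(a$strand), c("+", "-"))
})

test_that("make_genes places non-overlapping bodies (interval sweep)", {
  g <- tiny_genome(1e5)
  genes <- make_genes(g, 10, 1000, 4000, seed = 3)
  for (ch in unique(genes$chrom)) {
    d <- genes[genes$chrom == ch, ]
    d <- d[order(d$start), ]
    # brute-force sweep: each start must be at or after the previous end
    expect_true(all(d$start[-1] >= head(d$end, -1)))
  }
  # and the exhaustive pairwise check
  n <- nrow(genes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (genes$chrom[i] != genes$chrom[j]) next
    ov <- min(genes$end[i], genes$end[j]) -
      max(genes$start[i], genes$start[j])
    expect_lte(ov, 0)
  }
})

test_that("make_genes errors when the genome cannot hold the genes", {
  expect_error(make_genes(tiny_genome(5000), 10, 2000, 3000, seed = 1),
               "could not place")
})

test_that("simulate_chip emits exactly n_reads, reproducibly", {
  g <- tiny_genome(1e5)
  genes <- make_genes(g, 5, 1000, 3000, seed = 1)
  p <- chip_sim_params(n_reads = 5000, seed = 7)
  rs <- simulate_chip(g, genes, p)
  expect_equal(nrow(rs), 5000L)
  expect_identical(as.data.frame(rs), as.data.frame(simulate_chip(g, genes, p)))
  expect_true(all(rs$start >= 0 & rs$end <= 1e5))
  expect_equal(nrow(simulate_chip(g, genes,
                                  chip_sim_params(n_reads = 0))), 0L)
})

test_that("background-only reads are uniform per window (chi-square GOF)", {
  g <- tiny_genome(1e5)
  genes <- make_genes(g, 5, 1000, 3000, seed = 1)
  rs <- simulate_chip(g, genes, chip_sim_params(n_reads = 2e5, seed = 11))
  counts <- tile_counts(rs, g, 50)$values$chr1
  # edge windows have reduced midpoint support; test the interior
  interior <- counts[2:(length(counts) - 1)]
  gof <- suppressWarnings(chisq.test(interior))
  expect_gt(gof$p.value, 0.01)
})

test_that("body enrichment raises in-gene window counts above background", {
  g <- tiny_genome(1e5)
  genes <- make_genes(g, 5, 2000, 4000, seed = 2)
  be <- c(8, rep(1, 4))
  rs <- simulate_chip(g, genes, chip_sim_params(
    body_enrichment = be, n_reads = 1e5, seed = 13))
  counts <- tile_counts(rs, g, 50)$values$chr1
  win_of <- function(pos) pos %/% 50 + 1
  in_g1 <- seq(win_of(genes$start[1]) + 1, win_of(genes$end[1]) - 1)
  in_any <- unlist(lapply(seq_len(5), function(i)
    seq(win_of(genes$start[i]), win_of(genes$end[i]))))
  bg <- setdiff(seq_along(counts), in_any)
  tt <- t.test(counts[in_g1], counts[bg], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("simulate_expression matches its Poisson ground truth", {
  # null case: no fold change, equal libraries
  p0 <- expr_sim_params(300, fold_changes = 1, base_mean = 100, seed = 5)
  t0 <- simulate_expression(p0)
  gg <- t0$type == "gene"
  expect_lt(abs(mean(t0$cond2[gg]) - mean(t0$cond1[gg])),
            3 * sqrt(2 * 100 / 300))
  # seeded determinism
  expect_identical(t0, simulate_expression(p0))
  # fold_change = 4 at base 100: condition-2 mean within 3 SD of 400
  p4 <- expr_sim_params(300, fold_changes = 4, base_mean = 100, seed = 6)
  t4 <- simulate_expression(p4)
  expect_lt(abs(mean(t4$cond2[t4$type == "gene"]) - 400),
            3 * sqrt(400 / 300))
  # spike-ins have identical expectations across conditions
  sp <- t0$type == "spikein"
  expect_lt(abs(mean(t0$cond1[sp]) - mean(t0$cond2[sp])),
            4 * sqrt(2 * 500 / sum(sp)))
})

test_that("polysome traces integrate to the requested areas", {
  # independent trapezoid oracle
  trapz0 <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  tr <- simulate_polysome_trace(1, 3, n_points = 2000, seed = 9)
  mr <- attr(tr, "mono_region"); pr <- attr(tr, "poly_region")
  a_mono <- trapz0(tr$position[mr[1]:mr[2]], tr$absorbance[mr[1]:mr[2]])
  a_poly <- trapz0(tr$position[pr[1]:pr[2]], tr$absorbance[pr[1]:pr[2]])
  expect_lt(abs(a_mono - 1), 0.01)
  expect_lt(abs(a_poly - 3), 0.03)
  expect_lt(abs(polysome_ratio(tr) - 3), 0.03)
  sym <- simulate_polysome_trace(1, 1, seed = 10)
  expect_lt(abs(polysome_ratio(sym) - 1), 0.01)
  expect_error(simulate_polysome_trace(1, 1, n_points = 0), "n_points")
})
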