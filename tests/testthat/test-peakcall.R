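test_that("deduplicate keeps one read per (chrom, start, strand)", {
  rs <- reads_from(c(10, 10, 10, 20), strand = c("+", "+", "-", "+"))
  dd <- deduplicate(rs)
  expect_equal(nrow(dd), 3L)           # strand-aware: 10+/10-/20+
  expect_identical(as.data.frame(deduplicate(dd)), as.data.frame(dd))
})

test_that("equalize_depth subsamples to the smaller set, seeded", {
  ip <- reads_from(seq(0, 990, by = 10))     # 100 reads
  input <- reads_from(seq(0, 790, by = 10))  # 80 reads
  eq <- equalize_depth(ip, input, seed = 1)
  expect_equal(nrow(eq$ip), 80L)
  expect_equal(nrow(eq$input), 80L)
  expect_identical(as.data.frame(eq$input), as.data.frame(input))
  eq2 <- equalize_depth(ip, input, seed = 1)
  expect_identical(as.data.frame(eq$ip), as.data.frame(eq2$ip))
  same <- equalize_depth(ip, ip, seed = 1)
  expect_identical(as.data.frame(same$ip), as.data.frame(ip))
  expect_error(equalize_depth(ip, input[0, ], seed = 1), "empty")
})

test_that("tile_counts assigns reads to windows by midpoint", {
  g <- genome_spec(c(chr1 = 500))
  # read [60,110): midpoint 85 -> second window
  tr <- tile_counts(reads_from(60, 110), g, 50)
  expect_equal(tr$values$chr1, c(0, 1, rep(0, 8)))
  rs <- reads_from(seq(0, 440, by = 7))
  expect_equal(sum(tile_counts(rs, g, 50)$values$chr1), nrow(rs))
  empty <- reads_from(numeric(0))
  expect_equal(sum(tile_counts(empty, g, 50)$values$chr1), 0)
  expect_error(tile_counts(reads_from(480, 530), g, 50), "beyond")
})

test_that("poisson_sf matches an explicit upper-tail summation", {
  # oracle: sum the Poisson pmf from k upward until terms vanish
  sf_oracle <- function(k, lam) {
    i <- k; acc <- 0
    repeat {
      term <- exp(i * log(lam) - lam - lgamma(i + 1))
      acc <- acc + term
      if (term < acc * 1e-17 && i > lam + k) break
      i <- i + 1
    }
    acc
  }
  for (lam in c(0.1, 0.5, 1, 2, 5, 10, 20)) {
    for (k in 0:50) {
      expect_equal(poisson_sf(k, lam), sf_oracle(k, lam),
                   tolerance = 1e-12)
    }
  }
  expect_equal(poisson_sf(0, 3.7), 1)
  expect_equal(poisson_sf(1, 2), 1 - exp(-2))
  expect_equal(poisson_sf(6, 1), 5.94e-4, tolerance = 1e-2)
  # monotone non-increasing in k, non-decreasing in lam
  expect_true(all(diff(poisson_sf(0:30, 5)) <= 0))
  expect_true(all(diff(poisson_sf(rep(5, 20), seq(0.5, 10, by = 0.5))) >= 0))
  expect_error(poisson_sf(3, 0), "lam")
})

test_that("the both-neighbor rule flags only interior runs", {
  g <- genome_spec(c(chr1 = 500))
  mk <- function(v) window_track(list(chr1 = v), 50, g)
  input <- mk(rep(1, 10))
  # candidates at windows 2..4 (p(30|1) << 1e-3), window 5 fails
  ip <- mk(c(0, 30, 30, 30, 0, 0, 0, 0, 0, 0))
  sig <- window_significance(ip, input, peak_call_params())
  expect_equal(which(sig$chroms$chr1$candidate), 2:4)
  expect_equal(which(sig$chroms$chr1$significant), 3L)
  peaks <- merge_peaks(sig)
  expect_equal(nrow(peaks), 1L)
  expect_equal(c(peaks$start, peaks$end, peaks$n_windows), c(50, 200, 3))
  expect_lt(peaks$min_p, 1e-3)
  # isolated candidates never become significant
  ip2 <- mk(c(30, 0, 30, 0, 0, 0, 0, 0, 0, 0))
  sig2 <- window_significance(ip2, input, peak_call_params())
  expect_equal(sum(sig2$chroms$chr1$significant), 0L)
  expect_equal(nrow(merge_peaks(sig2)), 0L)
  # identical IP and input: lambda >= observed everywhere, nothing called
  sig3 <- window_significance(input, input, peak_call_params())
  expect_equal(sum(sig3$chroms$chr1$candidate), 0L)
})

test_that("the one-sided neighbor rule accepts run edges", {
  g <- genome_spec(c(chr1 = 500))
  mk <- function(v) window_track(list(chr1 = v), 50, g)
  input <- mk(rep(1, 10))
  ip <- mk(c(30, 30, 30, 0, 0, 0, 0, 0, 0, 0))
  sig <- window_significance(ip, input,
                             peak_call_params(neighbor_rule = "one_sided"))
  expect_equal(which(sig$chroms$chr1$significant), c(1L, 3L))
})

test_that("merge_peaks separates runs and requires length >= 3", {
  g <- genome_spec(c(chr1 = 600))
  mk <- function(v) window_track(list(chr1 = v), 50, g)
  input <- mk(rep(1, 12))
  ip <- mk(c(30, 30, 30, 0, 30, 30, 30, 30, 0, 0, 0, 0))
  peaks <- merge_peaks(window_significance(ip, input, peak_call_params()))
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$start, c(0, 200))
  expect_equal(peaks$end, c(150, 400))
  expect_equal(peaks$n_windows, c(3L, 4L))
})

test_that("count conservation holds through dedup + tiling", {
  g <- tiny_genome(1e5)
  genes <- make_genes(g, 5, 1000, 3000, seed = 1)
  rs <- deduplicate(simulate_chip(g, genes,
    chip_sim_params(body_enrichment = 4, n_reads = 3e4, seed = 21)))
  expect_equal(track_total(tile_counts(rs, g, 50)), nrow(rs))
})

test_that("enriched gene bodies are recovered with high precision", {
  g <- genome_spec(c(chr1 = 1e6))
  genes <- make_genes(g, 60, 2000, 6000, seed = 31)
  ip <- simulate_chip(g, genes, chip_sim_params(
    body_enrichment = 8, n_reads = 1.5e5, seed = 32))
  input <- simulate_chip(g, genes, chip_sim_params(
    n_reads = 1.5e5, seed = 33))
  res <- call_peaks(ip, input, g, peak_call_params(seed = 34))
  overlaps_gene <- function(s, e) any(genes$start < e & genes$end > s)
  hit_gene <- vapply(seq_len(nrow(genes)), function(i)
    any(res$peaks$start < genes$end[i] & res$peaks$end > genes$start[i]),
    logical(1))
  peak_in_gene <- vapply(seq_len(nrow(res$peaks)), function(i)
    overlaps_gene(res$peaks$start[i], res$peaks$end[i]), logical(1))
  expect_gte(mean(hit_gene), 0.90)      # recall over enriched bodies
  expect_gte(mean(peak_in_gene), 0.95)  # precision of called peaks
})
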