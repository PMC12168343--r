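test_that("rpkm implements reads per kilobase per million", {
  expect_equal(rpkm(10, 2000, 1e6), 5)
  expect_equal(rpkm(0, 1500, 2e6), 0)
  expect_equal(rpkm(10, 2000, 2e6), rpkm(10, 2000, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "exon_length")
  expect_error(rpkm(1, 1000, 0), "total_mapped")
})

test_that("spike-in factors rescale sums to the cross-sample mean", {
  # spike RPKM sums engineered to 100 (s1) and 50 (s2)
  counts <- data.frame(
    id = c("gene_a", "spike_01"), exon_length = c(1000, 1000),
    s1 = c(999900, 100), s2 = c(999950, 50))
  et <- spikein_normalize(expression_table(counts,
                                           spikein_ids = "spike_01"))
  expect_equal(unname(et$scale_factors), c(0.75, 1.5))
  spike_sums <- colSums(et$adjusted[et$type == "spikein", , drop = FALSE])
  expect_equal(unname(spike_sums), c(75, 75), tolerance = 1e-9)
  # equal sums: identity
  counts2 <- data.frame(id = c("g", "spike_01"),
                        exon_length = c(1000, 2000),
                        s1 = c(500, 80), s2 = c(500, 80))
  et2 <- spikein_normalize(expression_table(counts2, "spike_01"))
  expect_equal(unname(et2$scale_factors), c(1, 1))
  expect_error(
    spikein_normalize(expression_table(
      data.frame(id = c("g", "spike_01"), exon_length = c(1000, 1000),
                 s1 = c(5, 0), s2 = c(5, 3)), "spike_01")),
    "zero spike-in")
})

test_that("spike-in sums equalize exactly on simulated data", {
  tab <- simulate_expression(expr_sim_params(
    100, n_spikeins = 12, library_scale = c(1, 2.7), seed = 3))
  et <- spikein_normalize(expression_table(tab))
  s <- colSums(et$adjusted[et$type == "spikein", ])
  expect_lt(abs(s[1] - s[2]) / s[1], 1e-9)
})

test_that("classify_de applies cutoff, floor, and detection filter", {
  counts <- data.frame(
    id = c("up_g", "flat_g", "lost_g", "pad", "spike_01"),
    exon_length = 1000,
    c1 = c(5, 5, 0, 999990 - 10, 10),
    c2 = c(20, 5, 0.01, 999990 - 25.01, 10))
  et <- spikein_normalize(expression_table(counts, "spike_01"))
  de <- classify_de(et, fold_cutoff = 2, min_expr = 0.1)
  lab <- setNames(de$label, de$id)
  expect_equal(unname(lab[c("up_g", "flat_g", "lost_g")]),
               c("up", "unchanged", "undetected"))
})

test_that("fold-change classification recovers simulated truth", {
  fc <- c(rep(4, 60), rep(0.25, 40), rep(1, 200))
  tab <- simulate_expression(expr_sim_params(
    300, base_mean = 150, fold_changes = fc, library_scale = c(1, 2),
    seed = 8))
  et <- spikein_normalize(expression_table(tab))
  de <- classify_de(et, fold_cutoff = 2, min_expr = 1)
  truth <- ifelse(fc >= 4, "up", ifelse(fc <= 0.25, "down", "other"))
  strong <- truth != "other"
  expect_gte(mean(de$label[strong] == truth[strong]), 0.95)
})

test_that("category p-values match a binomial-coefficient oracle", {
  universe <- sprintf("u%02d", 1:20)
  cat10 <- universe[1:10]
  sel <- universe[1:5]
  res <- category_enrichment(sel, list(inside = cat10), universe,
                             min_genes = 5)
  expect_equal(res$p_raw, choose(10, 5) / choose(20, 5),
               tolerance = 1e-12)
  # category == universe: p = 1
  res2 <- category_enrichment(sel, list(all = universe), universe,
                              min_genes = 5)
  expect_equal(res2$p_raw, 1)
  # full enumeration oracle on a 22-gene universe
  N <- 22; K <- 8; n <- 6
  uni <- sprintf("v%02d", 1:N)
  catK <- uni[1:K]
  sel2 <- c(uni[1:4], uni[15:16])                # overlap 4
  res3 <- category_enrichment(sel2, list(c = catK), uni, min_genes = 2)
  p_enum <- sum(vapply(4:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
  expect_equal(res3$p_raw, p_enum, tolerance = 1e-12)
})

test_that("the min-gene prefilter runs before Bonferroni", {
  universe <- sprintf("u%03d", 1:100)
  sel <- universe[1:20]
  cats <- list(big = universe[1:30],      # overlap 20
               small = universe[c(1:9, 95)],  # overlap 9 -> dropped
               other = universe[15:40])   # overlap 6 -> dropped
  res <- category_enrichment(sel, cats, universe, min_genes = 10,
                             alpha_corrected = 0.01)
  expect_equal(res$category, "big")
  # Bonferroni multiplier equals the number of *tested* categories (1)
  expect_equal(res$p_bonferroni, pmin(res$p_raw, 1))
})
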