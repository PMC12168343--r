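#' Reads per kilobase of exon per million mapped reads
#'
#' `count / (exon_length_bp / 1000) / (total_mapped / 1e6)`, vectorized.
#'
#' @param count Raw read count(s), `>= 0`.
#' @param exon_length_bp Exonic length(s) in bp, `> 0`.
#' @param total_mapped Total mapped reads in the sample, `> 0`.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 2000, 1e6)  # 5
#' @export
rpkm <- function(count, exon_length_bp, total_mapped) {
  .assert(all(count >= 0), "counts must be >= 0")
  .assert(all(exon_length_bp > 0), "exon_length_bp must be > 0")
  .assert(all(total_mapped > 0), "total_mapped must be > 0")
  count / (exon_length_bp / 1000) / (total_mapped / 1e6)
}

#' Assemble an expression table with per-sample RPKM
#'
#' @param counts data.frame with an `id` column, an `exon_length` column
#'   (bp), and one numeric raw-count column per sample. A `type` column
#'   (`"gene"`/`"spikein"`), as produced by [simulate_expression()], is
#'   honoured; otherwise rows named in `spikein_ids` are flagged.
#' @param spikein_ids Character vector of spike-in row ids (ignored when
#'   `counts` already has a `type` column).
#' @return An `expression_table`: list with `ids`, `type`, `exon_length`,
#'   `counts` (matrix), `totals` (per-sample mapped reads), `rpkm`
#'   (matrix), and `adjusted` (`NULL` until [spikein_normalize()]).
#' @export
expression_table <- function(counts, spikein_ids = character()) {
  .assert(all(c("id", "exon_length") %in% names(counts)),
          "counts needs 'id' and 'exon_length' columns")
  .assert(!anyDuplicated(counts$id), "row ids must be unique")
  samples <- setdiff(names(counts), c("id", "type", "exon_length"))
  .assert(length(samples) >= 1, "no sample columns found")
  cm <- as.matrix(counts[samples])
  .assert(is.numeric(cm) && all(cm >= 0), "counts must be numeric and >= 0")
  rownames(cm) <- counts$id
  type <- if ("type" %in% names(counts)) counts$type else
    ifelse(counts$id %in% spikein_ids, "spikein", "gene")
  .assert(any(type == "spikein") || length(spikein_ids) == 0,
          "spikein_ids do not match any row id")
  totals <- colSums(cm)
  .assert(all(totals > 0), "every sample needs at least one read")
  rk <- rpkm(cm, counts$exon_length, rep(totals, each = nrow(cm)))
  structure(list(ids = counts$id, type = type,
                 exon_length = counts$exon_length, counts = cm,
                 totals = totals, rpkm = rk, adjusted = NULL,
                 scale_factors = NULL),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table: ", sum(x$type == "gene"), " genes + ",
      sum(x$type == "spikein"), " spike-ins x ", ncol(x$counts),
      " samples", if (!is.null(x$adjusted)) " (spike-in normalized)",
      "\n", sep = "")
  invisible(x)
}

#' Normalize RPKM across samples using spike-in sums
#'
#' The per-sample scale factor is the mean across samples of the spike-in
#' RPKM sums divided by that sample's spike-in RPKM sum; adjusted RPKM is
#' raw RPKM times the factor. After adjustment the spike-in sums are equal
#' in every sample, so genes are expressed on a common absolute scale even
#' under global shifts in library composition.
#'
#' @param et An [expression_table()] with at least one spike-in row and a
#'   positive spike-in RPKM sum in every sample.
#' @return The table with `adjusted` and `scale_factors` filled in.
#' @export
spikein_normalize <- function(et) {
  .assert(inherits(et, "expression_table"), "not an expression_table")
  spike <- et$type == "spikein"
  .assert(any(spike), "table has no spike-in rows")
  sums <- colSums(et$rpkm[spike, , drop = FALSE])
  .assert(all(sums > 0), "zero spike-in RPKM sum in sample(s): ",
          paste(names(sums)[sums == 0], collapse = ", "))
  factors <- mean(sums) / sums
  et$adjusted <- sweep(et$rpkm, 2, factors, `*`)
  et$scale_factors <- factors
  et
}

#' Classify genes by spike-in-normalized fold change
#'
#' For a two-condition table: a gene is `undetected` when its adjusted
#' RPKM is below `min_expr` in both conditions; otherwise `up` when the
#' condition-2 / condition-1 ratio is `>= fold_cutoff`, `down` when it is
#' `<= 1 / fold_cutoff`, else `unchanged`. Ratios use a pseudo-RPKM floor
#' of 0.01 so zeros never divide; the floor only matters near the
#' detection limit. Spike-in rows are excluded.
#'
#' @param et A spike-in-normalized [expression_table()] with exactly two
#'   sample columns (condition 1, condition 2).
#' @param fold_cutoff Fold-change cutoff (> 1), default 2.
#' @param min_expr Detection threshold on adjusted RPKM, default 1.
#' @return data.frame with `id`, `rpkm_1`, `rpkm_2`, `log2_fc`, `label`.
#' @export
classify_de <- function(et, fold_cutoff = 2, min_expr = 1) {
  .assert(inherits(et, "expression_table"), "not an expression_table")
  .assert(!is.null(et$adjusted),
          "run spikein_normalize() before classify_de()")
  .assert(ncol(et$adjusted) == 2L,
          "classify_de needs exactly 2 conditions, got ",
          ncol(et$adjusted))
  .assert(fold_cutoff > 1, "fold_cutoff must be > 1")
  g <- et$type == "gene"
  a <- et$adjusted[g, 1]; b <- et$adjusted[g, 2]
  floor_ <- 0.01
  ratio <- pmax(b, floor_) / pmax(a, floor_)
  label <- ifelse(a < min_expr & b < min_expr, "undetected",
           ifelse(ratio >= fold_cutoff, "up",
           ifelse(ratio <= 1 / fold_cutoff, "down", "unchanged")))
  data.frame(id = et$ids[g], rpkm_1 = a, rpkm_2 = b,
             log2_fc = log2(ratio), label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric category over-representation test
#'
#' For each category, the raw p-value is the hypergeometric upper tail
#' `P(overlap >= observed)` given the universe size, category size within
#' the universe, and selection size. Categories overlapping the selection
#' in fewer than `min_genes` genes are excluded *before* multiple-testing
#' correction; Bonferroni then multiplies by the number of categories
#' actually tested. A category is significant when its corrected p-value
#' is below `alpha_corrected`.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param categories Named list of character vectors (category id ->
#'   member gene ids) or a 2-column data.frame `(category_id, gene_id)`.
#' @param universe Character vector of all gene ids under consideration.
#' @param min_genes Minimum selection overlap for a category to be tested
#'   (default 10).
#' @param alpha_corrected Cutoff on the Bonferroni-corrected p (default
#'   0.01).
#' @return data.frame with `category`, `n_category`, `overlap`, `p_raw`,
#'   `p_bonferroni`, `significant`, sorted by `p_raw`.
#' @export
category_enrichment <- function(selected, categories, universe,
                                min_genes = 10, alpha_corrected = 0.01) {
  .assert(.is_count(min_genes, min = 1), "min_genes must be >= 1")
  .assert(alpha_corrected > 0 && alpha_corrected < 1,
          "alpha_corrected must be in (0, 1)")
  .assert(!anyDuplicated(universe), "universe ids must be unique")
  selected <- unique(selected)
  .assert(all(selected %in% universe), "selected genes not all in universe")
  if (is.data.frame(categories)) {
    .assert(ncol(categories) >= 2, "category table needs 2 columns")
    categories <- split(as.character(categories[[2]]),
                        as.character(categories[[1]]))
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(unique(categories[[cat]]), universe)
    K <- length(members)
    ov <- length(intersect(members, selected))
    data.frame(category = cat, n_category = K, overlap = ov,
               p_raw = phyper(ov - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$overlap >= min_genes, , drop = FALSE]
  m <- nrow(out)
  out$p_bonferroni <- pmin(out$p_raw * m, 1)
  out$significant <- out$p_bonferroni < alpha_corrected
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}
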