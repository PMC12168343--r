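#' Describe a genome as named chromosome lengths
#'
#' A `genome_spec` is the minimal assembly description the pipeline needs:
#' chromosome names and their lengths in base pairs. All coordinates in the
#' package are 0-based half-open against this spec.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#'   Names must be unique, lengths strictly positive.
#' @return An object of class `genome_spec` (a named numeric vector).
#' @examples
#' genome_spec(c(chr1 = 5e6, chr2 = 2e6))
#' @export
genome_spec <- function(chrom_lengths) {
  .assert(is.numeric(chrom_lengths) && length(chrom_lengths) >= 1L,
          "chrom_lengths must be a non-empty numeric vector")
  nms <- names(chrom_lengths)
  .assert(!is.null(nms) && all(nzchar(nms)), "chromosomes must be named")
  .assert(!anyDuplicated(nms), "chromosome names must be unique")
  .assert(all(is.finite(chrom_lengths)) && all(chrom_lengths > 0) &&
            all(chrom_lengths == floor(chrom_lengths)),
          "chromosome lengths must be positive integers")
  structure(setNames(as.numeric(chrom_lengths), nms),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Construct a validated gene-model table
#'
#' Gene bodies are 0-based half-open `[start, end)` intervals. The
#' transcription start site (TSS) is `start` on the plus strand and `end` on
#' the minus strand; the termination site (TTS) is the opposite end. Exons
#' are stored as list-columns of interval starts/ends and must lie within
#' the body.
#'
#' @param df A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally list-columns `exon_starts`, `exon_ends`
#'   (default: one exon spanning the body).
#' @return A `gene_models` data.frame with derived `tss`/`tts` columns.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  .assert(all(need %in% names(df)),
          "gene table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .assert(!anyDuplicated(df$gene_id), "gene_id values must be unique")
  .assert(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(all(df$start >= 0) && all(df$end > df$start),
          "gene bodies must satisfy 0 <= start < end")
  if (is.null(df$exon_starts)) {
    df$exon_starts <- as.list(df$start)
    df$exon_ends <- as.list(df$end)
  }
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    .assert(length(es) == length(ee) && length(es) >= 1L,
            "gene ", df$gene_id[i], ": malformed exon list")
    .assert(all(es < ee) && all(es >= df$start[i]) && all(ee <= df$end[i]),
            "gene ", df$gene_id[i], ": exon outside gene body")
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tts <- ifelse(df$strand == "+", df$end, df$start)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Place non-overlapping toy genes on a genome
#'
#' Genes are placed by seeded rejection sampling: a chromosome is drawn with
#' probability proportional to its length, a body length uniformly between
#' `min_len` and `max_len`, and a start position uniformly along the
#' chromosome; placements closer than `min_gap` to an existing gene are
#' rejected. Each toy gene has a single exon spanning its body, so exon
#' length equals body length and RPKM ground truth stays analytic. Both
#' strands are always represented when two or more genes are placed.
#'
#' @param genome A [genome_spec()].
#' @param n_genes Number of genes to place (>= 0).
#' @param min_len,max_len Gene body length range (bp).
#' @param min_gap Minimum gap enforced between gene bodies (bp).
#' @param seed RNG seed.
#' @return A `gene_models` table sorted by chromosome and start.
#' @examples
#' g <- genome_spec(c(chr1 = 1e5))
#' make_genes(g, 10, min_len = 1000, max_len = 4000, seed = 1)
#' @export
make_genes <- function(genome, n_genes, min_len = 1000, max_len = 10000,
                       min_gap = 1000, seed = 1) {
  .assert(inherits(genome, "genome_spec"), "genome must be a genome_spec")
  .assert(.is_count(n_genes), "n_genes must be a non-negative integer")
  .assert(min_len >= 1 && max_len >= min_len, "need 1 <= min_len <= max_len")
  if (n_genes == 0L) {
    return(gene_models(data.frame(gene_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  strand = character())))
  }
  .assert(any(genome >= min_len), "genome too small for any gene")
  .with_seed(seed, {
    placed <- lapply(names(genome), function(x) cbind(start = numeric(),
                                                      end = numeric()))
    names(placed) <- names(genome)
    out <- vector("list", n_genes)
    tries <- 0L
    max_tries <- 1000L * n_genes
    i <- 1L
    while (i <= n_genes) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n_genes, " non-overlapping genes; ",
             "genome too small or too crowded", call. = FALSE)
      chrom <- sample(names(genome), 1L, prob = as.numeric(genome))
      len <- floor(runif(1L, min_len, max_len + 1))
      L <- genome[[chrom]]
      if (len > L) next
      start <- floor(runif(1L, 0, L - len + 1))
      end <- start + len
      prev <- placed[[chrom]]
      if (nrow(prev) && any(prev[, "start"] < end + min_gap &
                            prev[, "end"] + min_gap > start)) next
      placed[[chrom]] <- rbind(prev, c(start = start, end = end))
      out[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE)
      i <- i + 1L
    }
    df <- do.call(rbind, out)
    df$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (n_genes >= 2L && length(unique(df$strand)) == 1L)
      df$strand[n_genes] <- setdiff(c("+", "-"), df$strand[1L])
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    df$gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    rownames(df) <- NULL
    gene_models(df[, c("gene_id", "chrom", "start", "end", "strand")])
  })
}
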