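# shared builders for tests; everything generated in code, nothing on disk

tiny_genome <- function(len = 1e5) genome_spec(c(chr1 = len))

# window track on one chromosome straight from a numeric vector
track_from <- function(v, window_size = 50, len = length(v) * window_size,
                       kind = "count") {
  g <- genome_spec(c(chr1 = len))
  window_track(list(chr1 = v), window_size, g, value_kind = kind)
}

# constant-valued density track over a genome
uniform_track <- function(genome, value, window_size = 50) {
  vals <- lapply(names(genome), function(ch)
    rep(value, ceiling(genome[[ch]] / window_size)))
  names(vals) <- names(genome)
  window_track(vals, window_size, genome, value_kind = "density")
}

# gene table with hand-picked coordinates, grid-aligned by construction
genes_at <- function(tss, strand, body_len = 2000, chrom = "chr1") {
  start <- ifelse(strand == "+", tss, tss - body_len)
  gene_models(data.frame(
    gene_id = sprintf("g%02d", seq_along(tss)), chrom = chrom,
    start = start, end = start + body_len, strand = strand,
    stringsAsFactors = FALSE))
}

# read set from parallel vectors
reads_from <- function(start, end = start + 50, strand = "+",
                       chrom = "chr1") {
  n <- length(start)
  read_set(data.frame(chrom = rep_len(chrom, n), start = start, end = end,
                      strand = rep_len(strand, n),
                      stringsAsFactors = FALSE))
}
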