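#' Construct a validated set of aligned-read intervals
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open coordinates).
#' @param sample_id Identifier attached to the set.
#' @param genome Optional [genome_spec()]; if given, chromosome names and
#'   bounds are validated against it.
#' @return A `read_set` data.frame.
#' @export
read_set <- function(df, sample_id = "sample", genome = NULL) {
  need <- c("chrom", "start", "end", "strand")
  .assert(all(need %in% names(df)),
          "read table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  .assert(all(df$start >= 0), "negative read coordinates")
  .assert(all(df$end > df$start), "reads must satisfy end > start")
  .assert(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  if (!is.null(genome)) {
    .assert(all(df$chrom %in% names(genome)),
            "unknown chromosome(s): ",
            paste(unique(setdiff(df$chrom, names(genome))), collapse = ", "))
    .assert(all(df$end <= genome[df$chrom]), "read beyond chromosome end")
  }
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("read_set", "data.frame")
  df
}

.fail_lines <- function(bad, msg) {
  .assert(length(bad) == 0L, msg, " at line(s) ",
          paste(head(bad, 10L), collapse = ", "),
          if (length(bad) > 10L) " ..." else "")
}

#' Read aligned-read intervals from BED6 or tagAlign
#'
#' Both formats are six tab-separated columns (chrom, start, end,
#' name-or-sequence, score, strand) with 0-based half-open coordinates.
#' Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @param format `"bed6"` or `"tagalign"` (parsed identically; the fourth
#'   column is a read name in BED6 and the read sequence in tagAlign).
#' @param sample_id Identifier for the resulting set (default: file name).
#' @param genome Optional [genome_spec()] for chromosome validation.
#' @return A [read_set()].
#' @export
read_reads <- function(path, format = c("bed6", "tagalign"),
                       sample_id = NULL, genome = NULL) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  .assert(ncol(dt) >= 6L, "expected >= 6 tab-separated columns in ", path)
  dt <- dt[, 1:6]
  data.table::setnames(dt, c("chrom", "start", "end", "name", "score",
                             "strand"))
  .fail_lines(which(!is.finite(dt$start) | !is.finite(dt$end)),
              "non-numeric coordinates")
  .fail_lines(which(dt$start < 0), "negative coordinates")
  .fail_lines(which(dt$end <= dt$start), "end <= start")
  .fail_lines(which(!dt$strand %in% c("+", "-")), "bad strand")
  if (!is.null(genome))
    .fail_lines(which(!dt$chrom %in% names(genome)), "unknown chromosome")
  read_set(as.data.frame(dt[, c("chrom", "start", "end", "strand")]),
           sample_id = sample_id %||% basename(path), genome = genome)
}

#' Write a read set as BED6
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  .assert(inherits(reads, "read_set"), "not a read_set")
  dt <- data.table::data.table(
    chrom = reads$chrom, start = as.integer(reads$start),
    end = as.integer(reads$end),
    name = sprintf("read_%d", seq_len(nrow(reads))),
    score = 0L, strand = reads$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or GTF-lite
#'
#' BED12 is parsed natively (block fields become exons). GTF-lite is the
#' nine-column GTF dialect (seqname, source, feature, start, end, score,
#' strand, frame, attributes with a `gene_id` tag); `exon` rows are grouped
#' by gene_id, and 1-based closed coordinates are converted to the internal
#' 0-based half-open convention on read. Minus-strand genes get their TSS at
#' the body end coordinate.
#'
#' @param path File path.
#' @param format `"bed12"` or `"gtf"`.
#' @return A [gene_models()] table.
#' @export
read_genes <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: ", path)
  if (format == "bed12") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    .assert(ncol(dt) >= 12L, "expected 12 BED columns in ", path)
    dt <- dt[, 1:12]
    data.table::setnames(dt, c("chrom", "start", "end", "name", "score",
                               "strand", "thick_start", "thick_end",
                               "item_rgb", "block_count", "block_sizes",
                               "block_starts"))
    .fail_lines(which(dt$end <= dt$start), "end <= start")
    .fail_lines(which(!dt$strand %in% c("+", "-")), "bad strand")
    exon_starts <- vector("list", nrow(dt))
    exon_ends <- vector("list", nrow(dt))
    for (i in seq_len(nrow(dt))) {
      sizes <- as.numeric(strsplit(sub(",$", "", dt$block_sizes[i]),
                                   ",")[[1]])
      offs <- as.numeric(strsplit(sub(",$", "", dt$block_starts[i]),
                                  ",")[[1]])
      .assert(length(sizes) == dt$block_count[i] &&
                length(offs) == dt$block_count[i],
              "line ", i, ": block fields disagree with blockCount")
      exon_starts[[i]] <- dt$start[i] + offs
      exon_ends[[i]] <- dt$start[i] + offs + sizes
      .assert(all(exon_ends[[i]] <= dt$end[i]) &&
                all(exon_starts[[i]] >= dt$start[i]),
              "line ", i, ": exon outside gene body")
    }
    df <- data.frame(gene_id = dt$name, chrom = dt$chrom, start = dt$start,
                     end = dt$end, strand = dt$strand,
                     stringsAsFactors = FALSE)
    df$exon_starts <- exon_starts
    df$exon_ends <- exon_ends
    return(gene_models(df))
  }
  # GTF-lite
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 9)))
  .assert(ncol(dt) == 9L, "expected 9 GTF columns in ", path)
  data.table::setnames(dt, c("chrom", "source", "feature", "start", "end",
                             "score", "strand", "frame", "attributes"))
  dt <- dt[dt$feature == "exon", ]
  .assert(nrow(dt) > 0L, "no exon features in ", path)
  m <- regmatches(dt$attributes,
                  regexpr('gene_id "[^"]+"', dt$attributes))
  .fail_lines(which(lengths(regmatches(dt$attributes,
    gregexpr('gene_id "[^"]+"', dt$attributes))) == 0L),
    "missing gene_id attribute")
  gid <- sub('gene_id "([^"]+)"', "\\1", m)
  # 1-based closed -> 0-based half-open
  dt$start <- dt$start - 1
  .fail_lines(which(dt$end <= dt$start), "end <= start")
  rows <- split(seq_len(nrow(dt)), gid)
  df <- do.call(rbind, lapply(names(rows), function(g) {
    i <- rows[[g]]
    data.frame(gene_id = g, chrom = dt$chrom[i[1]],
               start = min(dt$start[i]), end = max(dt$end[i]),
               strand = dt$strand[i[1]], stringsAsFactors = FALSE)
  }))
  df$exon_starts <- lapply(names(rows), function(g)
    sort(dt$start[rows[[g]]]))
  df$exon_ends <- lapply(names(rows), function(g) sort(dt$end[rows[[g]]]))
  gene_models(df[order(df$chrom, df$start), , drop = FALSE])
}

#' Write gene models as BED12
#'
#' @param genes A [gene_models()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  .assert(inherits(genes, "gene_models"), "not a gene_models table")
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    paste(genes$chrom[i], format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), genes$gene_id[i], 0,
          genes$strand[i],
          format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), "0", length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a window track as bedGraph
#'
#' Consecutive equal-valued windows are collapsed into one bedGraph interval
#' (run-length encoding); zero runs are written too, so the file tiles each
#' chromosome completely. The final interval is clipped at the chromosome
#' end.
#'
#' @param track A [window_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  .assert(inherits(track, "window_track"), "not a window_track")
  ws <- track$window_size
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * ws
    starts <- c(0, head(ends, -1L))
    ends <- pmin(ends, track$chrom_lengths[[ch]])
    fmt <- function(x) format(x, scientific = FALSE, trim = TRUE,
                              digits = 12)
    writeLines(paste(ch, fmt(starts), fmt(ends), fmt(r$values),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a window track
#'
#' Inverse of [write_track()]: interval boundaries must align to the window
#' grid (the final interval of a chromosome may stop at the chromosome end).
#'
#' @param path bedGraph path.
#' @param genome A [genome_spec()].
#' @param window_size Window width the file was written at (bp).
#' @param value_kind Passed to [window_track()].
#' @return A [window_track()].
#' @export
read_track <- function(path, genome, window_size, value_kind = "count") {
  .assert(file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  .assert(ncol(dt) == 4L, "expected 4 bedGraph columns in ", path)
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  .fail_lines(which(!dt$chrom %in% names(genome)), "unknown chromosome")
  vals <- lapply(names(genome), function(ch) {
    nw <- ceiling(genome[[ch]] / window_size)
    v <- numeric(nw)
    d <- dt[dt$chrom == ch, ]
    if (nrow(d) == 0L) return(v)
    .assert(all(d$start %% window_size == 0),
            "bedGraph intervals not aligned to ", window_size,
            "-bp grid on ", ch)
    i0 <- d$start %/% window_size + 1L
    i1 <- pmin(ceiling(d$end / window_size), nw)
    for (j in seq_len(nrow(d))) v[i0[j]:i1[j]] <- d$value[j]
    v
  })
  names(vals) <- names(genome)
  window_track(vals, window_size, genome, value_kind = value_kind)
}
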