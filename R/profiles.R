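#' Parameters for gene-anchored signal summaries
#'
#' @param tss_upstream Bases upstream of the TSS covered by TSS-anchored
#'   profiles and by peak-to-gene association (default 1000).
#' @param tss_downstream Bases downstream of the TSS (default 5000).
#' @param body_scaled_length Common length (bp) every gene body is rescaled
#'   to in metagenes (default 3000); must be a multiple of `bin`.
#' @param flank Unscaled flank length (bp) either side of the metagene body.
#' @param bin Profile resolution in bp.
#' @return A `profile_params` list.
#' @export
profile_params <- function(tss_upstream = 1000, tss_downstream = 5000,
                           body_scaled_length = 3000, flank = 1000,
                           bin = 50) {
  .assert(bin >= 1, "bin must be >= 1")
  .assert(tss_upstream >= 0 && tss_downstream > 0,
          "tss window must be non-degenerate")
  .assert(body_scaled_length %% bin == 0,
          "body_scaled_length must be a multiple of bin")
  .assert(flank %% bin == 0, "flank must be a multiple of bin")
  .assert((tss_upstream + tss_downstream) %% bin == 0,
          "tss_upstream + tss_downstream must be a multiple of bin")
  structure(list(tss_upstream = tss_upstream,
                 tss_downstream = tss_downstream,
                 body_scaled_length = body_scaled_length,
                 flank = flank, bin = bin),
            class = "profile_params")
}

# per-gene TSS-anchored bin means, oriented 5'->3'; one row per gene.
# Column j covers offsets [off[j], off[j] + bin) relative to the TSS in
# transcription orientation.
.profile_matrix <- function(track, genes, upstream, downstream, bin) {
  .assert(nrow(genes) > 0, "empty gene list")
  off <- seq(-upstream, downstream - bin, by = bin)
  m <- matrix(0, nrow = nrow(genes), ncol = length(off),
              dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      s <- genes$tss[i] + off
      e <- s + bin
    } else {
      e <- genes$tss[i] - off
      s <- e - bin
    }
    m[i, ] <- interval_means(track, genes$chrom[i], s, e)
  }
  attr(m, "positions") <- off
  m
}

#' Genes with a peak near their TSS
#'
#' A gene is associated when at least one peak overlaps the interval from
#' `tss_upstream` bp upstream to `tss_downstream` bp downstream of its TSS,
#' measured in transcription orientation (the window is mirrored for
#' minus-strand genes). Overlap means non-empty intersection of the
#' half-open intervals.
#'
#' @param peaks Peak table from [merge_peaks()].
#' @param genes A [gene_models()] table.
#' @param params A [profile_params()].
#' @return Character vector of associated gene ids.
#' @export
associate_genes <- function(peaks, genes, params = profile_params()) {
  .assert(is.data.frame(peaks) &&
            all(c("chrom", "start", "end") %in% names(peaks)),
          "peaks must have chrom/start/end")
  plus <- genes$strand == "+"
  ws <- ifelse(plus, genes$tss - params$tss_upstream,
               genes$tss - params$tss_downstream)
  we <- ifelse(plus, genes$tss + params$tss_downstream,
               genes$tss + params$tss_upstream)
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(peaks$chrom == genes$chrom[i] & peaks$start < we[i] &
          peaks$end > ws[i])
  }, logical(1))
  genes$gene_id[hit]
}

#' Average signal profile around transcription start sites
#'
#' Per-gene signal vectors over `[-tss_upstream, +tss_downstream)` relative
#' to the TSS (minus-strand genes flipped so all run 5' to 3') are averaged
#' across genes. Bins falling off a chromosome contribute 0 signal but stay
#' in the denominator.
#'
#' @param track A [window_track()].
#' @param genes A non-empty [gene_models()] table.
#' @param params A [profile_params()].
#' @return data.frame with `position` (bin start offset from the TSS, bp)
#'   and `signal` columns.
#' @export
tss_profile <- function(track, genes, params = profile_params()) {
  m <- .profile_matrix(track, genes, params$tss_upstream,
                       params$tss_downstream, params$bin)
  data.frame(position = attr(m, "positions"), signal = colMeans(m))
}

#' Per-gene TSS-anchored signal matrix for heat maps
#'
#' One row per gene, columns as in [tss_profile()]. Rows are ordered by
#' descending mean row signal; passing the `gene_id` order of a reference
#' condition via `order_by` reuses that ordering so heat-map panels align
#' across conditions. Column means of the matrix equal the average
#' profile.
#'
#' @param track A [window_track()].
#' @param genes A non-empty [gene_models()] table.
#' @param params A [profile_params()].
#' @param order_by `NULL` (sort by this matrix's own row means, descending)
#'   or a character vector of gene ids giving the row order.
#' @return Numeric matrix with gene ids as rownames and a `positions`
#'   attribute (bin start offsets, bp).
#' @export
heatmap_matrix <- function(track, genes, params = profile_params(),
                           order_by = NULL) {
  m <- .profile_matrix(track, genes, params$tss_upstream,
                       params$tss_downstream, params$bin)
  ord <- if (is.null(order_by)) {
    order(rowMeans(m), decreasing = TRUE)
  } else {
    .assert(setequal(order_by, rownames(m)),
            "order_by must be a permutation of the gene ids")
    match(order_by, rownames(m))
  }
  pos <- attr(m, "positions")
  m <- m[ord, , drop = FALSE]
  attr(m, "positions") <- pos
  m
}

#' Body-scaled metagene profile
#'
#' Each gene body (TSS to TTS) is rescaled onto a common
#' `body_scaled_length` axis by area-preserving linear interpolation:
#' scaled bin `j` averages the track over the matching fractional slice of
#' the real body. Flanks of `flank` bp are copied unscaled. Minus-strand
#' genes are flipped. Genes whose body is shorter than one bin are skipped
#' with a warning and reported via the `n_skipped` attribute.
#'
#' @param track A [window_track()].
#' @param genes A non-empty [gene_models()] table.
#' @param params A [profile_params()].
#' @return data.frame with `position` (bp on the composite axis: flank
#'   `[-flank, 0)`, body `[0, body_scaled_length)`, flank beyond) and
#'   `signal`; attributes `n_genes_used`, `n_skipped`.
#' @export
metagene <- function(track, genes, params = profile_params()) {
  .assert(nrow(genes) > 0, "empty gene list")
  bin <- params$bin
  keep <- (genes$end - genes$start) >= bin
  if (any(!keep))
    warning(sum(!keep), " gene(s) shorter than one bin skipped")
  genes <- genes[keep, , drop = FALSE]
  .assert(nrow(genes) > 0, "no gene is at least one bin long")
  nb <- params$body_scaled_length %/% bin
  nf <- params$flank %/% bin
  prof <- matrix(0, nrow = nrow(genes), ncol = nf + nb + nf)
  for (i in seq_len(nrow(genes))) {
    L <- genes$end[i] - genes$start[i]
    frac <- seq(0, 1, length.out = nb + 1)
    if (genes$strand[i] == "+") {
      up_s <- genes$tss[i] - params$flank + (seq_len(nf) - 1) * bin
      up_e <- up_s + bin
      body_b <- genes$start[i] + frac * L
      body_s <- head(body_b, -1); body_e <- tail(body_b, -1)
      dn_s <- genes$tts[i] + (seq_len(nf) - 1) * bin
      dn_e <- dn_s + bin
    } else {
      up_e <- genes$tss[i] + params$flank - (seq_len(nf) - 1) * bin
      up_s <- up_e - bin
      body_b <- genes$end[i] - frac * L
      body_s <- tail(body_b, -1); body_e <- head(body_b, -1)
      dn_e <- genes$tts[i] - (seq_len(nf) - 1) * bin
      dn_s <- dn_e - bin
    }
    prof[i, ] <- c(
      interval_means(track, genes$chrom[i], up_s, up_e),
      interval_means(track, genes$chrom[i], body_s, body_e),
      interval_means(track, genes$chrom[i], dn_s, dn_e))
  }
  pos <- c(-params$flank + (seq_len(nf) - 1) * bin,
           (seq_len(nb) - 1) * bin,
           params$body_scaled_length + (seq_len(nf) - 1) * bin)
  out <- data.frame(position = pos, signal = colMeans(prof))
  attr(out, "n_genes_used") <- nrow(genes)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Difference track between two conditions
#'
#' Both tracks are depth-normalized to reads per million and subtracted
#' window by window (`a - b`). Explicit normalization makes the operation
#' safe even when the inputs were not depth-equalized.
#'
#' @param a,b Count [window_track()]s on the same grid.
#' @return A `difference` [window_track()].
#' @export
differential_track <- function(a, b) {
  .assert(inherits(a, "window_track") && inherits(b, "window_track"),
          "need window_tracks")
  .assert(.same_grid(a, b), "tracks are on different window grids")
  an <- rpm_track(a); bn <- rpm_track(b)
  g <- genome_spec(a$chrom_lengths)
  window_track(Map(`-`, an$values, bn$values), a$window_size, g,
               value_kind = "difference")
}

#' Polysome-to-monosome ratio from an absorbance trace
#'
#' Integrates the trace by the trapezoidal rule over the two designated
#' index regions and returns `AUC(polysome) / AUC(monosome)`. The regions
#' must be disjoint and lie within the trace; a zero monosome area is an
#' error. The trace is assumed baseline-subtracted.
#'
#' @param trace data.frame with `position` and `absorbance` columns (e.g.
#'   from [simulate_polysome_trace()]) or a numeric absorbance vector
#'   (positions taken as equally spaced).
#' @param mono_region,poly_region Length-2 integer index ranges; default to
#'   the `mono_region`/`poly_region` attributes of the trace when present.
#' @return The polysome/monosome area ratio (single number).
#' @export
polysome_ratio <- function(trace, mono_region = NULL, poly_region = NULL) {
  mono_region <- mono_region %||% attr(trace, "mono_region")
  poly_region <- poly_region %||% attr(trace, "poly_region")
  .assert(!is.null(mono_region) && !is.null(poly_region),
          "mono_region and poly_region are required")
  if (is.data.frame(trace)) {
    x <- trace$position; y <- trace$absorbance
  } else {
    y <- as.numeric(trace); x <- seq_along(y)
  }
  ok_region <- function(r) length(r) == 2L && r[1] >= 1 && r[2] <= length(y) &&
    r[1] < r[2]
  .assert(ok_region(mono_region) && ok_region(poly_region),
          "regions must be index pairs within the trace")
  .assert(mono_region[2] < poly_region[1] || poly_region[2] < mono_region[1],
          "mono and poly regions must be disjoint")
  auc <- function(r) pracma::trapz(x[r[1]:r[2]], y[r[1]:r[2]])
  mono <- auc(mono_region)
  .assert(mono > 0, "monosome area is zero")
  auc(poly_region) / mono
}
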