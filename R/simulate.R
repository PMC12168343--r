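#' Parameters for the two-condition ChIP read simulator
#'
#' The simulator draws read midpoints from a piecewise-constant rate:
#' `background_rate` everywhere, multiplied by `body_enrichment[g]` over the
#' body of gene `g` and by `promoter_enrichment[g]` over the
#' `2 * promoter_halfwidth`-bp window centred on its TSS (factors compose
#' multiplicatively where the promoter window overlaps the body head). An
#' input (whole-chromatin control) sample is simply a run with all factors
#' at 1.
#'
#' @param background_rate Expected relative read density per bp of
#'   unenriched genome (any positive scale; only ratios matter because the
#'   total read count is fixed).
#' @param body_enrichment Multiplicative enrichment over gene bodies;
#'   scalar or one value per gene, all `>= 0`.
#' @param promoter_enrichment Multiplicative enrichment over TSS-centred
#'   windows; scalar or per-gene, all `>= 0`.
#' @param promoter_halfwidth Half-width of the TSS window (bp).
#' @param n_reads Total reads to emit (exact).
#' @param read_length Read length in bp (>= 1).
#' @param seed RNG seed.
#' @return A `chip_sim_params` list.
#' @export
chip_sim_params <- function(background_rate = 0.02, body_enrichment = 1,
                            promoter_enrichment = 1,
                            promoter_halfwidth = 1000, n_reads = 1e5,
                            read_length = 50, seed = 1) {
  .assert(background_rate > 0, "background_rate must be > 0")
  .assert(all(body_enrichment >= 0) && all(promoter_enrichment >= 0),
          "enrichment factors must be >= 0")
  .assert(.is_count(n_reads), "n_reads must be a non-negative integer")
  .assert(.is_count(read_length, min = 1), "read_length must be >= 1")
  .assert(promoter_halfwidth >= 0, "promoter_halfwidth must be >= 0")
  structure(list(background_rate = background_rate,
                 body_enrichment = body_enrichment,
                 promoter_enrichment = promoter_enrichment,
                 promoter_halfwidth = promoter_halfwidth,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 seed = seed),
            class = "chip_sim_params")
}

# per-bp midpoint rate vector for one chromosome (1-based index = bp + 1)
.chip_rate <- function(L, genes_ch, params) {
  rate <- rep(params$background_rate, L)
  if (nrow(genes_ch)) {
    be <- rep_len(params$body_enrichment, attr(genes_ch, "n_total"))
    pe <- rep_len(params$promoter_enrichment, attr(genes_ch, "n_total"))
    for (k in seq_len(nrow(genes_ch))) {
      i <- genes_ch$.idx[k]
      b0 <- genes_ch$start[k] + 1L
      b1 <- genes_ch$end[k]
      rate[b0:b1] <- rate[b0:b1] * be[i]
      hw <- params$promoter_halfwidth
      if (hw > 0 && pe[i] != 1) {
        p0 <- max(genes_ch$tss[k] - hw, 0) + 1L
        p1 <- min(genes_ch$tss[k] + hw, L)
        if (p1 >= p0) rate[p0:p1] <- rate[p0:p1] * pe[i]
      }
    }
  }
  rate
}

#' Simulate a ChIP-seq read set over a toy genome
#'
#' Emits exactly `params$n_reads` fixed-length reads whose midpoints are
#' drawn from the enrichment rate described in [chip_sim_params()]; strands
#' are assigned uniformly. Fragment-size variation is not modelled.
#'
#' @param genome A [genome_spec()].
#' @param genes A [gene_models()] table (enrichment factors are recycled
#'   over its rows, in row order).
#' @param params A [chip_sim_params()].
#' @param sample_id Identifier for the returned set.
#' @return A [read_set()].
#' @export
simulate_chip <- function(genome, genes, params, sample_id = "chip") {
  .assert(inherits(genome, "genome_spec"), "genome must be a genome_spec")
  .assert(inherits(params, "chip_sim_params"), "params must be chip_sim_params")
  .assert(all(genes$chrom %in% names(genome)) &&
            all(genes$end <= genome[genes$chrom]),
          "genes must lie within the genome")
  rl <- params$read_length
  .assert(all(genome >= rl), "chromosome shorter than read_length")
  n <- params$n_reads
  if (n == 0L) {
    return(read_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), strand = character()),
                    sample_id = sample_id, genome = genome))
  }
  .with_seed(params$seed, {
    genes$.idx <- seq_len(nrow(genes))
    per_chrom <- lapply(names(genome), function(ch) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      attr(g, "n_total") <- nrow(genes)
      g
    })
    names(per_chrom) <- names(genome)
    rates <- lapply(names(genome), function(ch) {
      r <- .chip_rate(genome[[ch]], per_chrom[[ch]], params)
      # restrict midpoints so reads fit inside the chromosome
      lo <- floor(rl / 2)
      hi <- genome[[ch]] - (rl - floor(rl / 2))
      if (lo > 0) r[seq_len(lo)] <- 0
      if (hi + 1 < genome[[ch]]) r[(hi + 2):genome[[ch]]] <- 0
      r
    })
    names(rates) <- names(genome)
    w <- vapply(rates, sum, numeric(1))
    chrom_of <- if (length(genome) == 1L) rep(1L, n) else
      sample.int(length(genome), n, replace = TRUE, prob = w)
    nper <- tabulate(chrom_of, nbins = length(genome))
    parts <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      if (nper[ci] == 0L) next
      r <- rates[[ci]]
      mid <- if (max(r) == min(r[r > 0])) {
        pos <- which(r > 0)
        pos[sample.int(length(pos), nper[ci], replace = TRUE)] - 1L
      } else {
        sample.int(length(r), nper[ci], replace = TRUE, prob = r) - 1L
      }
      start <- mid - floor(rl / 2)
      parts[[ci]] <- data.frame(chrom = names(genome)[ci], start = start,
                                end = start + rl,
                                stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    read_set(df, sample_id = sample_id, genome = genome)
  })
}

#' Parameters for the spike-in expression simulator
#'
#' @param n_genes Number of gene rows.
#' @param n_spikeins Number of spike-in rows (constant true abundance
#'   across conditions).
#' @param base_mean Expected condition-1 count per gene (scalar or
#'   per-gene).
#' @param fold_changes Multiplicative change in condition 2 (scalar or
#'   per-gene, all > 0).
#' @param library_scale Length-2 vector of per-sample global scaling
#'   factors (sequencing-depth distortion).
#' @param spike_mean Expected count per spike-in before library scaling.
#' @param exon_length Exon length (bp) assigned to every row, used for
#'   RPKM ground truth (scalar or per-row for genes).
#' @param seed RNG seed.
#' @return An `expr_sim_params` list.
#' @export
expr_sim_params <- function(n_genes, n_spikeins = 10, base_mean = 100,
                            fold_changes = 1, library_scale = c(1, 1),
                            spike_mean = 500, exon_length = 1000, seed = 1) {
  .assert(.is_count(n_genes) && .is_count(n_spikeins),
          "n_genes and n_spikeins must be non-negative integers")
  .assert(all(base_mean >= 0) && all(spike_mean >= 0), "means must be >= 0")
  .assert(all(fold_changes > 0), "fold_changes must be > 0")
  .assert(length(library_scale) == 2L && all(library_scale > 0),
          "library_scale must be two positive factors")
  .assert(all(exon_length > 0), "exon_length must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_spikeins = as.integer(n_spikeins),
                 base_mean = base_mean, fold_changes = fold_changes,
                 library_scale = library_scale, spike_mean = spike_mean,
                 exon_length = exon_length, seed = seed),
            class = "expr_sim_params")
}

#' Simulate a two-condition counts table with spike-ins
#'
#' Gene counts are Poisson around `base_mean * library_scale[1]` in
#' condition 1 and `base_mean * fold_changes * library_scale[2]` in
#' condition 2. Spike-in rows have identical expected abundance in both
#' conditions before library scaling, which is what makes them usable as a
#' normalization anchor.
#'
#' @param params An [expr_sim_params()].
#' @return A data.frame with columns `id`, `type` (`"gene"`/`"spikein"`),
#'   `exon_length`, `cond1`, `cond2`; the true fold changes and library
#'   scales are attached as attributes `fold_changes` and `library_scale`.
#' @export
simulate_expression <- function(params) {
  .assert(inherits(params, "expr_sim_params"), "params must be expr_sim_params")
  ng <- params$n_genes; ns <- params$n_spikeins
  bm <- rep_len(params$base_mean, ng)
  fc <- rep_len(params$fold_changes, ng)
  el <- rep_len(params$exon_length, ng)
  sm <- rep_len(params$spike_mean, ns)
  ls <- params$library_scale
  .with_seed(params$seed, {
    df <- data.frame(
      id = c(sprintf("gene_%04d", seq_len(ng)),
             sprintf("spike_%02d", seq_len(ns))),
      type = rep(c("gene", "spikein"), c(ng, ns)),
      exon_length = c(el, rep_len(1000, ns)),
      cond1 = rpois(ng + ns, c(bm, sm) * ls[1]),
      cond2 = rpois(ng + ns, c(bm * fc, sm) * ls[2]),
      stringsAsFactors = FALSE)
    attr(df, "fold_changes") <- fc
    attr(df, "library_scale") <- ls
    df
  })
}

#' Simulate a polysome-profile absorbance trace
#'
#' Produces a smooth absorbance curve over a unit sedimentation axis with a
#' monosome (80S) peak and a decaying polysome peak train, scaled so the
#' trapezoidal area under each designated region matches the requested
#' areas to well under 1%; a small additive noise term is included. The
#' region index ranges are attached as attributes `mono_region` and
#' `poly_region` for [polysome_ratio()].
#'
#' @param mono_area Target area under the monosome region (arbitrary
#'   absorbance units).
#' @param poly_area Target area under the polysome region.
#' @param n_points Number of trace samples (>= 50).
#' @param seed RNG seed (noise).
#' @param noise_sd Standard deviation of the additive noise relative to the
#'   trace maximum.
#' @return data.frame with columns `position`, `absorbance`.
#' @export
simulate_polysome_trace <- function(mono_area, poly_area, n_points = 2000,
                                    seed = 1, noise_sd = 1e-4) {
  .assert(mono_area >= 0 && poly_area >= 0, "areas must be >= 0")
  .assert(.is_count(n_points, min = 1) && n_points >= 50,
          "n_points must be an integer >= 50")
  x <- seq(0, 1, length.out = n_points)
  mono_region <- range(which(x >= 0.15 & x <= 0.35))
  poly_region <- range(which(x >= 0.45 & x <= 0.95))
  mono <- dnorm(x, mean = 0.25, sd = 0.025)
  centers <- c(0.55, 0.64, 0.73, 0.82, 0.90)
  weights <- 0.75^(seq_along(centers) - 1)
  poly <- colSums(weights * t(vapply(centers, function(m)
    dnorm(x, mean = m, sd = 0.022), numeric(n_points))))
  scale_to <- function(shape, region, area) {
    i <- region[1]:region[2]
    a <- pracma::trapz(x[i], shape[i])
    if (a == 0) shape * 0 else shape * (area / a)
  }
  y <- scale_to(mono, mono_region, mono_area) +
    scale_to(poly, poly_region, poly_area)
  y <- .with_seed(seed, y + rnorm(n_points, sd = noise_sd * max(y, 1e-12)))
  out <- data.frame(position = x, absorbance = y)
  attr(out, "mono_region") <- mono_region
  attr(out, "poly_region") <- poly_region
  out
}
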