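#' Parameters for the random-gene-set resampling null
#'
#' @param n_trials Number of random gene sets drawn (default 100).
#' @param tss_halfwidth Half-width of the TSS window the profile and its
#'   scalar summary cover, in bp (default 1000).
#' @param bin Profile resolution in bp.
#' @param seed RNG seed.
#' @return A `resampling_params` list.
#' @export
resampling_params <- function(n_trials = 100, tss_halfwidth = 1000,
                              bin = 50, seed = 1) {
  .assert(.is_count(n_trials, min = 1), "n_trials must be >= 1")
  .assert(tss_halfwidth >= bin, "tss_halfwidth must be >= bin")
  .assert((2 * tss_halfwidth) %% bin == 0,
          "2 * tss_halfwidth must be a multiple of bin")
  structure(list(n_trials = as.integer(n_trials),
                 tss_halfwidth = tss_halfwidth, bin = bin, seed = seed),
            class = "resampling_params")
}

#' TSS-window profile and scalar summary for one gene set
#'
#' The profile is the [tss_profile()] of the track over
#' `[-tss_halfwidth, +tss_halfwidth)` restricted to the given genes; the
#' summary is the mean over the profile bins, i.e. the average signal in
#' the TSS window across the set.
#'
#' @param track A [window_track()] (typically a [differential_track()]).
#' @param genes A [gene_models()] table.
#' @param gene_set Non-empty character vector of gene ids from `genes`.
#' @param params A [resampling_params()].
#' @return List with `profile` (data.frame `position`, `signal`) and
#'   `summary` (single number).
#' @export
gene_set_summary <- function(track, genes, gene_set,
                             params = resampling_params()) {
  .assert(length(gene_set) > 0, "gene_set is empty")
  .assert(all(gene_set %in% genes$gene_id),
          "gene_set contains ids absent from genes")
  sub <- genes[match(gene_set, genes$gene_id), , drop = FALSE]
  m <- .profile_matrix(track, sub, params$tss_halfwidth,
                       params$tss_halfwidth, params$bin)
  profile <- data.frame(position = attr(m, "positions"),
                        signal = colMeans(m))
  list(profile = profile, summary = mean(profile$signal))
}

#' Resampling null for a target gene set's TSS signal
#'
#' Compares the average TSS-window signal of a target gene set against
#' equally sized sets drawn at random (without replacement within a trial)
#' from a universe that excludes the target genes. Returns the observed
#' profile, the pointwise null mean and min–max envelope, the per-trial
#' scalar summaries, and an empirical p-value for the one-sided question
#' "is the target's summary unusually high?".
#'
#' Monte-Carlo mode uses the add-one correction
#' `p = (1 + #\{trials >= observed\}) / (n_trials + 1)` so p is never zero;
#' with `exhaustive = TRUE` every subset of the universe of the target's
#' size is enumerated instead and the exact fraction
#' `#\{subsets >= observed\} / #\{subsets\}` is returned.
#'
#' @param track A [window_track()], typically a [differential_track()].
#' @param genes A [gene_models()] table.
#' @param target_set Character vector of target gene ids.
#' @param universe Gene ids to draw null sets from; defaults to all genes
#'   except the target set. Must not intersect the target and must be at
#'   least as large as it.
#' @param params A [resampling_params()].
#' @param exhaustive Enumerate all subsets instead of sampling (only
#'   sensible for small universes).
#' @return A `resampling_result` list: `observed_profile`,
#'   `null_mean_profile`, `null_min_profile`, `null_max_profile`,
#'   `observed_summary`, `null_summaries`, `empirical_p`, `n_trials`.
#' @export
resample_null <- function(track, genes, target_set, universe = NULL,
                          params = resampling_params(),
                          exhaustive = FALSE) {
  .assert(length(target_set) > 0, "target_set is empty")
  universe <- universe %||% setdiff(genes$gene_id, target_set)
  .assert(length(intersect(universe, target_set)) == 0,
          "universe must exclude the target set")
  .assert(length(universe) >= length(target_set),
          "universe smaller than the target set")
  .assert(all(c(universe, target_set) %in% genes$gene_id),
          "unknown gene ids")
  k <- length(target_set)
  # per-gene profiles computed once; trials are then just row averages
  all_ids <- c(target_set, universe)
  sub <- genes[match(all_ids, genes$gene_id), , drop = FALSE]
  m <- .profile_matrix(track, sub, params$tss_halfwidth,
                       params$tss_halfwidth, params$bin)
  pos <- attr(m, "positions")
  obs_prof <- colMeans(m[seq_len(k), , drop = FALSE])
  observed <- mean(obs_prof)
  uni_m <- m[k + seq_along(universe), , drop = FALSE]
  trial_rows <- if (exhaustive) {
    combn(length(universe), k, simplify = FALSE)
  } else {
    .with_seed(params$seed, lapply(seq_len(params$n_trials), function(i)
      sample.int(length(universe), k)))
  }
  trial_profs <- t(vapply(trial_rows, function(rows)
    colMeans(uni_m[rows, , drop = FALSE]), numeric(ncol(m))))
  null_summaries <- rowMeans(trial_profs)
  b <- sum(null_summaries >= observed)
  empirical_p <- if (exhaustive) b / length(trial_rows) else
    (1 + b) / (length(trial_rows) + 1)
  structure(list(
    observed_profile = data.frame(position = pos, signal = obs_prof),
    null_mean_profile = colMeans(trial_profs),
    null_min_profile = apply(trial_profs, 2, min),
    null_max_profile = apply(trial_profs, 2, max),
    observed_summary = observed,
    null_summaries = null_summaries,
    empirical_p = empirical_p,
    n_trials = length(trial_rows)),
    class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("resampling_result: observed summary ",
      format(x$observed_summary, digits = 4), ", null range [",
      format(min(x$null_summaries), digits = 4), ", ",
      format(max(x$null_summaries), digits = 4), "] over ", x$n_trials,
      " trials, empirical p = ", format(x$empirical_p, digits = 4), "\n",
      sep = "")
  invisible(x)
}
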