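#' Parameters for window-based Poisson peak calling
#'
#' The caller tiles the genome into `window_size`-bp windows, tests each
#' IP window count against a Poisson expectation derived from the matched
#' input, and requires the p-value cutoff to be met in neighboring windows
#' before a window counts as significant.
#'
#' @param window_size Window width in bp (default 50).
#' @param alpha Poisson p-value cutoff (default 1e-3).
#' @param neighbor_rule `"both"` (default): both immediate flanking windows
#'   must also pass the cutoff; `"one_sided"`: the two consecutive windows
#'   on at least one side must pass.
#' @param seed RNG seed used for depth equalization.
#' @return A `peak_call_params` list.
#' @export
peak_call_params <- function(window_size = 50, alpha = 1e-3,
                             neighbor_rule = c("both", "one_sided"),
                             seed = 1) {
  neighbor_rule <- match.arg(neighbor_rule)
  .assert(.is_count(window_size, min = 1), "window_size must be >= 1")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(window_size = as.integer(window_size), alpha = alpha,
                 neighbor_rule = neighbor_rule, seed = seed),
            class = "peak_call_params")
}

#' Remove duplicate reads
#'
#' A duplicate is a read with the same (chrom, start, strand) as one
#' already seen; for single-end fixed-length reads the end coordinate is
#' redundant. Idempotent.
#'
#' @param reads A [read_set()].
#' @return A [read_set()] with at most one read per (chrom, start, strand).
#' @export
deduplicate <- function(reads) {
  .assert(inherits(reads, "read_set"), "not a read_set")
  keep <- !duplicated(data.frame(reads$chrom, reads$start, reads$strand))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(reads, "sample_id")
  class(out) <- c("read_set", "data.frame")
  out
}

#' Randomly subsample IP and input to the same depth
#'
#' Both sets are reduced (without replacement) to the size of the smaller
#' one; the smaller set is returned unchanged. Seeded for reproducibility.
#'
#' @param ip,input Non-empty [read_set()]s.
#' @param seed RNG seed.
#' @return List with elements `ip` and `input`, both of equal size.
#' @export
equalize_depth <- function(ip, input, seed = 1) {
  .assert(inherits(ip, "read_set") && inherits(input, "read_set"),
          "ip and input must be read_sets")
  .assert(nrow(ip) > 0 && nrow(input) > 0,
          "cannot equalize depth with an empty read set")
  n <- min(nrow(ip), nrow(input))
  take <- function(rs, which_seed) {
    if (nrow(rs) == n) return(rs)
    idx <- .with_seed(which_seed, sort(sample.int(nrow(rs), n)))
    out <- rs[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sample_id") <- attr(rs, "sample_id")
    class(out) <- c("read_set", "data.frame")
    out
  }
  list(ip = take(ip, .sub_seed(seed, 1L)),
       input = take(input, .sub_seed(seed, 2L)))
}

#' Count reads in fixed-width genome windows
#'
#' Each read is assigned to exactly one window by its midpoint
#' `floor((start + end) / 2)`; the sum of window counts therefore equals
#' the number of reads.
#'
#' @param reads A [read_set()].
#' @param genome A [genome_spec()].
#' @param window_size Window width in bp.
#' @return A count [window_track()].
#' @export
tile_counts <- function(reads, genome, window_size = 50) {
  .assert(inherits(reads, "read_set"), "not a read_set")
  .assert(inherits(genome, "genome_spec"), "genome must be a genome_spec")
  .assert(all(reads$chrom %in% names(genome)),
          "reads on chromosomes absent from the genome")
  .assert(all(reads$start >= 0) && all(reads$end <= genome[reads$chrom]),
          "read beyond chromosome end")
  mid <- (reads$start + reads$end) %/% 2
  idx <- mid %/% window_size + 1L
  vals <- lapply(names(genome), function(ch) {
    nw <- ceiling(genome[[ch]] / window_size)
    tabulate(idx[reads$chrom == ch], nbins = nw)
  })
  names(vals) <- names(genome)
  window_track(vals, window_size, genome, value_kind = "count")
}

#' Poisson upper-tail probability P(X >= k)
#'
#' Survival-function form of the Poisson test used per window: the
#' probability of observing `k` or more reads under expectation `lam`.
#' Monotone non-increasing in `k` and non-decreasing in `lam`.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lam Expected count(s), strictly positive.
#' @return P(X >= k) for X ~ Poisson(lam), vectorized.
#' @examples
#' poisson_sf(6, 1)       # ~5.9e-4
#' poisson_sf(1, 2)       # 1 - exp(-2)
#' @export
poisson_sf <- function(k, lam) {
  .assert(all(k >= 0) && all(k == floor(k)),
          "k must be non-negative integer(s)")
  .assert(all(lam > 0), "lam must be > 0")
  ppois(k - 1, lambda = lam, lower.tail = FALSE)
}

#' Per-window Poisson significance against matched input
#'
#' For every window, the expectation is
#' `lam = max(input count in that window, genome-wide mean input per
#' window)`; the floor prevents zero-lambda artifacts where the input is
#' sparse. A window is a *candidate* if `P(X >= ip count) < alpha`, and
#' *significant* if it is a candidate and its neighbors also are, per
#' `neighbor_rule`. Chromosome-edge windows can never be significant (a
#' missing neighbor counts as failing).
#'
#' @param ip_track,input_track Count [window_track()]s on the same grid,
#'   depth-equalized upstream.
#' @param params A [peak_call_params()].
#' @return A `window_significance` object: per-chromosome `p`, `candidate`,
#'   `significant` vectors plus the two count tracks.
#' @export
window_significance <- function(ip_track, input_track,
                                params = peak_call_params()) {
  .assert(inherits(ip_track, "window_track") &&
            inherits(input_track, "window_track"), "need window_tracks")
  .assert(.same_grid(ip_track, input_track),
          "IP and input tracks are on different window grids")
  n_windows <- sum(vapply(ip_track$values, length, numeric(1)))
  mean_input <- track_total(input_track) / n_windows
  .assert(mean_input > 0, "input track is empty")
  chroms <- lapply(names(ip_track$values), function(ch) {
    ip <- ip_track$values[[ch]]
    lam <- pmax(input_track$values[[ch]], mean_input)
    p <- poisson_sf(ip, lam)
    cand <- p < params$alpha
    nw <- length(cand)
    sig <- rep(FALSE, nw)
    if (nw >= 3L) {
      left <- c(FALSE, cand[-nw])
      right <- c(cand[-1L], FALSE)
      if (params$neighbor_rule == "both") {
        sig <- cand & left & right
      } else {
        left2 <- c(FALSE, FALSE, cand[seq_len(nw - 2L)])
        right2 <- c(cand[-(1:2)], FALSE, FALSE)
        sig <- cand & ((left & left2) | (right & right2))
      }
    }
    list(p = p, candidate = cand, significant = sig)
  })
  names(chroms) <- names(ip_track$values)
  structure(list(chroms = chroms, params = params,
                 ip_track = ip_track, input_track = input_track,
                 mean_input = mean_input),
            class = "window_significance")
}

#' Merge significant windows into peaks
#'
#' Every maximal run of three or more consecutive candidate windows that
#' contains at least one significant window becomes one peak spanning the
#' run. Peaks are sorted by coordinate and carry the smallest window
#' p-value and the mean IP/input window counts over the run.
#'
#' @param sig A `window_significance` object from [window_significance()].
#' @return data.frame with columns `chrom`, `start`, `end`, `n_windows`,
#'   `min_p`, `mean_ip`, `mean_input`, `score` (`-log10(min_p)`).
#' @export
merge_peaks <- function(sig) {
  .assert(inherits(sig, "window_significance"), "not a window_significance")
  ws <- sig$ip_track$window_size
  out <- lapply(names(sig$chroms), function(ch) {
    s <- sig$chroms[[ch]]
    r <- rle(s$candidate)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= 3L)
    keep <- keep[vapply(keep, function(k)
      any(s$significant[starts[k]:ends[k]]), logical(1))]
    if (!length(keep)) return(NULL)
    data.frame(
      chrom = ch,
      start = (starts[keep] - 1L) * ws,
      end = ends[keep] * ws,
      n_windows = r$lengths[keep],
      min_p = vapply(keep, function(k) min(s$p[starts[k]:ends[k]]),
                     numeric(1)),
      mean_ip = vapply(keep, function(k)
        mean(sig$ip_track$values[[ch]][starts[k]:ends[k]]), numeric(1)),
      mean_input = vapply(keep, function(k)
        mean(sig$input_track$values[[ch]][starts[k]:ends[k]]), numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      min_p = numeric(), mean_ip = numeric(),
                      mean_input = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$score <- -log10(pmax(out$min_p, .Machine$double.xmin))
  rownames(out) <- NULL
  out
}

#' Full enrichment-calling pipeline for one IP/input pair
#'
#' Convenience composition of the calling stages in order: duplicate
#' removal, random subsampling to equal depth, midpoint tiling into
#' windows, per-window Poisson significance, and peak merging.
#'
#' @param ip,input [read_set()]s for the IP and matched control.
#' @param genome A [genome_spec()].
#' @param params A [peak_call_params()].
#' @return List with `peaks`, `significance`, `ip_track`, `input_track`,
#'   and `depth` (reads per sample after dedup + equalization).
#' @export
call_peaks <- function(ip, input, genome, params = peak_call_params()) {
  ip <- deduplicate(ip)
  input <- deduplicate(input)
  eq <- equalize_depth(ip, input, seed = params$seed)
  ip_track <- tile_counts(eq$ip, genome, params$window_size)
  input_track <- tile_counts(eq$input, genome, params$window_size)
  sig <- window_significance(ip_track, input_track, params)
  list(peaks = merge_peaks(sig), significance = sig,
       ip_track = ip_track, input_track = input_track,
       depth = nrow(eq$ip))
}
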