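#' Fixed-width window track over a genome
#'
#' A `window_track` holds one numeric vector per chromosome, one value per
#' `window_size`-bp window tiling the chromosome from position 0. The last
#' window of each chromosome may extend past the chromosome end; the vector
#' length is always `ceiling(chrom_length / window_size)`.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param window_size Window width in bp (>= 1).
#' @param genome A [genome_spec()] giving chromosome lengths.
#' @param value_kind One of `"count"`, `"density"`, `"difference"`.
#' @return An object of class `window_track`.
#' @export
window_track <- function(values, window_size, genome,
                         value_kind = c("count", "density", "difference")) {
  value_kind <- match.arg(value_kind)
  .assert(inherits(genome, "genome_spec"), "genome must be a genome_spec")
  .assert(.is_count(window_size, min = 1), "window_size must be >= 1")
  .assert(is.list(values) && setequal(names(values), names(genome)),
          "values must be a named list matching the genome's chromosomes")
  values <- values[names(genome)]
  for (ch in names(genome)) {
    nw <- ceiling(genome[[ch]] / window_size)
    .assert(length(values[[ch]]) == nw,
            "track vector for ", ch, " must have ", nw, " windows")
    if (value_kind == "count")
      .assert(all(values[[ch]] >= 0), "counts must be non-negative")
  }
  structure(list(values = values, window_size = as.integer(window_size),
                 chrom_lengths = setNames(as.numeric(genome), names(genome)),
                 value_kind = value_kind),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track (", x$value_kind, "): ", length(x$values),
      " chromosome(s), window ", x$window_size, " bp, total ",
      format(track_total(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Sum of all window values in a track
#' @param track A [window_track()].
#' @return A single number.
#' @export
track_total <- function(track) {
  .assert(inherits(track, "window_track"), "not a window_track")
  sum(vapply(track$values, sum, numeric(1)))
}

# do two tracks share the same window grid?
.same_grid <- function(a, b) {
  identical(a$window_size, b$window_size) &&
    identical(names(a$values), names(b$values)) &&
    identical(a$chrom_lengths, b$chrom_lengths)
}

#' Depth-normalize a count track to reads per million
#'
#' Divides every window value by the track total and multiplies by 1e6,
#' producing a `density` track. Used before subtracting tracks from samples
#' of different depth.
#'
#' @param track A count [window_track()] with positive total.
#' @return A `density` window_track.
#' @export
rpm_track <- function(track) {
  tot <- track_total(track)
  .assert(tot > 0, "cannot RPM-normalize an empty track")
  g <- genome_spec(track$chrom_lengths)
  window_track(lapply(track$values, function(v) v * 1e6 / tot),
               track$window_size, g, value_kind = "density")
}

# Integral of the track step function from position 0 to each x (bp units).
# x outside [0, n_windows * window_size] contributes nothing extra.
.track_integral <- function(v, ws, x) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  x <- pmin(pmax(x, 0), n * ws)
  i <- pmin(floor(x / ws), n - 1)
  cs[i + 1] * ws + v[i + 1] * (x - i * ws)
}

#' Mean track signal over arbitrary base-pair intervals
#'
#' Computes the length-weighted mean window value over each half-open
#' interval `[starts[i], ends[i])` on one chromosome. Parts of an interval
#' lying outside the chromosome contribute 0 signal but still count in the
#' denominator, so profiles near chromosome edges decay rather than break.
#'
#' @param track A [window_track()].
#' @param chrom Chromosome name (single string).
#' @param starts,ends Numeric vectors of interval bounds (bp), `ends > starts`.
#' @return Numeric vector of means, one per interval.
#' @export
interval_means <- function(track, chrom, starts, ends) {
  .assert(inherits(track, "window_track"), "not a window_track")
  .assert(chrom %in% names(track$values), "unknown chromosome: ", chrom)
  .assert(length(starts) == length(ends) && all(ends > starts),
          "intervals must satisfy end > start")
  v <- track$values[[chrom]]
  ws <- track$window_size
  (.track_integral(v, ws, ends) - .track_integral(v, ws, starts)) /
    (ends - starts)
}
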