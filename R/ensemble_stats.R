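# Time-series statistics, histograms, correlations, and the
# superposition-averaged structure.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Returns the proper rotation `R` and translation `t` minimising the RMSD
#' of `P` onto `Q` (`Q ~ P %*% t(R) + t`), with the reflection branch of
#' the SVD corrected so `det(R) = +1` always.
#'
#' @param P,Q `N x 3` coordinate matrices (N >= 3), row-matched.
#' @return List with `rotation` (3 x 3), `translation` (length 3), and
#'   `rmsd` of the superposed sets (Angstrom).
#' @export
kabsch_rotation <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 3L)
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  s <- svd(crossprod(P0, Q0))          # t(P0) %*% Q0
  if (min(s$d) < 1e-12 * max(s$d, 1e-300) && sum(s$d > 1e-12 * max(s$d)) < 2)
    stop("degenerate (collinear) point set: superposition is ill-defined")
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate point set: superposition is ill-defined")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P0 %*% t(R)
  list(rotation = R,
       translation = cQ - drop(R %*% cP),
       rmsd = sqrt(mean(rowSums((fitted - Q0)^2))))
}

#' Superposition-averaged structure of a trajectory
#'
#' Every frame is rigidly aligned (all atoms, unweighted) onto the first
#' frame with [kabsch_rotation()], aligned coordinates are averaged per
#' atom, and the per-atom positional spread (RMSF) about the mean is
#' reported.
#'
#' @param traj An `xyz_trajectory` with at least one frame.
#' @return Object of class `average_structure`: `coords` (`natoms x 3`
#'   mean coordinates, Angstrom), `rmsf` (length natoms, Angstrom),
#'   `elements`, `reference_frame` (source index of frame 1).
#' @export
average_structure <- function(traj) {
  stopifnot(inherits(traj, "xyz_trajectory"))
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames")
  ref <- traj$coords[, , 1]
  aligned <- array(NA_real_, dim = dim(traj$coords))
  aligned[, , 1] <- ref
  for (k in seq_len(nf)[-1]) {
    fit <- kabsch_rotation(traj$coords[, , k], ref)
    aligned[, , k] <- sweep(traj$coords[, , k] %*% t(fit$rotation), 2,
                            fit$translation, `+`)
  }
  mean_xyz <- apply(aligned, c(1, 2), mean)
  dev2 <- sweep(aligned, c(1, 2), mean_xyz)^2
  rmsf <- sqrt(apply(dev2, 1, sum) / nf)
  structure(list(coords = mean_xyz, rmsf = rmsf, elements = traj$elements,
                 reference_frame = traj$frame_index[1]),
            class = "average_structure")
}

#' @export
print.average_structure <- function(x, ...) {
  cat("<average_structure> ", length(x$elements), " atoms, mean RMSF ",
      signif(mean(x$rmsf), 4), " A (reference frame ", x$reference_frame,
      ")\n", sep = "")
  invisible(x)
}

#' Write an average structure as single-frame XYZ
#' @param avg An [average_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_average_structure <- function(avg, path) {
  stopifnot(inherits(avg, "average_structure"))
  traj <- trajectory(avg$elements, avg$coords, frame_index = 0L, times = 0)
  write_xyz_trajectory(traj, path)
}

#' Descriptive statistics of a series
#'
#' Min, max, mean, population standard deviation (divide by n — the series
#' is the full population of frames, not a sample), and range.
#'
#' @param values Non-empty numeric vector.
#' @param units Optional units tag carried in the result.
#' @return Object of class `series_stats`.
#' @export
series_stats <- function(values, units = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("`values` must be a non-empty finite numeric series")
  n <- length(values)
  m <- mean(values)
  structure(list(min = min(values), max = max(values), mean = m,
                 std = sqrt(sum((values - m)^2) / n),
                 range = max(values) - min(values),
                 n = n, units = units),
            class = "series_stats")
}

#' @export
print.series_stats <- function(x, ...) {
  cat(sprintf("<series_stats> n=%d  min %.4g  max %.4g  mean %.4g  std %.4g  range %.4g",
              x$n, x$min, x$max, x$mean, x$std, x$range))
  if (!is.na(x$units)) cat(" [", x$units, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Root-mean-square deviation between two series
#'
#' `sqrt(mean((a - b)^2))` — e.g. between experimental and time-averaged
#' calculated shifts.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Scalar RMSD.
#' @export
rmsd_values <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("`a` and `b` must be non-empty and of equal length")
  sqrt(mean((a - b)^2))
}

#' Histogram with uniform bins on a snapped support
#'
#' Uniform bins of width `bin_width` spanning
#' `[bin_width * floor(min/bin_width), bin_width * ceiling(max/bin_width)]`;
#' bins are half-open `[lo, hi)` except the last, which is closed.
#'
#' @param values Numeric series.
#' @param bin_width Positive bin width (e.g. 5 ppm for shift spectra,
#'   1 degree for angle distributions).
#' @return Object of class `shift_histogram`: `breaks`, `counts`, `n`.
#' @export
shift_histogram <- function(values, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive")
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("`values` must be a non-empty finite numeric series")
  lo <- bin_width * floor(min(values) / bin_width)
  hi <- bin_width * ceiling(max(values) / bin_width)
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  # half-open [lo, hi), last bin closed
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts, n = length(values)),
            class = "shift_histogram")
}

#' @export
print.shift_histogram <- function(x, ...) {
  cat("<shift_histogram> ", length(x$counts), " bins over [",
      x$breaks[1], ", ", x$breaks[length(x$breaks)], "], n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

#' Pearson correlation between two series
#'
#' @param a,b Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
series_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("`a` and `b` must be of equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a series has zero variance")
  stats::cor(a, b)
}
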