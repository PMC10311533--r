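# Pseudo-C3 axis construction and donor-metal-axis angles.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("zero-length vector cannot be normalised")
  v / n
}

#' Unit normal of the plane through three points
#'
#' The normal is oriented so that its dot product with `orient_ref` is
#' positive; this fixes the hemisphere consistently across frames.
#'
#' @param p1,p2,p3 Numeric length-3 points (Angstrom).
#' @param orient_ref Orientation reference vector (need not be unit).
#' @return Unit length-3 vector.
#' @export
plane_unit_normal <- function(p1, p2, p3, orient_ref) {
  v1 <- p2 - p1; v2 <- p3 - p1
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  area2 <- sqrt(sum(n^2))           # twice the triangle area
  if (area2 / 2 <= 1e-10)
    stop("degenerate geometry: the three points are (near-)collinear")
  n <- n / area2
  d <- sum(n * orient_ref)
  if (abs(d) < 1e-12)
    stop("orientation ambiguity: reference vector is orthogonal to the plane normal")
  if (d < 0) n <- -n
  n
}

#' Instantaneous pseudo-C3 axis of one frame
#'
#' The pseudo-threefold axis is the renormalised average of the unit
#' normals of the three donor planes (O triplet, axial-N triplet,
#' equatorial-N triplet), each normal oriented towards the axial-N side
#' (reference: vector from the O-triplet centroid to the N_ax-triplet
#' centroid).
#'
#' @param frame A frame as returned by [get_frame()], or any list with
#'   `coords` (`natoms x 3`).
#' @param donors A [donor_map()].
#' @return List of class `axis_result`: unit `axis`, the 3 x 3 matrix
#'   `component_normals` (rows O, N_ax, N_eq) and `frame_index`.
#' @export
pseudo_c3_axis <- function(frame, donors) {
  stopifnot(inherits(donors, "donor_map"))
  xyz <- frame$coords
  tri <- list(O = donors$o_donors, N_ax = donors$n_ax, N_eq = donors$n_eq)
  cent <- function(ix) colMeans(xyz[.idx1(ix), , drop = FALSE])
  orient_ref <- cent(donors$n_ax) - cent(donors$o_donors)
  normals <- matrix(NA_real_, 3, 3, dimnames = list(names(tri), NULL))
  for (g in names(tri)) {
    p <- xyz[.idx1(tri[[g]]), , drop = FALSE]
    normals[g, ] <- tryCatch(
      plane_unit_normal(p[1, ], p[2, ], p[3, ], orient_ref),
      error = function(e) stop("donor group ", g, ": ", conditionMessage(e)))
  }
  structure(list(axis = .unit(colMeans(normals)),
                 component_normals = normals,
                 frame_index = if (is.null(frame$index)) NA_integer_ else frame$index),
            class = "axis_result")
}

#' Angle between a metal-donor bond and an axis
#'
#' @param metal,donor Length-3 points (Angstrom).
#' @param axis Unit length-3 vector.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
donor_axis_angle <- function(metal, donor, axis) {
  b <- donor - metal
  nb <- sqrt(sum(b^2))
  if (nb < .Machine$double.eps) stop("zero-length metal-donor bond vector")
  ct <- sum(b * axis) / (nb * sqrt(sum(axis^2)))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Donor-metal-axis angle time series for one donor group
#'
#' The pseudo-C3 axis is recomputed in every frame; the three arm angles
#' (arm identity follows donor-map order and is stable across frames) are
#' evaluated against it.
#'
#' @param traj An `xyz_trajectory`.
#' @param donors A [donor_map()].
#' @param group One of `"O"`, `"N_ax"`, `"N_eq"`.
#' @return Object of class `angle_series`: list with `group`, `times` (fs),
#'   `frame_index`, and `angles`, an `nframes x 3` matrix in degrees with
#'   columns `arm1`, `arm2`, `arm3`.
#' @export
angle_time_series <- function(traj, donors, group = c("O", "N_ax", "N_eq")) {
  stopifnot(inherits(traj, "xyz_trajectory"), inherits(donors, "donor_map"))
  group <- match.arg(group)
  if (max(c(donors$metal, donors$o_donors, donors$n_ax, donors$n_eq,
            unlist(donors$h_triplets))) >= n_atoms(traj))
    stop("donor map indexes atoms beyond the trajectory atom count")
  gidx <- switch(group, O = donors$o_donors, N_ax = donors$n_ax,
                 N_eq = donors$n_eq)
  nf <- n_frames(traj)
  ang <- matrix(NA_real_, nf, 3,
                dimnames = list(NULL, paste0("arm", 1:3)))
  for (k in seq_len(nf)) {
    fr <- get_frame(traj, k)
    ax <- tryCatch(pseudo_c3_axis(fr, donors),
                   error = function(e) stop("frame ", fr$index, ": ",
                                            conditionMessage(e)))
    metal <- fr$coords[.idx1(donors$metal), ]
    for (a in 1:3)
      ang[k, a] <- donor_axis_angle(metal, fr$coords[.idx1(gidx[a]), ], ax$axis)
  }
  structure(list(group = group,
                 times = if (is.null(traj$times)) as.numeric(traj$frame_index) else traj$times,
                 frame_index = traj$frame_index,
                 angles = ang),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat("<angle_series> group ", x$group, ", ", nrow(x$angles), " frames\n",
      sep = "")
  cat(sprintf("  pooled mean %.2f deg, min %.2f, max %.2f\n",
              mean(x$angles), min(x$angles), max(x$angles)))
  invisible(x)
}

#' Write an angle series as CSV
#'
#' Columns `frame`, `time_fs`, `arm1_deg`, `arm2_deg`, `arm3_deg`; angles
#' printed to 4 decimal places.
#'
#' @param series An [angle_time_series()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  df <- data.frame(frame = series$frame_index, time_fs = series$times,
                   arm1_deg = round(series$angles[, 1], 4),
                   arm2_deg = round(series$angles[, 2], 4),
                   arm3_deg = round(series$angles[, 3], 4))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
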