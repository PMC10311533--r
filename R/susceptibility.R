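# Magnetic susceptibility tensors, anisotropy decomposition, and
# pseudocontact shifts (full point-dipole tensor model and Bleaney's
# axial crystal-field approximation).

#' Construct a susceptibility tensor
#'
#' @param matrix Symmetric 3 x 3 numeric matrix.
#' @param units `"cgs_molar_cm3_per_mol"` (the convention of molar
#'   susceptibilities from quantum chemistry, cm^3 mol^-1) or
#'   `"si_molecular_m3"` (per-molecule SI, m^3, as used by the point-dipole
#'   shift formula).
#' @param temperature Temperature in K at which the tensor was evaluated.
#' @return Object of class `chi_tensor`.
#' @export
chi_tensor <- function(matrix, units = "cgs_molar_cm3_per_mol",
                       temperature = 298) {
  units <- match.arg(units, .chi_units)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3L, 3L)),
            all(is.finite(matrix)))
  scale <- max(abs(matrix), .Machine$double.xmin)
  if (max(abs(matrix - t(matrix))) > 1e-10 * scale)
    stop("susceptibility tensor is not symmetric within tolerance")
  matrix <- (matrix + t(matrix)) / 2
  structure(list(matrix = matrix, units = units,
                 temperature = as.numeric(temperature)),
            class = "chi_tensor")
}

#' @export
print.chi_tensor <- function(x, ...) {
  cat("<chi_tensor> units ", x$units, ", T = ", x$temperature, " K\n", sep = "")
  print(signif(x$matrix, 6))
  cat("  iso =", signif(sum(diag(x$matrix)) / 3, 6), "\n")
  invisible(x)
}

#' Convert susceptibility units
#'
#' cgs molar (cm^3 mol^-1) and SI per-molecule (m^3) representations are
#' related elementwise by `chi_SI = chi_cgs * 4*pi*1e-6 / N_A`.
#'
#' @param chi A [chi_tensor()].
#' @param target Target unit flag.
#' @return A [chi_tensor()] in the target units; temperature preserved.
#' @export
convert_chi_units <- function(chi, target) {
  stopifnot(inherits(chi, "chi_tensor"))
  target <- match.arg(target, .chi_units)
  if (identical(chi$units, target)) return(chi)
  f <- .const$chi_cgs_to_si
  m <- if (target == "si_molecular_m3") chi$matrix * f else chi$matrix / f
  chi_tensor(m, units = target, temperature = chi$temperature)
}

# sign-fix an eigenvector: largest-|component| made positive (deterministic
# orientation, also the tie-break for degenerate eigenvalues)
.fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v

#' Decompose a susceptibility tensor into isotropic part and anisotropy
#'
#' Diagonalises the traceless part `chi' = chi - (tr chi / 3) I`. The
#' principal z-axis carries the traceless eigenvalue of largest magnitude;
#' of the remaining two, x carries the larger magnitude, so that
#' `|dchi_rh| <= (2/3) |dchi_ax|` (the standard paramagnetic-NMR
#' convention) and the frame is right-handed. The tensor is classed
#' easy-axis when `chi'_zz > 0` (one large, two small eigenvalues) and
#' easy-plane otherwise.
#'
#' @param chi A [chi_tensor()].
#' @return Object of class `chi_decomposition` with fields `iso`,
#'   `eigenvalues` (full-tensor principal values, order x, y, z), `axes`
#'   (3 x 3, columns = principal x, y, z), `dchi_ax`
#'   (`chi_zz - (chi_xx + chi_yy)/2`), `dchi_rh` (`chi_xx - chi_yy`),
#'   `anisotropy_class`, and `units`.
#' @export
decompose_chi <- function(chi) {
  stopifnot(inherits(chi, "chi_tensor"))
  iso <- sum(diag(chi$matrix)) / 3
  tracefree <- chi$matrix - diag(iso, 3)
  e <- eigen(tracefree, symmetric = TRUE)   # values decreasing
  ord_z <- which.max(abs(e$values))
  rest <- setdiff(1:3, ord_z)
  ord_x <- rest[which.max(abs(e$values[rest]))]
  ord_y <- setdiff(rest, ord_x)
  vals <- e$values[c(ord_x, ord_y, ord_z)]
  vx <- .fix_sign(e$vectors[, ord_x])
  vz <- .fix_sign(e$vectors[, ord_z])
  vy <- c(vz[2] * vx[3] - vz[3] * vx[2],   # y = z cross x: right-handed
          vz[3] * vx[1] - vz[1] * vx[3],
          vz[1] * vx[2] - vz[2] * vx[1])
  axes <- cbind(x = vx, y = vy, z = vz)
  dchi_ax <- 1.5 * vals[3]
  dchi_rh <- vals[1] - vals[2]
  structure(list(iso = iso,
                 eigenvalues = vals + iso,
                 axes = axes,
                 dchi_ax = dchi_ax,
                 dchi_rh = dchi_rh,
                 anisotropy_class = if (vals[3] > 0) "easy-axis" else "easy-plane",
                 units = chi$units),
            class = "chi_decomposition")
}

#' @export
print.chi_decomposition <- function(x, ...) {
  cat("<chi_decomposition> (", x$units, ")\n",
      sprintf("  iso %.6g   dchi_ax %.6g   dchi_rh %.6g   [%s]\n",
              x$iso, x$dchi_ax, x$dchi_rh, x$anisotropy_class), sep = "")
  invisible(x)
}

#' Pseudocontact shift from a full susceptibility tensor
#'
#' Point-dipole model: with `r` the metal-to-nucleus vector (in m) and
#' `chi~` the traceless part of the per-molecule SI tensor (m^3),
#' `delta_pc = 1e6 / (4 pi r^5) * t(r) %*% chi~ %*% r` (ppm). The
#' equivalent principal-axis-system form
#' `1e6 / (12 pi r^5) * (dchi_ax (3 z^2 - r^2) + 1.5 dchi_rh (x^2 - y^2))`
#' is evaluated alongside and asserted equal — a built-in cross-check of
#' the decomposition conventions.
#'
#' @param chi A [chi_tensor()] (any units; converted internally).
#' @param metal,nucleus Positions in Angstrom.
#' @return Shift in ppm.
#' @export
pcs_full_tensor <- function(chi, metal, nucleus) {
  stopifnot(inherits(chi, "chi_tensor"))
  chi_si <- convert_chi_units(chi, "si_molecular_m3")
  rvec_ang <- nucleus - metal
  r_ang <- sqrt(sum(rvec_ang^2))
  if (r_ang < 0.5)
    stop("metal-nucleus distance ", signif(r_ang, 3),
         " A is below the 0.5 A point-dipole validity limit")
  rvec <- rvec_ang * 1e-10
  r <- r_ang * 1e-10
  iso <- sum(diag(chi_si$matrix)) / 3
  tracefree <- chi_si$matrix - diag(iso, 3)
  d_cart <- 1e6 * drop(rvec %*% tracefree %*% rvec) / (4 * pi * r^5)
  # PAS form as internal oracle
  dec <- decompose_chi(chi_si)
  rp <- drop(t(dec$axes) %*% rvec)        # coordinates in the PAS
  d_pas <- 1e6 * (dec$dchi_ax * (3 * rp[3]^2 - r^2) +
                    1.5 * dec$dchi_rh * (rp[1]^2 - rp[2]^2)) / (12 * pi * r^5)
  if (abs(d_cart - d_pas) > 1e-8 * max(abs(d_cart), abs(d_pas)) + 1e-9)
    stop("internal inconsistency: coordinate-free and PAS shift formulas disagree")
  d_cart
}

#' Bleaney axial pseudocontact shift
#'
#' Bleaney's simplified crystal-field theory:
#' `delta ~ prefactor * C_J * B20 * (3 cos^2 theta - 1) / (r^3 T^2)`.
#' With the default `prefactor = 1` the result is in Bleaney-convention
#' relative units (the `C_J` scale is normalised to `C_Dy = -100`); supply
#' an absolute prefactor to obtain ppm under a specific convention.
#'
#' @param params List (or `bleaney_params()`) with `B20` (axial
#'   crystal-field parameter, cm^-1), `C_J` (Bleaney constant), `T`
#'   (temperature, K) and optional `prefactor` (default 1).
#' @param theta Polar angle of the nucleus from the symmetry axis, degrees.
#' @param r Metal-nucleus distance, Angstrom.
#' @return Relative (or ppm, per `prefactor`) shift.
#' @export
pcs_bleaney <- function(params, theta, r) {
  stopifnot(is.list(params), !is.null(params$B20), !is.null(params$C_J),
            !is.null(params$T))
  if (params$T <= 0) stop("temperature must be positive")
  if (any(r <= 0)) stop("metal-nucleus distance must be positive")
  pref <- if (is.null(params$prefactor)) 1 else params$prefactor
  ct <- cos(theta * pi / 180)
  pref * params$C_J * params$B20 * (3 * ct^2 - 1) / (r^3 * params$T^2)
}

#' Bundle Bleaney-model parameters
#'
#' @param B20 Axial crystal-field parameter (cm^-1).
#' @param ion Ln(III) element symbol used to look up `C_J` from
#'   [bleaney_constants()]; ignored when `C_J` is given directly.
#' @param C_J Bleaney constant (overrides `ion`).
#' @param T Temperature in K.
#' @param prefactor Absolute prefactor hook (default 1: Bleaney-convention
#'   relative units).
#' @return List suitable for [pcs_bleaney()].
#' @export
bleaney_params <- function(B20, ion = "Dy", C_J = NULL, T = 298,
                           prefactor = 1) {
  if (is.null(C_J)) {
    tab <- bleaney_constants()
    if (!ion %in% names(tab)) stop("no Bleaney constant tabulated for ", ion)
    C_J <- tab[[ion]]
  }
  if (T <= 0) stop("temperature must be positive")
  list(B20 = B20, C_J = C_J, T = T, prefactor = prefactor)
}

#' Per-frame pseudocontact shifts along a trajectory
#'
#' Applies [pcs_full_tensor()] with each frame's metal position to the
#' nine pyridyl protons, then forms the triplet averages H1/H2/H3 (the
#' chemically equivalent sets of the symmetric complex) and time averages.
#'
#' @param traj An `xyz_trajectory`.
#' @param chi_series List of [chi_tensor()] objects, one per frame.
#' @param donors A [donor_map()].
#' @return Object of class `shift_series`: `per_atom` (`nframes x 9` ppm,
#'   columns named `H1_1 ... H3_3`), `triplet` (`nframes x 3`, columns
#'   H1/H2/H3), `time_average` (named length-3), `times`, `frame_index`,
#'   and `nucleus_index` (0-based atom indices per column of `per_atom`).
#' @export
pcs_trajectory <- function(traj, chi_series, donors) {
  stopifnot(inherits(traj, "xyz_trajectory"), inherits(donors, "donor_map"))
  nf <- n_frames(traj)
  if (!is.list(chi_series) || length(chi_series) != nf)
    stop("`chi_series` must supply one tensor per frame (",
         length(chi_series), " tensors for ", nf, " frames)")
  hnames <- names(donors$h_triplets)
  nuc_idx <- unlist(donors$h_triplets, use.names = FALSE)
  colnm <- unlist(lapply(hnames, function(h) paste0(h, "_", 1:3)))
  per_atom <- matrix(NA_real_, nf, 9, dimnames = list(NULL, colnm))
  for (k in seq_len(nf)) {
    chi <- chi_series[[k]]
    if (!inherits(chi, "chi_tensor"))
      stop("chi_series[[", k, "]] is not a chi_tensor")
    xyz <- traj$coords[, , k]
    metal <- xyz[.idx1(donors$metal), ]
    per_atom[k, ] <- vapply(nuc_idx, function(i)
      pcs_full_tensor(chi, metal, xyz[.idx1(i), ]), numeric(1))
  }
  triplet <- sapply(hnames, function(h)
    rowMeans(per_atom[, paste0(h, "_", 1:3), drop = FALSE]))
  if (nf == 1L) triplet <- matrix(triplet, 1, 3, dimnames = list(NULL, hnames))
  structure(list(per_atom = per_atom,
                 triplet = triplet,
                 time_average = colMeans(triplet),
                 times = if (is.null(traj$times)) as.numeric(traj$frame_index) else traj$times,
                 frame_index = traj$frame_index,
                 nucleus_index = stats::setNames(nuc_idx, colnm)),
            class = "shift_series")
}

#' @export
print.shift_series <- function(x, ...) {
  cat("<shift_series> ", nrow(x$per_atom), " frames, 9 nuclei\n", sep = "")
  cat("  time-averaged triplet shifts (ppm):\n")
  print(signif(x$time_average, 4))
  invisible(x)
}

#' Read / write per-frame susceptibility tensors
#'
#' JSON format: a list of records `{frame, T_K, units, chi}` with `chi` a
#' 3 x 3 matrix. CSV format: columns `frame, T_K, units, xx, yy, zz, xy,
#' xz, yz` (the six unique components).
#'
#' @param path File path (`.json` or `.csv`).
#' @return List of [chi_tensor()] objects (with `frame` attributes).
#' @export
read_chi_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("xx", "yy", "zz", "xy", "xz", "yz")
    if (!all(need %in% names(df)))
      stop("chi CSV must have columns ", paste(need, collapse = ", "))
    lapply(seq_len(nrow(df)), function(i) {
      m <- with(df[i, ], matrix(c(xx, xy, xz, xy, yy, yz, xz, yz, zz), 3, 3))
      ct <- chi_tensor(m, units = as.character(df$units[i]),
                       temperature = df$T_K[i])
      attr(ct, "frame") <- df$frame[i]
      ct
    })
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(recs, function(r) {
      m <- matrix(unlist(r$chi), 3, 3, byrow = TRUE)
      ct <- chi_tensor(m, units = r$units, temperature = r$T_K)
      attr(ct, "frame") <- r$frame
      ct
    })
  }
}

#' @rdname read_chi_series
#' @param chi_series List of [chi_tensor()] objects.
#' @param frame_index Frame numbers to record (defaults to each tensor's
#'   `frame` attribute, else 0-based position).
#' @export
write_chi_series <- function(chi_series, path, frame_index = NULL) {
  if (is.null(frame_index))
    frame_index <- vapply(seq_along(chi_series), function(i) {
      f <- attr(chi_series[[i]], "frame")
      if (is.null(f)) i - 1L else as.integer(f)
    }, integer(1))
  recs <- lapply(seq_along(chi_series), function(i) {
    ch <- chi_series[[i]]
    list(frame = frame_index[i], T_K = ch$temperature, units = ch$units,
         chi = apply(ch$matrix, 1, as.list))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a shift series as CSV plus summary
#'
#' @param shifts A [pcs_trajectory()] result.
#' @param path Output CSV path (per-frame table). When `summary_path` is
#'   given, a JSON summary with the triplet time averages is written too.
#' @param summary_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_shift_series <- function(shifts, path, summary_path = NULL) {
  stopifnot(inherits(shifts, "shift_series"))
  df <- data.frame(frame = shifts$frame_index, time_fs = shifts$times,
                   shifts$per_atom, shifts$triplet, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(as.list(shifts$time_average), summary_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
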