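# Desk-scale crystal-field surrogate: ground-multiplet Hamiltonian from
# Stevens operator equivalents with a point-charge parameterisation, and
# the Van Vleck equilibrium susceptibility tensor.
#
# Operator conventions. Rank-k spherical tensor operators T_k^q are built
# by ladder recursion from the highest-weight component T_k^k = J+^k
# ([J-, T_k^q] = sqrt((k+q)(k-q+1)) T_k^{q-1}), then combined into real
# Hermitian tesseral operators. The q = 0 operators are rescaled to the
# classical Stevens polynomials (O_2^0 = 3 Jz^2 - J(J+1) exactly); q != 0
# operators keep the spherical-tensor relative normalisation of their
# rank. point_charge_cf() uses the *matching dual* real tesseral
# harmonics, which makes H = sum_kq B_k^q O_k^q exactly equal to the
# rotationally invariant contraction sum_q (-1)^q C_k^{-q}(n) T_k^q per
# charge — so the whole surrogate chain is equivariant under rotations
# regardless of normalisation bookkeeping.

#' Ground-multiplet spin system of a lanthanide ion
#'
#' @param J Total angular momentum (integer or half-integer). Default
#'   15/2, the 6H15/2 ground term of Dy(III) (4f^9).
#' @param gJ Lande g-factor; default 4/3 (Dy(III)).
#' @return Object of class `spin_system` with the `2J+1` dimensional
#'   angular-momentum matrices `Jz`, `Jp`, `Jm` in the `|J, mJ>` basis
#'   (mJ = J ... -J).
#' @export
spin_system <- function(J = 15 / 2, gJ = 4 / 3) {
  twoJ <- round(2 * J)
  if (abs(2 * J - twoJ) > 1e-9 || twoJ < 1)
    stop("2J+1 must be a positive integer (J integer or half-integer)")
  if (gJ <= 0) stop("gJ must be positive")
  J <- twoJ / 2
  m <- seq(J, -J)
  n <- length(m)
  Jp <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    Jp[i, i + 1L] <- sqrt(J * (J + 1) - m[i + 1L] * (m[i + 1L] + 1))
  structure(list(J = J, gJ = gJ, dim = n, m = m,
                 Jz = diag(m), Jp = Jp, Jm = t(Jp)),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system> J = ", format(x$J), ", gJ = ", format(x$gJ),
      ", dim = ", x$dim, "\n", sep = "")
  invisible(x)
}

# spherical tensor components T_k^q, q = k..-k (list index k-q+1)
.sph_tensors <- function(system, k) {
  T <- vector("list", 2L * k + 1L)
  Tk <- diag(system$dim)
  for (i in seq_len(k)) Tk <- Tk %*% system$Jp
  T[[1L]] <- Tk
  q <- k
  for (i in seq_len(2L * k)) {
    T[[i + 1L]] <- (system$Jm %*% T[[i]] - T[[i]] %*% system$Jm) /
      sqrt((k + q) * (k - q + 1))
    q <- q - 1
  }
  T
}

# classical Stevens q=0 polynomial in mJ, used to scale each rank
.stevens_q0_poly <- function(k, m, X) {
  switch(as.character(k),
         "2" = 3 * m^2 - X,
         "4" = 35 * m^4 - (30 * X - 25) * m^2 + 3 * X^2 - 6 * X,
         "6" = 231 * m^6 - (315 * X - 735) * m^4 +
           (105 * X^2 - 525 * X + 294) * m^2 -
           5 * X^3 + 40 * X^2 - 60 * X,
         stop("rank k must be 2, 4 or 6"))
}

# rank scale s_k such that s_k * T_k^0 equals the Stevens q=0 polynomial
.rank_scale <- function(system, k, T = NULL) {
  if (is.null(T)) T <- .sph_tensors(system, k)
  X <- system$J * (system$J + 1)
  poly <- .stevens_q0_poly(k, system$m, X)
  d <- Re(diag(T[[k + 1L]]))
  i <- which.max(abs(poly))
  poly[i] / d[i]
}

#' Stevens operator-equivalent matrix
#'
#' Hermitian tesseral operator in the `|J, mJ>` basis. `q = 0` operators
#' match the classical Stevens polynomials exactly (`O_2^0 = 3 Jz^2 -
#' J(J+1)`); `q != 0` operators are the real (cosine for `q > 0`, sine for
#' `q < 0`) tesseral combinations of the rank-k spherical tensor with the
#' rank's common scale. For `k > 2J` the operator vanishes identically and
#' an error is raised rather than returning a silent zero.
#'
#' @param system A [spin_system()].
#' @param k Rank, one of 2, 4, 6.
#' @param q Component, `-k <= q <= k`.
#' @return `(2J+1) x (2J+1)` real matrix.
#' @export
stevens_operator <- function(system, k, q) {
  stopifnot(inherits(system, "spin_system"))
  if (!k %in% c(2, 4, 6)) stop("rank k must be 2, 4 or 6")
  if (abs(q) > k) stop("|q| must not exceed k")
  if (k > 2 * system$J)
    stop("k = ", k, " exceeds 2J = ", 2 * system$J,
         ": the operator equivalent vanishes identically")
  T <- .sph_tensors(system, k)
  s <- .rank_scale(system, k, T)
  O <- if (q == 0) {
    T[[k + 1L]]
  } else {
    aq <- abs(q)
    Tp <- T[[k - aq + 1L]]; Tm <- T[[k + aq + 1L]]
    if (q > 0) ((-1)^aq * Tp + Tm) / sqrt(2)
    else ((-1)^aq * Tp - Tm) / (1i * sqrt(2))
  }
  O <- s * O
  O <- (O + Conj(t(O))) / 2            # enforce exact Hermiticity
  if (max(abs(Im(O))) < 1e-12 * max(abs(Re(O)), 1)) O <- Re(O)
  O
}

# real tesseral harmonics z_kq dual to the operators above:
# z_k0 = C_k^0, z_kq = sqrt(2) Re[(-1)^q C_k^q] (q>0),
# z_k,-|q| = sqrt(2) Im[(-1)^|q| C_k^|q|], with Racah-normalised
# C_k^q = sqrt((k-q)!/(k+q)!) P_k^q(cos th) e^{i q ph} (Condon-Shortley).
# z_20(th) = (3 cos^2 th - 1)/2.
.tesseral_z <- function(k, q, theta, phi) {
  aq <- abs(q)
  P <- pracma::legendre(k, cos(theta))[aq + 1L, ]
  cpos <- sqrt(factorial(k - aq) / factorial(k + aq)) * P
  if (q == 0) return(cpos)
  if (q > 0) sqrt(2) * (-1)^aq * cpos * cos(aq * phi)
  else sqrt(2) * (-1)^aq * cpos * sin(aq * phi)
}

#' Assemble a point-charge set
#'
#' @param charges Numeric vector of charges in elementary-charge units.
#' @param positions `n x 3` matrix of positions in Angstrom, relative to
#'   the metal at the origin.
#' @param A_k Named numeric `c(A2=, A4=, A6=)`: per-rank radial scale
#'   factors in cm^-1 Angstrom^(k+1) per elementary charge. They fold the
#'   Stevens reduced matrix element theta_k, the radial expectation value
#'   <r^k> and the Coulomb prefactor. Defaults are the Dy(III) values
#'   built from theta_2 = -2/315, theta_4 = -8/135135, theta_6 =
#'   4/3864861 and Freeman-Watson <r^k> (0.726, 1.322, 5.102 a0^k),
#'   including the electron-charge sign.
#' @return Object of class `charge_set`.
#' @export
charge_set <- function(charges, positions,
                       A_k = c(A2 = 149.93, A4 = 0.71266, A6 = -0.013466)) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) == length(charges),
            all(is.finite(positions)), all(is.finite(charges)),
            all(is.finite(A_k)))
  if (!all(c("A2", "A4", "A6") %in% names(A_k)))
    stop("`A_k` must be named A2, A4, A6")
  R <- sqrt(rowSums(positions^2))
  if (any(R < 1e-8)) stop("a point charge coincides with the metal at the origin")
  structure(list(charges = as.numeric(charges), positions = positions,
                 A_k = A_k[c("A2", "A4", "A6")]),
            class = "charge_set")
}

#' Crystal-field parameters from a point-charge model
#'
#' `B_k^q = A_k / s_k * sum_i q_i z_kq(theta_i, phi_i) / R_i^(k+1)`, with
#' `z_kq` the real tesseral harmonics dual to [stevens_operator()]'s
#' normalisation (`s_k` is the rank scale; the single-charge `B_2^0`
#' contribution is proportional to `q (3 cos^2 theta - 1) / R^3`, so it
#' vanishes at the magic angle `theta = arccos(1/sqrt(3))`).
#'
#' @param charges A [charge_set()].
#' @param system A [spin_system()] (fixes the rank scales and which ranks
#'   are admissible).
#' @return Object of class `cf_parameters`: named list `B[["k2"]] ...`
#'   of length-(2k+1) numeric vectors indexed `q = -k..k`.
#' @export
point_charge_cf <- function(charges, system) {
  stopifnot(inherits(charges, "charge_set"), inherits(system, "spin_system"))
  if (length(charges$charges) == 0L) stop("empty charge set")
  pos <- charges$positions
  R <- sqrt(rowSums(pos^2))
  theta <- acos(pmax(-1, pmin(1, pos[, 3] / R)))
  phi <- atan2(pos[, 2], pos[, 1])
  ks <- c(2, 4, 6)
  ks <- ks[ks <= 2 * system$J]
  B <- list()
  for (k in ks) {
    s_k <- .rank_scale(system, k)
    A_k <- charges$A_k[[paste0("A", k)]]
    bk <- vapply(-k:k, function(q)
      sum(charges$charges * .tesseral_z(k, q, theta, phi) / R^(k + 1)),
      numeric(1)) * A_k / s_k
    B[[paste0("k", k)]] <- stats::setNames(bk, paste0("q", -k:k))
  }
  structure(list(B = B), class = "cf_parameters")
}

#' @export
print.cf_parameters <- function(x, ...) {
  cat("<cf_parameters> (cm^-1)\n")
  for (nm in names(x$B)) {
    cat(" ", nm, ": ")
    cat(paste0(names(x$B[[nm]]), "=", signif(x$B[[nm]], 4)), sep = "  ")
    cat("\n")
  }
  invisible(x)
}

#' Extract one crystal-field coefficient
#'
#' @param params A [point_charge_cf()] result (`cf_parameters`).
#' @param k,q Rank and component.
#' @return Numeric coefficient in cm^-1 (0 when the rank is absent).
#' @export
cf_coefficient <- function(params, k, q) {
  stopifnot(inherits(params, "cf_parameters"))
  bk <- params$B[[paste0("k", k)]]
  if (is.null(bk)) return(0)
  unname(bk[[paste0("q", q)]])
}

#' Crystal-field Hamiltonian from Stevens coefficients
#'
#' `H = sum_{k,q} B_k^q O_k^q`, Hermitian, in cm^-1, traceless up to
#' numerical tolerance (all rank >= 2 operator equivalents are traceless).
#'
#' @param params A `cf_parameters` object (see [point_charge_cf()]), or a
#'   bare list of the same shape.
#' @param system A [spin_system()].
#' @return `(2J+1) x (2J+1)` Hermitian matrix (complex in general).
#' @export
cf_hamiltonian <- function(params, system) {
  stopifnot(inherits(system, "spin_system"))
  B <- if (inherits(params, "cf_parameters")) params$B else params
  H <- matrix(0 + 0i, system$dim, system$dim)
  for (nm in names(B)) {
    k <- as.integer(sub("^k", "", nm))
    bk <- B[[nm]]
    for (q in -k:k) {
      b <- bk[[paste0("q", q)]]
      if (!is.null(b) && b != 0)
        H <- H + b * stevens_operator(system, k, q)
    }
  }
  (H + Conj(t(H))) / 2
}

# Equilibrium magnetization vector M(B) = Tr[mu e^{-beta H(B)}]/Z at field
# B (Gauss, cgs); muJ are the Zeeman matrices per Gauss, so the magnetic
# moment operator is -muJ. Returns erg G^-1 per molecule.
.magnetization <- function(Hcf_erg, muJ, Bfield, kT_erg) {
  H <- Hcf_erg
  for (a in 1:3) if (Bfield[a] != 0) H <- H + Bfield[a] * muJ[[a]]
  e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  w <- exp(-(e$values - min(e$values)) / kT_erg)
  vapply(1:3, function(a) {
    d <- Re(diag(Conj(t(e$vectors)) %*% muJ[[a]] %*% e$vectors))
    -sum(w * d) / sum(w)
  }, numeric(1))
}

#' Van Vleck susceptibility tensor of a crystal-field Hamiltonian
#'
#' Equilibrium (Boltzmann) molar susceptibility
#' `chi_ab = -N_A d2F/dB_a dB_b` at zero field, with
#' `F = -kB T ln Tr exp(-(H + gJ muB B.J)/kB T)`. Two implementations:
#'
#' * `method = "fd"` (default): central finite differences, over field, of
#'   the analytically evaluated equilibrium magnetization `M = -dF/dB`
#'   (so `chi = dM/dB = -d2F/dB2`), with Richardson extrapolation over
#'   steps `delta_B` and `delta_B / 2`. Each
#'   result is cross-checked against the sum-over-states evaluation and an
#'   error is raised if they disagree by more than `check_tol` relative —
#'   a numerical-stability guard.
#' * `method = "sos"`: analytic Van Vleck sum over states, with first-order
#'   (Curie) terms summed inside degenerate blocks (grouped at
#'   `degeneracy_tol` cm^-1, basis-invariant trace form) and second-order
#'   terms across blocks.
#'
#' @param H Hermitian crystal-field matrix in cm^-1 (see
#'   [cf_hamiltonian()]), or `NULL`/zero matrix for the free ion.
#' @param system A [spin_system()].
#' @param T Temperature in K.
#' @param method `"fd"` or `"sos"`.
#' @param delta_B Finite-difference field step in Gauss (default 10 G =
#'   1 mT, comfortably inside the linear-response regime).
#' @param check_tol Relative tolerance for the fd-vs-sos cross-check.
#' @param degeneracy_tol Energy gap (cm^-1) below which states are treated
#'   as degenerate in the sum over states.
#' @return A [chi_tensor()] in cgs molar units (cm^3 mol^-1) at `T`.
#' @export
vanvleck_chi <- function(H, system, T = 298, method = c("fd", "sos"),
                         delta_B = 10, check_tol = 1e-6,
                         degeneracy_tol = 1e-8) {
  stopifnot(inherits(system, "spin_system"))
  method <- match.arg(method)
  if (T <= 0) stop("temperature must be positive")
  if (is.null(H)) H <- matrix(0, system$dim, system$dim)
  if (!all(dim(H) == system$dim)) stop("H has the wrong dimension for this system")
  if (max(abs(H - Conj(t(H)))) > 1e-8 * max(abs(H), 1))
    stop("H is not Hermitian")
  chi_sos <- .chi_sos(H, system, T, degeneracy_tol)
  if (method == "sos")
    return(chi_tensor(chi_sos, units = "cgs_molar_cm3_per_mol", temperature = T))
  chi_fd <- .chi_fd(H, system, T, delta_B)
  scale <- max(abs(chi_sos))
  if (max(abs(chi_fd - chi_sos)) > check_tol * scale)
    stop("numerical-stability error: finite-difference and sum-over-states ",
         "susceptibilities disagree beyond ", check_tol, " relative")
  chi_tensor((chi_fd + t(chi_fd)) / 2, units = "cgs_molar_cm3_per_mol",
             temperature = T)
}

# finite-difference chi_ab = dM_a/dB_b (equivalently -d2F/dBdB, since
# M = -dF/dB is evaluated analytically at each field), with Richardson
# extrapolation over steps h and h/2. Differencing the magnetization
# rather than ln Z avoids the catastrophic cancellation of second
# differences of a quantity dominated by its field-independent part, so
# a 1 mT step is numerically comfortable.
.chi_fd <- function(H, system, T, delta_B) {
  Hcf_erg <- H * .const$hc_erg_cm
  kT <- .const$k_B_cgs * T
  mu <- system$gJ * .const$mu_B_cgs
  Jx <- (system$Jp + system$Jm) / 2
  Jy <- (system$Jp - system$Jm) / (2i)
  muJ <- list(mu * Jx, mu * Jy, mu * system$Jz)  # Zeeman per Gauss
  dM <- function(h) {
    M <- matrix(0, 3, 3)                         # rows alpha, cols beta
    for (b in 1:3) {
      eb <- replace(numeric(3), b, h)
      M[, b] <- (.magnetization(Hcf_erg, muJ, eb, kT) -
                   .magnetization(Hcf_erg, muJ, -eb, kT)) / (2 * h)
    }
    M
  }
  D1 <- dM(delta_B); D2 <- dM(delta_B / 2)
  Dr <- (4 * D2 - D1) / 3            # Richardson: removes the O(h^2) term
  .const$N_A * (Dr + t(Dr)) / 2
}

# analytic Van Vleck sum over states with degenerate-block handling
.chi_sos <- function(H, system, T, degeneracy_tol) {
  kT_cm <- .const$k_B_cm * T
  e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  ev <- e$values                      # cm^-1 (eigen: decreasing order)
  V <- e$vectors
  mu <- system$gJ * .const$mu_B_cgs
  Jx <- (system$Jp + system$Jm) / 2
  Jy <- (system$Jp - system$Jm) / (2i)
  muE <- lapply(list(Jx, Jy, system$Jz),
                function(Jm3) mu * (Conj(t(V)) %*% Jm3 %*% V))
  w <- exp(-(ev - min(ev)) / kT_cm)
  Z <- sum(w)
  n <- length(ev)
  # degenerate-block ids (eigen returns decreasing values)
  blk <- cumsum(c(1L, as.integer(abs(diff(ev)) > degeneracy_tol)))
  same <- outer(blk, blk, "==")
  dE_cm <- outer(ev, ev, function(a, b) b - a)      # E_m - E_n, bra = row
  kT_erg <- .const$k_B_cgs * T
  W <- matrix(w, n, n)                # weight of the bra state (row)
  # stable Boltzmann-difference factor (p_n - p_m)/(E_m - E_n) per state
  # pair: w_n * (1 - exp(-dE/kT)) / dE, summed over both orderings. The
  # expm1 form avoids the catastrophic cancellation that plain weight
  # differences suffer when a Kramers doublet is split only by
  # eigensolver noise just above the grouping tolerance.
  fac <- matrix(0, n, n)
  off <- !same
  Wlo <- pmax(W, t(W))               # weight of the lower-energy state
  fac[off] <- -Wlo[off] * expm1(-abs(dE_cm[off]) / kT_cm) /
    (abs(dE_cm[off]) * .const$hc_erg_cm)
  chi <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    prod_ab <- Re(muE[[a]] * t(muE[[b]]))  # mu_a[n,m] mu_b[m,n]
    curie <- sum(W[same] * prod_ab[same]) / kT_erg
    vv <- sum(fac[off] * prod_ab[off])
    chi[a, b] <- chi[b, a] <- .const$N_A * (curie + vv) / Z
  }
  # subtract beta <mu_a><mu_b> (zero for time-even H, kept for exactness)
  mbar <- vapply(muE, function(M) sum(Re(diag(M)) * w) / Z, numeric(1))
  chi - .const$N_A * outer(mbar, mbar) / kT_erg
}
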