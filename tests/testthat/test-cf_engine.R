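test_that("Stevens operators: exact O_2^0, structure, and the forced null", {
  sys <- dy_system()
  O20 <- stevens_operator(sys, 2, 0)
  m <- seq(15 / 2, -15 / 2)
  expect_equal(diag(O20), 3 * m^2 - (15 / 2) * (17 / 2), tolerance = 1e-12)
  expect_equal(O20[upper.tri(O20)], rep(0, sum(upper.tri(O20))))
  sys1 <- spin_system(J = 1, gJ = 2)
  expect_equal(diag(stevens_operator(sys1, 2, 0)), c(1, -2, 1))
  # k > 2J: flagged, not silently zero
  expect_error(stevens_operator(spin_system(J = 1 / 2, gJ = 2), 2, 0),
               "vanishes identically")
  expect_error(stevens_operator(sys1, 4, 0), "vanishes identically")
  # Hermiticity for all (k, q); q = 0 commutes with Jz
  for (k in c(2, 4, 6)) for (q in -k:k) {
    O <- stevens_operator(sys, k, q)
    expect_equal(O, Conj(t(O)), tolerance = 1e-10)
    if (q == 0)
      expect_equal(O %*% sys$Jz, sys$Jz %*% O, tolerance = 1e-8)
  }
})

test_that("point-charge model: magic-angle null and axial/equatorial
           cancellation", {
  sys <- dy_system()
  th_magic <- acos(1 / sqrt(3))
  # single negative charge: B20 sign follows sign(A2 q (3cos^2 th - 1))
  on_axis <- point_charge_cf(charge_set(-1, matrix(c(0, 0, 2.4), 1, 3)), sys)
  expect_lt(cf_coefficient(on_axis, 2, 0), 0)   # A2 > 0, q < 0, factor > 0
  at_magic <- point_charge_cf(
    charge_set(-1, matrix(2.4 * c(sin(th_magic), 0, cos(th_magic)), 1, 3)),
    sys)
  expect_lt(abs(cf_coefficient(at_magic, 2, 0)), 1e-12)
  # one axial + two equatorial charges of the same magnitude and radius:
  # geometric factors 2 and 2*(-1) cancel
  cancel <- point_charge_cf(
    charge_set(c(-1, -1, -1),
               rbind(c(0, 0, 2.4), c(2.4, 0, 0), c(0, 2.4, 0))), sys)
  expect_lt(abs(cf_coefficient(cancel, 2, 0)), 1e-12)
  expect_error(charge_set(-1, matrix(0, 1, 3)), "origin")
})

test_that("rotating a charge set about z preserves B20; all components
           survive a brute-force re-evaluation", {
  sys <- dy_system()
  set.seed(31)
  pos <- matrix(rnorm(12), 4, 3)
  pos <- pos / sqrt(rowSums(pos^2)) * runif(4, 2, 3)
  q <- runif(4, -1, -0.3)
  p0 <- point_charge_cf(charge_set(q, pos), sys)
  Rz <- rotation_matrix(c(0, 0, 1), 73.2)
  p1 <- point_charge_cf(charge_set(q, pos %*% t(Rz)), sys)
  expect_equal(cf_coefficient(p1, 2, 0), cf_coefficient(p0, 2, 0),
               tolerance = 1e-12)
  expect_equal(cf_coefficient(p1, 4, 0), cf_coefficient(p0, 4, 0),
               tolerance = 1e-12)
  # brute force: B_kq must equal the per-charge tesseral sum computed
  # independently from spherical coordinates (q = 0 components here)
  z20 <- function(v) (3 * (v[3] / sqrt(sum(v^2)))^2 - 1) / 2
  b20_brute <- sum(vapply(1:4, function(i)
    q[i] * z20(pos[i, ]) / sum(pos[i, ]^2)^1.5, numeric(1)))
  ratio <- cf_coefficient(p0, 2, 0) / b20_brute
  # ratio is the fixed A2/s2 scale, identical for every configuration
  pos2 <- pos + 0.3
  p2 <- point_charge_cf(charge_set(q, pos2), sys)
  b20_brute2 <- sum(vapply(1:4, function(i)
    q[i] * z20(pos2[i, ]) / sum(pos2[i, ]^2)^1.5, numeric(1)))
  expect_equal(cf_coefficient(p2, 2, 0) / b20_brute2, ratio,
               tolerance = 1e-10)
})

test_that("CF Hamiltonian is Hermitian, traceless, with closed-form
           diagonal spectrum for a pure B20 term", {
  sys <- dy_system()
  # all-zero parameters: zero matrix, full degeneracy
  H0 <- cf_hamiltonian(list(), sys)
  expect_equal(H0, matrix(0 + 0i, 16, 16))
  # pure negative B20: eigenvalues follow 3 mJ^2 - J(J+1), ground doublet
  # at the largest |mJ| (easy-axis ordering)
  B <- list(k2 = setNames(c(0, 0, -2, 0, 0), paste0("q", -2:2)))
  H <- cf_hamiltonian(B, sys)
  m <- seq(15 / 2, -15 / 2)
  expect_equal(Re(diag(H)), -2 * (3 * m^2 - (15 / 2) * (17 / 2)),
               tolerance = 1e-10)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), -2 * (3 * (15 / 2)^2 - (15 / 2) * (17 / 2)),
               tolerance = 1e-10)
  # random parameters: Hermitian, traceless, real spectrum
  set.seed(37)
  Br <- list(k2 = setNames(rnorm(5), paste0("q", -2:2)),
             k4 = setNames(rnorm(9, sd = 0.1), paste0("q", -4:4)),
             k6 = setNames(rnorm(13, sd = 0.01), paste0("q", -6:6)))
  Hr <- cf_hamiltonian(Br, sys)
  expect_equal(Hr, Conj(t(Hr)), tolerance = 1e-10)
  expect_lt(abs(sum(diag(Hr))), 1e-8 * max(abs(Hr)))
})

test_that("zero-CF susceptibility obeys the Curie law at all tested
           temperatures", {
  sys <- dy_system()
  curie <- function(T) 6.02214076e23 * (4 / 3)^2 * (9.2740100783e-21)^2 *
    (15 / 2) * (17 / 2) / (3 * 1.380649e-16 * T)
  for (T in c(50, 150, 298)) {
    chi <- vanvleck_chi(NULL, sys, T = T, method = "sos")
    expect_equal(chi$matrix, diag(curie(T), 3), tolerance = 1e-8)
  }
  # the finite-difference route reproduces the closed form too
  chi_fd <- vanvleck_chi(NULL, sys, T = 298)
  expect_equal(chi_fd$matrix, diag(curie(298), 3), tolerance = 1e-8)
  expect_equal(curie(298), 0.0475, tolerance = 2e-3)  # ~0.05 cgs molar
  # trace decreases with temperature (Curie-like)
  tr <- vapply(c(50, 150, 298), function(T)
    sum(diag(vanvleck_chi(NULL, sys, T = T, method = "sos")$matrix)),
    numeric(1))
  expect_true(all(diff(tr) < 0))
})

test_that("strong easy-axis CF reaches the Ising-doublet limit", {
  sys <- dy_system()
  B <- list(k2 = setNames(c(0, 0, -20, 0, 0), paste0("q", -2:2)))
  H <- cf_hamiltonian(B, sys)
  chi <- vanvleck_chi(H, sys, T = 50, method = "sos")
  # chi_zz -> N_A (gJ 15/2)^2 muB^2 / (kB T) = 37.5/T cgs molar
  ising <- 6.02214076e23 * ((4 / 3) * (15 / 2))^2 * (9.2740100783e-21)^2 /
    (1.380649e-16 * 50)
  expect_equal(chi$matrix[3, 3], ising, tolerance = 1e-3)
  expect_lt(chi$matrix[1, 1], 0.02 * chi$matrix[3, 3])
  # and at 298 K the quoted 0.1258 value scales as 37.5/T
  expect_equal(ising * 50 / 298, 0.1258, tolerance = 2e-3)
})

test_that("finite-difference and sum-over-states tensors agree to 1e-6
           for random crystal fields at 50 and 298 K", {
  sys <- dy_system()
  set.seed(41)
  for (rep in 1:3) {
    B <- list(k2 = setNames(rnorm(5, sd = 2), paste0("q", -2:2)),
              k4 = setNames(rnorm(9, sd = 0.2), paste0("q", -4:4)),
              k6 = setNames(rnorm(13, sd = 0.02), paste0("q", -6:6)))
    H <- cf_hamiltonian(B, sys)
    for (T in c(50, 298)) {
      sos <- vanvleck_chi(H, sys, T = T, method = "sos")$matrix
      fd <- lnshift:::.chi_fd(H, sys, T, 10)
      expect_lt(max(abs(fd - sos)) / max(abs(sos)), 1e-6)
      # vanvleck_chi(method = "fd") embeds this check and must not error
      expect_no_error(vanvleck_chi(H, sys, T = T))
    }
  }
  # chi is symmetric positive semidefinite
  chi <- vanvleck_chi(cf_hamiltonian(
    list(k2 = setNames(rnorm(5), paste0("q", -2:2))), sys), sys, 298)$matrix
  expect_equal(chi, t(chi))
  expect_true(all(eigen(chi, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
})

test_that("the whole surrogate chain is equivariant: rotated charges give
           the rotated susceptibility tensor", {
  sys <- dy_system()
  set.seed(43)
  pos <- matrix(rnorm(27), 9, 3)
  pos <- pos / sqrt(rowSums(pos^2)) * runif(9, 2, 3)
  q <- runif(9, -1, -0.2)
  chiA <- vanvleck_chi(cf_hamiltonian(point_charge_cf(charge_set(q, pos),
                                                      sys), sys),
                       sys, 298, method = "sos")$matrix
  for (rep in 1:3) {
    R <- random_rotation()
    chiB <- vanvleck_chi(cf_hamiltonian(
      point_charge_cf(charge_set(q, pos %*% t(R)), sys), sys),
      sys, 298, method = "sos")$matrix
    expect_lt(max(abs(chiB - R %*% chiA %*% t(R))) / max(abs(chiA)), 1e-8)
  }
})

test_that("scanning an O-like charge triplet through the magic angle flips
           B20 and the anisotropy class", {
  sys <- dy_system()
  chi_class <- function(theta_deg) {
    th <- theta_deg * pi / 180
    pos <- t(vapply(c(0, 120, 240) * pi / 180, function(ph)
      2.35 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)), numeric(3)))
    cf <- point_charge_cf(charge_set(rep(-0.8, 3), pos), sys)
    # rank-2 axial term only: a C3-symmetric set has no |q| < 3 tesseral
    # components except q = 0
    B <- list(k2 = setNames(c(0, 0, cf_coefficient(cf, 2, 0), 0, 0),
                            paste0("q", -2:2)))
    chi <- vanvleck_chi(cf_hamiltonian(B, sys), sys, 298, method = "sos")
    list(b20 = cf_coefficient(cf, 2, 0),
         class = decompose_chi(chi)$anisotropy_class)
  }
  below <- chi_class(50)
  above <- chi_class(60)
  expect_lt(below$b20, 0)
  expect_gt(above$b20, 0)
  expect_equal(below$class, "easy-axis")
  expect_equal(above$class, "easy-plane")
  near <- chi_class(acos(1 / sqrt(3)) * 180 / pi)
  expect_lt(abs(near$b20), 1e-10)
})
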