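test_that("unit conversion matches the cgs-molar/SI-molecular bridge", {
  chi <- chi_tensor(diag(0.05, 3), units = "cgs_molar_cm3_per_mol")
  si <- convert_chi_units(chi, "si_molecular_m3")
  # 0.05 * 4*pi*1e-6 / N_A
  expect_equal(si$matrix[1, 1], 0.05 * 4 * pi * 1e-6 / 6.02214076e23,
               tolerance = 1e-12)
  expect_equal(si$matrix[1, 1], 1.043e-30, tolerance = 1e-3)
  back <- convert_chi_units(si, "cgs_molar_cm3_per_mol")
  expect_equal(back$matrix, chi$matrix, tolerance = 1e-12)
  expect_equal(back$temperature, 298)
  zero <- convert_chi_units(chi_tensor(matrix(0, 3, 3)), "si_molecular_m3")
  expect_equal(zero$matrix, matrix(0, 3, 3))
  expect_error(chi_tensor(matrix(rnorm(9), 3, 3)), "not symmetric")
})

test_that("tensor decomposition recovers axiality, rhombicity and class", {
  c0 <- 0.03
  easy_axis <- decompose_chi(chi_tensor(diag(c(c0, c0, 2 * c0))))
  expect_equal(easy_axis$iso, 4 * c0 / 3)
  expect_equal(easy_axis$dchi_ax, c0)
  expect_equal(easy_axis$dchi_rh, 0)
  expect_equal(easy_axis$anisotropy_class, "easy-axis")
  easy_plane <- decompose_chi(chi_tensor(diag(c(2 * c0, 2 * c0, c0))))
  expect_equal(easy_plane$dchi_ax, -c0)
  expect_equal(easy_plane$anisotropy_class, "easy-plane")
  expect_equal(unname(abs(easy_plane$axes[, "z"])), c(0, 0, 1))
})

test_that("decomposition is rotation invariant and reconstructs the input", {
  set.seed(7)
  for (rep in 1:5) {
    m <- crossprod(matrix(rnorm(9), 3, 3)) / 20
    chi <- chi_tensor(m)
    d0 <- decompose_chi(chi)
    # reconstruction from iso + eigensystem
    rec <- d0$axes %*% diag(d0$eigenvalues) %*% t(d0$axes)
    expect_equal(rec, m, tolerance = 1e-10)
    expect_equal(det(d0$axes), 1, tolerance = 1e-10)
    expect_lte(abs(d0$dchi_rh), (2 / 3) * abs(d0$dchi_ax) + 1e-12)
    R <- random_rotation()
    d1 <- decompose_chi(chi_tensor(R %*% m %*% t(R)))
    expect_equal(d1$iso, d0$iso, tolerance = 1e-10)
    expect_equal(d1$dchi_ax, d0$dchi_ax, tolerance = 1e-10)
    expect_equal(d1$dchi_rh, d0$dchi_rh, tolerance = 1e-10)
    expect_equal(d1$anisotropy_class, d0$anisotropy_class)
  }
})

test_that("full-tensor PCS matches closed forms on and off axis", {
  dax <- 1e-32
  chi <- chi_tensor(diag(c(-dax / 3, -dax / 3, 2 * dax / 3)),
                    units = "si_molecular_m3")
  # on-axis closed form: dchi_ax / (6 pi r^3) * 1e6
  r <- 4
  expect_equal(pcs_full_tensor(chi, c(0, 0, 0), c(0, 0, r)),
               dax / (6 * pi * (r * 1e-10)^3) * 1e6, tolerance = 1e-10)
  expect_equal(pcs_full_tensor(chi, c(0, 0, 0), c(0, 0, r)), 8.29,
               tolerance = 1e-3)
  # magic-angle null for any radius and azimuth
  th <- acos(1 / sqrt(3))
  for (phi in c(0, 1.1, 4)) {
    nuc <- 5 * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    expect_lt(abs(pcs_full_tensor(chi, c(0, 0, 0), nuc)), 1e-10)
  }
  expect_error(pcs_full_tensor(chi, c(0, 0, 0), c(0.3, 0, 0)),
               "point-dipole")
})

test_that("coordinate-free and PAS forms agree for random tensors", {
  set.seed(17)
  for (rep in 1:20) {
    m <- (crossprod(matrix(rnorm(9), 3, 3)) - diag(1.5, 3)) * 1e-32
    chi <- chi_tensor(m, units = "si_molecular_m3")
    nuc <- rnorm(3); nuc <- nuc / sqrt(sum(nuc^2)) * runif(1, 3, 8)
    # pcs_full_tensor runs both code paths and errors if they disagree
    d <- pcs_full_tensor(chi, c(0, 0, 0), nuc)
    expect_true(is.finite(d))
    # explicit independent recomputation of the coordinate-free form
    rm <- nuc * 1e-10; rr <- sqrt(sum(rm^2))
    tracefree <- m - diag(sum(diag(m)) / 3, 3)
    expect_equal(d, 1e6 * drop(rm %*% tracefree %*% rm) / (4 * pi * rr^5),
                 tolerance = 1e-12)
  }
})

test_that("PCS is linear in the tensor, null for isotropic chi, and
           invariant under joint rotation", {
  set.seed(19)
  m <- (crossprod(matrix(rnorm(9), 3, 3)) - diag(1, 3)) * 1e-32
  nuc <- c(2.4, -3.1, 1.7)
  d <- pcs_full_tensor(chi_tensor(m, units = "si_molecular_m3"),
                       c(0, 0, 0), nuc)
  expect_equal(pcs_full_tensor(chi_tensor(2 * m, units = "si_molecular_m3"),
                               c(0, 0, 0), nuc), 2 * d, tolerance = 1e-10)
  expect_equal(pcs_full_tensor(chi_tensor(diag(3e-32, 3),
                                          units = "si_molecular_m3"),
                               c(0, 0, 0), nuc), 0)
  for (rep in 1:3) {
    R <- random_rotation()
    dr <- pcs_full_tensor(chi_tensor(R %*% m %*% t(R),
                                     units = "si_molecular_m3"),
                          c(0, 0, 0), drop(R %*% nuc))
    expect_equal(dr, d, tolerance = 1e-10 * abs(d))
  }
})

test_that("sphere-averaged PCS vanishes within Monte-Carlo error", {
  set.seed(23)
  m <- (crossprod(matrix(rnorm(9), 3, 3)) - diag(1, 3)) * 1e-32
  chi <- chi_tensor(m, units = "si_molecular_m3")
  n <- 2e4
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * 5
  d <- vapply(seq_len(n), function(i)
    pcs_full_tensor(chi, c(0, 0, 0), u[i, ]), numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(n))
})

test_that("Bleaney model: angular nulls, ratios and r^-3 scaling", {
  p <- bleaney_params(B20 = -1, ion = "Dy")
  expect_equal(p$C_J, -100)
  d0 <- pcs_bleaney(p, 0, 4)
  d90 <- pcs_bleaney(p, 90, 4)
  expect_equal(d0 / d90, -2, tolerance = 1e-12)
  expect_equal(pcs_bleaney(p, acos(1 / sqrt(3)) * 180 / pi, 4), 0,
               tolerance = 1e-12)
  expect_equal(pcs_bleaney(p, 30, 8), pcs_bleaney(p, 30, 4) / 8,
               tolerance = 1e-12)
  # 1/T^2 temperature dependence
  p350 <- bleaney_params(B20 = -1, ion = "Dy", T = 350)
  expect_equal(pcs_bleaney(p350, 30, 4) / pcs_bleaney(p, 30, 4),
               (298 / 350)^2, tolerance = 1e-12)
  expect_error(pcs_bleaney(p, 10, 0), "positive")
})

test_that("axial full-tensor PCS has the Bleaney angular profile", {
  dax <- 2e-32
  chi <- chi_tensor(diag(c(-dax / 3, -dax / 3, 2 * dax / 3)),
                    units = "si_molecular_m3")
  th <- seq(5, 175, by = 5)
  full <- vapply(th, function(t)
    pcs_full_tensor(chi, c(0, 0, 0),
                    5 * c(sin(t * pi / 180), 0, cos(t * pi / 180))),
    numeric(1))
  bl <- vapply(th, function(t)
    pcs_bleaney(bleaney_params(B20 = 1, C_J = 1), t, 5), numeric(1))
  expect_equal(cor(full, bl), 1, tolerance = 1e-10)
  expect_gt(coef(lm(full ~ bl))[2], 0)   # positive scale factor
})

test_that("trajectory shifts compose per-nucleus calls; triplets average
           correctly", {
  tpl <- build_template()
  traj <- trajectory(tpl$frame$elements, tpl$frame$coords)
  dax <- 1e-32 * 6.02214076e23 / (4 * pi * 1e-6)   # in cgs-molar scale
  chi <- chi_tensor(diag(c(-dax / 3, -dax / 3, 2 * dax / 3)))
  ss <- pcs_trajectory(traj, list(chi), tpl$donors)
  # axial tensor aligned with the symmetry axis: triplet members identical
  for (h in c("H1", "H2", "H3")) {
    vals <- ss$per_atom[1, paste0(h, "_", 1:3)]
    expect_lt(diff(range(vals)), 1e-10)
    expect_equal(unname(ss$triplet[1, h]), unname(mean(vals)))
    # and equals a direct pcs_full_tensor call
    i <- tpl$donors$h_triplets[[h]][1] + 1L
    expect_equal(unname(ss$triplet[1, h]),
                 pcs_full_tensor(chi, tpl$frame$coords[1, ],
                                 tpl$frame$coords[i, ]),
                 tolerance = 1e-10)
  }
  # constant trajectory + constant tensor: time average = single frame
  traj3 <- trajectory(tpl$frame$elements,
                      array(rep(tpl$frame$coords, 3), c(19, 3, 3)))
  ss3 <- pcs_trajectory(traj3, list(chi, chi, chi), tpl$donors)
  expect_equal(ss3$time_average, setNames(ss$triplet[1, ], c("H1", "H2", "H3")))
  expect_error(pcs_trajectory(traj3, list(chi), tpl$donors), "one tensor per")
})

test_that("chi series round trip through JSON and CSV", {
  set.seed(29)
  chis <- lapply(1:3, function(i) {
    ct <- chi_tensor(crossprod(matrix(rnorm(9), 3, 3)) / 30)
    attr(ct, "frame") <- (i - 1L) * 30L
    ct
  })
  p <- withr::local_tempfile(fileext = ".json")
  write_chi_series(chis, p)
  back <- read_chi_series(p)
  for (i in 1:3) {
    expect_equal(back[[i]]$matrix, chis[[i]]$matrix, tolerance = 1e-12)
    expect_equal(attr(back[[i]], "frame"), (i - 1) * 30)
  }
  # CSV with the six unique components
  pcsv <- withr::local_tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(seq_along(chis), function(i) {
    m <- chis[[i]]$matrix
    data.frame(frame = (i - 1) * 30, T_K = 298,
               units = "cgs_molar_cm3_per_mol",
               xx = m[1, 1], yy = m[2, 2], zz = m[3, 3],
               xy = m[1, 2], xz = m[1, 3], yz = m[2, 3])
  }))
  write.csv(df, pcsv, row.names = FALSE)
  back2 <- read_chi_series(pcsv)
  expect_equal(back2[[2]]$matrix, chis[[2]]$matrix, tolerance = 1e-12)
})
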