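# Shared fixtures and small independent oracles for the test suite.

# random proper rotation, deterministic under the caller's seed
random_rotation <- function() {
  rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 360))
}

# tiny two-frame, three-atom XYZ text fixture
write_tiny_xyz <- function(path, times = NULL) {
  lines <- character()
  for (k in 1:2) {
    cm <- if (is.null(times)) sprintf("frame %d", k - 1L)
          else sprintf("frame %d time = %.1f", k - 1L, times[k])
    lines <- c(lines, "3", cm,
               sprintf("Gd %.6f %.6f %.6f", 0.1 * k, 0, 0),
               sprintf("O  %.6f %.6f %.6f", 2.3, 0.2 * k, 0),
               sprintf("N  %.6f %.6f %.6f", -1.1, 2.2, 0.3 * k))
  }
  writeLines(lines, path)
  path
}

# apply a rigid motion to every frame of a trajectory
transform_trajectory <- function(traj, R, t = c(0, 0, 0)) {
  for (k in seq_len(n_frames(traj)))
    traj$coords[, , k] <- sweep(traj$coords[, , k] %*% t(R), 2, t, `+`)
  traj
}

# brute-force pseudo-C3 axis: independent of the package's geometry path
# (explicit cross products and explicit averaging)
brute_force_axis <- function(xyz, donors) {
  tri <- list(donors$o_donors, donors$n_ax, donors$n_eq) # 0-based
  ref <- colMeans(xyz[donors$n_ax + 1L, , drop = FALSE]) -
    colMeans(xyz[donors$o_donors + 1L, , drop = FALSE])
  nrm <- sapply(tri, function(ix) {
    p <- xyz[ix + 1L, , drop = FALSE]
    a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    n <- n / sqrt(sum(n^2))
    if (sum(n * ref) < 0) -n else n
  })
  ax <- rowMeans(nrm)
  ax / sqrt(sum(ax^2))
}

# standard Dy(III) ground multiplet used throughout
dy_system <- function() spin_system(J = 15 / 2, gJ = 4 / 3)

# default-charge set placed on the donor atoms of a single frame
donor_charge_set <- function(xyz, donors,
                             q = c(O = -0.8, N_ax = -0.49, N_eq = -0.40)) {
  rows <- c(donors$o_donors, donors$n_ax, donors$n_eq) + 1L
  pos <- sweep(xyz[rows, , drop = FALSE], 2, xyz[donors$metal + 1L, ])
  charge_set(rep(q[c("O", "N_ax", "N_eq")], each = 3), pos)
}
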