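test_that("network construction applies the strict cutoff and reports components", {
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 7, 0))
  # cutoff below every pairwise distance: no springs, all singletons
  n0 <- build_network(pos, 2)
  expect_identical(nrow(n0$edges), 0L)
  expect_identical(n0$n_components, 3L)
  # two atoms within range: one spring with the right rest length
  n1 <- build_network(pos[1:2, ], 10)
  expect_identical(nrow(n1$edges), 1L)
  expect_equal(n1$rest_lengths, 5)
  # pairs at exactly the cutoff are not linked
  expect_identical(nrow(build_network(pos[1:2, ], 5)$edges), 0L)
  expect_identical(nrow(build_network(pos[1:2, ], 5 + 1e-9)$edges), 1L)
  expect_error(build_network(pos, -1), "cutoff")
})

test_that("potential energy is zero at reference, quadratic in stretch, rigid-invariant", {
  set.seed(21)
  pos <- connected_cloud(12, spacing = 4, seed = 21)
  net <- build_network(pos, 7)
  expect_equal(potential_energy(net, pos), 0)
  # single spring stretched by delta stores C/2 delta^2
  two <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)), 5, spring_constant = 2.5)
  delta <- 0.4
  expect_equal(potential_energy(two, rbind(c(0, 0, 0), c(3 + delta, 0, 0))),
               2.5 / 2 * delta^2)
  # random rigid transforms leave the energy of any conformation unchanged
  disp <- pos + matrix(rnorm(length(pos), sd = 0.3), nrow(pos), 3)
  e0 <- potential_energy(net, disp)
  for (s in 1:5) {
    set.seed(s)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    rot <- diag(3) + sin(th) * k + (1 - cos(th)) * k %*% k
    moved <- disp %*% t(rot) + matrix(rnorm(3, sd = 10), nrow(pos), 3,
                                      byrow = TRUE)
    expect_equal(potential_energy(net, moved), e0, tolerance = 1e-9)
  }
})

test_that("the analytic Hessian matches finite differences of the potential", {
  for (s in 1:3) {
    set.seed(30 + s)
    pos <- matrix(rnorm(15, sd = 3), 5, 3)
    net <- build_network(pos, 6)
    if (nrow(net$edges) == 0) next
    h <- build_hessian(net, sparse = FALSE)
    expect_equal(h, t(h))
    expect_equal(h, brute_force_hessian(net))
    # every row sums to zero: uniform translation costs nothing
    expect_lt(max(abs(rowSums(h))), 1e-12)
    expect_gt(min(eigen(h, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    # central finite differences of the energy
    x0 <- as.numeric(t(pos))
    en <- function(x) potential_energy(net, matrix(x, ncol = 3, byrow = TRUE))
    hh <- 1e-4
    fd <- matrix(0, 15, 15)
    for (i in 1:15) for (j in i:15) {
      ei <- ej <- numeric(15); ei[i] <- hh; ej[j] <- hh
      fd[i, j] <- fd[j, i] <-
        (en(x0 + ei + ej) - en(x0 + ei - ej) -
           en(x0 - ei + ej) + en(x0 - ei - ej)) / (4 * hh^2)
    }
    expect_equal(h, fd, tolerance = 1e-5)
  }
})

test_that("two bonded atoms have one nonzero eigenvalue of exactly 2C", {
  net <- build_network(rbind(c(0, 0, 0), c(5, 0, 0)), 10)
  modes <- compute_modes(net, 6, method = "dense")
  expect_equal(modes$eigenvalues[6], 2)
  expect_equal(modes$eigenvalues[1:5], rep(0, 5))
  expect_identical(count_rigid_modes(modes), 5L)
  # the stretching mode displaces the atoms along the bond, oppositely
  u <- matrix(modes$vectors[, 6], ncol = 3, byrow = TRUE)
  expect_equal(abs(u[, 1]), rep(sqrt(0.5), 2), tolerance = 1e-10)
  expect_lt(max(abs(u[, 2:3])), 1e-10)
})

test_that("a connected network has 6 rigid modes and flexible modes from index 7", {
  pos <- connected_cloud(50, spacing = 4, seed = 33)
  net <- build_network(pos, 8)
  expect_identical(net$n_components, 1L)
  modes <- compute_modes(net, 20)
  expect_identical(ncol(modes$vectors), 20L)
  expect_identical(modes$n_rigid, 6L)
  expect_lt(max(modes$eigenvalues[1:6]), 1e-8 * modes$eigenvalues[7])
  expect_gt(modes$eigenvalues[7], 0)
  # orthonormal within 1e-8
  gram <- crossprod(modes$vectors)
  expect_lt(max(abs(gram - diag(20))), 1e-8)
  # ascending eigenvalues, non-negative within tolerance
  expect_true(all(diff(modes$eigenvalues) >= -1e-12))
  expect_gt(min(modes$eigenvalues), -1e-8)
  # the 6 near-zero modes span the analytic translation/rotation space
  b <- rigid_body_basis(pos)
  sv <- svd(crossprod(b, modes$vectors[, 1:6]))$d
  expect_true(all(acos(pmin(sv, 1)) < 1e-3))
})

test_that("sparse shift-invert solver agrees with dense diagonalization", {
  pos <- connected_cloud(25, spacing = 4, seed = 34)
  net <- build_network(pos, 8)
  md <- compute_modes(net, 12, method = "dense")
  ms <- compute_modes(net, 12, method = "sparse")
  expect_equal(md$eigenvalues, ms$eigenvalues, tolerance = 1e-8)
  expect_identical(md$n_rigid, ms$n_rigid)
  # compare subspaces (individual vectors rotate inside degenerate blocks)
  sv <- svd(crossprod(md$vectors, ms$vectors))$d
  expect_gt(min(sv), 1 - 1e-6)
})

test_that("the ENM Hessian matches bio3d's ANM construction", {
  skip_if_not_installed("bio3d")
  pos <- connected_cloud(15, spacing = 4, seed = 35)
  cutoff <- 8
  net <- build_network(pos, cutoff)
  h <- build_hessian(net, sparse = FALSE)
  xyz <- as.numeric(t(pos))
  pfc <- function(r, ...) ifelse(r < cutoff, 1, 0)
  h_bio3d <- bio3d::build.hessian(xyz, pfc.fun = pfc)
  expect_equal(h, unname(as.matrix(h_bio3d)), tolerance = 1e-10)
})

test_that("disconnected networks warn and expose 12 near-zero modes", {
  a <- connected_cloud(10, spacing = 4, seed = 36)
  b <- sweep(connected_cloud(10, spacing = 4, seed = 37), 2, c(100, 0, 0), "+")
  net <- build_network(rbind(a, b), 8)
  expect_identical(net$n_components, 2L)
  expect_warning(modes <- compute_modes(net, 20), "components")
  # independent oracle: dense eigenvalues of the brute-force Hessian
  ev <- eigen(brute_force_hessian(net), symmetric = TRUE,
              only.values = TRUE)$values
  expect_identical(sum(ev < 1e-8), 12L)
  expect_identical(count_rigid_modes(modes), 12L)
  expect_identical(count_rigid_modes(modes, tol = Inf), 20L)
})
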