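test_that("rendering matches an untruncated per-voxel oracle and is linear", {
  set.seed(8)
  dims <- c(16L, 16L, 16L)
  origin <- c(-8, -8, -8)
  m <- random_model(5, box = 10, sigma = 1.5, seed = 8)
  vol <- render_model(m, dims, 1, origin)
  # brute-force oracle: full Gaussian sum, no truncation
  gx <- origin[1] + 0:15; gy <- origin[2] + 0:15; gz <- origin[3] + 0:15
  ref <- array(0, dims)
  for (a in seq_len(5)) {
    dx2 <- outer(outer((gx - m$positions[a, 1])^2,
                       (gy - m$positions[a, 2])^2, "+"),
                 (gz - m$positions[a, 3])^2, "+")
    ref <- ref + m$weights[a] * exp(-dx2 / (2 * m$sigma^2))
  }
  expect_lt(max(abs(vol$data - ref)) / max(ref), 1e-3)
  # a weight-w atom centred on a voxel renders that voxel to exactly w
  m1 <- pseudo_atom_model(matrix(c(0, 0, 0), 1), 3.5, sigma = 2)
  v1 <- render_model(m1, dims, 1, origin)
  expect_equal(v1$data[9, 9, 9], 3.5)
  # two far-apart atoms render to the sum of individual renders
  pa <- pseudo_atom_model(matrix(c(-6, 0, 0), 1), 1, sigma = 1)
  pb <- pseudo_atom_model(matrix(c(6, 0, 0), 1), 2, sigma = 1)
  pab <- pseudo_atom_model(rbind(c(-6, 0, 0), c(6, 0, 0)), c(1, 2), sigma = 1)
  expect_equal(render_model(pab, dims, 1, origin)$data,
               render_model(pa, dims, 1, origin)$data +
                 render_model(pb, dims, 1, origin)$data)
})

test_that("rendered mass matches the analytic Gaussian integral", {
  m <- pseudo_atom_model(matrix(c(0.3, -0.2, 0.1), 1), 4, sigma = 2)
  v <- render_model(m, c(32, 32, 32), 1, c(-16, -16, -16))
  analytic <- 4 * (2 * pi)^1.5 * 2^3   # w (2 pi)^{3/2} sigma^3 / voxel^3
  # ~0.1% of the mass lies beyond the 4-sigma truncation radius
  expect_equal(sum(v$data), analytic, tolerance = 2e-3)
})

test_that("approximation error is 0 for an exact model and ~1 for an absent one", {
  m <- random_model(4, box = 8, sigma = 2, seed = 9)
  vol <- render_model(m, c(24, 24, 24), 1, c(-12, -12, -12))
  mask <- binary_mask(array(1, dim(vol$data)), 1, vol$origin)
  expect_equal(approximation_error(vol, m, mask), 0)
  # a model rendering nothing inside the grid leaves the full density
  far <- pseudo_atom_model(matrix(c(500, 500, 500), 1), 1, sigma = 2)
  expect_equal(approximation_error(vol, far, mask), 1)
  zero <- density_volume(array(0, c(4, 4, 4)))
  zmask <- binary_mask(array(1, c(4, 4, 4)))
  expect_error(approximation_error(zero, far, zmask), "all zero")
})

test_that("fitting recovers a single Gaussian with 1-2 atoms below 1% error", {
  truth <- pseudo_atom_model(matrix(c(0, 0, 0), 1), 5, sigma = 2)
  vol <- render_model(truth, c(24, 24, 24), 1, c(-12, -12, -12))
  mask <- binary_mask(array(as.numeric(vol$data > 1e-4), dim(vol$data)), 1,
                      vol$origin)
  fit <- fit_pseudo_atoms(vol, mask,
                          fit_config(sigma_voxels = 2, target_error = 0.01,
                                     initial_atoms = 2, seed = 1))
  expect_lte(nrow(fit$positions), 2)
  expect_lt(fit$achieved_error, 0.01)
  expect_lt(sqrt(sum((fit$positions[1, ])^2)), 0.5)
  expect_equal(sum(fit$weights), 5, tolerance = 0.05)
})

test_that("fits are reproducible, monotone in error, and honour the contract", {
  set.seed(10)
  truth <- random_model(12, box = 14, sigma = 2, seed = 10)
  vol <- render_model(truth, c(24, 24, 24), 1.5, c(-18, -18, -18))
  mask <- binary_mask(array(as.numeric(vol$data > 1e-3 * max(vol$data)),
                            dim(vol$data)), 1.5, vol$origin)
  cfg <- fit_config(sigma_voxels = 4 / 3, target_error = 0.05, seed = 7,
                    initial_atoms = 10)
  f1 <- fit_pseudo_atoms(vol, mask, cfg)
  f2 <- fit_pseudo_atoms(vol, mask, cfg)
  expect_identical(f1$positions, f2$positions)
  expect_identical(f1$weights, f2$weights)
  # error history is non-increasing across outer iterations
  expect_true(all(diff(f1$history) <= 1e-12))
  # termination contract: below the cap and no warning => target reached
  expect_lte(f1$achieved_error, cfg$target_error)
  expect_true(all(f1$weights > 0))
  # achieved_error is recorded consistently with a fresh evaluation
  expect_equal(approximation_error(vol, f1, mask), f1$achieved_error,
               tolerance = 1e-10)
})

test_that("an unreachable target stops growth exactly at the atom cap", {
  set.seed(12)
  noise <- add_noise(density_volume(array(0, c(16, 16, 16)), 1.5), 1, seed = 12)
  mask <- binary_mask(array(as.numeric(noise$data > 0), dim(noise$data)), 1.5,
                      noise$origin)
  cap <- 60L
  expect_warning(
    fit <- fit_pseudo_atoms(noise, mask,
                            fit_config(sigma_voxels = 1, target_error = 0,
                                       max_atoms = cap, initial_atoms = 20,
                                       seed = 2)),
    "cap")
  expect_identical(nrow(fit$positions), as.integer(cap))
  expect_gt(fit$achieved_error, 0)
})

test_that("nearest-neighbour distances and their histogram behave on known geometries", {
  two <- pseudo_atom_model(rbind(c(0, 0, 0), c(5, 0, 0)), c(1, 1), 1)
  h2 <- nn_distance_histogram(two, n_bins = 4)
  expect_equal(sum(h2$counts), 2)
  tri <- pseudo_atom_model(rbind(c(0, 0, 0), c(3, 0, 0),
                                 c(1.5, 3 * sqrt(3) / 2, 0)), rep(1, 3), 1)
  h3 <- nn_distance_histogram(tri, n_bins = 5)
  expect_equal(sum(h3$counts), 3)
  expect_true(all(diff(h3$bin_edges) > 0))
  rm200 <- random_model(200, box = 50, seed = 13)
  h200 <- nn_distance_histogram(rm200, n_bins = 25)
  expect_equal(sum(h200$counts), 200)
  expect_error(nn_distance_histogram(pseudo_atom_model(matrix(0, 1, 3), 1, 1)),
               "at least 2")
  # two-column text export round-trips the counts
  p <- tempfile(fileext = ".tsv")
  write_distance_histogram(h200, p)
  tab <- read.table(p, header = TRUE)
  expect_equal(sum(tab$count), 200)
})

test_that("suggested cutoffs cover >= 95% of NN distances and connect the network", {
  # uniformly spaced collinear atoms: cutoff must reach the 5 A spacing
  line <- pseudo_atom_model(cbind(seq(0, 45, by = 5), 0, 0), rep(1, 10), 1)
  expect_gte(suggest_cutoff(line), 5)
  # fraction = 1 gives (just above) the maximum NN distance
  rm <- random_model(50, box = 30, seed = 14)
  d <- sort(volnma:::cpp_nn_distances(rm$positions))
  expect_equal(suggest_cutoff(rm, fraction = 1), max(d),
               tolerance = max(d) * 1e-5)
  # counting oracle across seeds: strict-below share >= 0.95, connected
  for (s in 1:5) {
    m <- random_model(200, box = 60, seed = 100 + s)
    cut <- suppressMessages(suggest_cutoff(m, 0.95))
    dd <- volnma:::cpp_nn_distances(m$positions)
    expect_gte(mean(dd < cut), 0.95)
    expect_identical(build_network(m, cut)$n_components, 1L)
  }
})
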