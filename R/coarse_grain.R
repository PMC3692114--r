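#' Construct a pseudo-atom model
#'
#' A pseudo-atom model approximates a density volume by a weighted sum of
#' isotropic 3D Gaussians of shared standard deviation `sigma`, each of
#' maximum amplitude 1 scaled by its weight:
#' \deqn{\hat V(r) = \sum_i w_i \exp(-|r - r_i|^2 / 2\sigma^2).}
#'
#' @param positions N x 3 numeric matrix of Gaussian centres, Angstrom.
#' @param weights length-N positive weights, density units.
#' @param sigma shared Gaussian standard deviation, Angstrom (> 0).
#' @param achieved_error relative L1 approximation error recorded by the fit.
#' @param seed integer seed the fit was run with.
#' @param source provenance string.
#' @return An object of class `pseudo_atom_model`.
#' @export
pseudo_atom_model <- function(positions, weights, sigma,
                              achieved_error = NA_real_, seed = NA_integer_,
                              source = "constructed") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("`positions` must be an N x 3 matrix")
  n <- nrow(positions)
  if (n < 1L) stop("a pseudo-atom model needs at least one atom")
  if (n > 9999L) stop("pseudo-atom count exceeds the 9999 cap")
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("`weights` length must match atom count")
  if (!all(is.finite(positions)) || !all(is.finite(weights)))
    stop("positions and weights must be finite")
  if (any(weights <= 0)) stop("all weights must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  structure(
    list(positions = unname(positions), weights = weights,
         sigma = as.numeric(sigma), achieved_error = as.numeric(achieved_error),
         seed = seed, source = source),
    class = "pseudo_atom_model"
  )
}

#' @export
print.pseudo_atom_model <- function(x, ...) {
  cat(sprintf("<pseudo_atom_model> %d atoms, sigma %.3g A\n",
              nrow(x$positions), x$sigma))
  if (is.finite(x$achieved_error))
    cat(sprintf("  achieved error %.4f\n", x$achieved_error))
  cat(sprintf("  weights [%.3g, %.3g]; source: %s\n",
              min(x$weights), max(x$weights), x$source))
  invisible(x)
}

#' Fit configuration for volume-to-pseudo-atoms conversion
#'
#' @param sigma_voxels Gaussian standard deviation in voxel units. The rule of
#'   thumb is a value similar to the voxel size (1); useful values run from 1
#'   (smaller pseudo-atoms) to 5 (larger ones).
#' @param target_error target relative approximation error (fraction, in
#'   (0, 1) -- or exactly 0 to force growth to the atom cap).
#' @param max_atoms hard cap on the number of pseudo-atoms (<= 9999, the cap
#'   forwarded to the normal-mode step).
#' @param initial_atoms number of density-sampled seed atoms.
#' @param max_outer_iters maximum number of growth iterations.
#' @param convergence_tol relative error improvement below which the inner
#'   refinement of an iteration stops.
#' @param seed integer seed for the stochastic initialization (mandatory so
#'   fits are reproducible).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(sigma_voxels = 1, target_error = 0.06,
                       max_atoms = 9999L, initial_atoms = 100L,
                       max_outer_iters = 200L, convergence_tol = 1e-3,
                       seed = 0L) {
  if (!is.finite(sigma_voxels) || sigma_voxels <= 0)
    stop("`sigma_voxels` must be > 0")
  if (!is.finite(target_error) || target_error < 0 || target_error >= 1)
    stop("`target_error` must lie in [0, 1)")
  max_atoms <- as.integer(max_atoms)
  if (is.na(max_atoms) || max_atoms < 1L || max_atoms > 9999L)
    stop("`max_atoms` must lie in [1, 9999]")
  initial_atoms <- as.integer(initial_atoms)
  if (is.na(initial_atoms) || initial_atoms < 1L)
    stop("`initial_atoms` must be >= 1")
  structure(
    list(sigma_voxels = sigma_voxels, target_error = target_error,
         max_atoms = max_atoms, initial_atoms = min(initial_atoms, max_atoms),
         max_outer_iters = as.integer(max_outer_iters),
         convergence_tol = convergence_tol, seed = as.integer(seed)),
    class = "fit_config"
  )
}

#' Render a pseudo-atom model onto a grid
#'
#' Evaluates the weighted Gaussian sum on every voxel. Gaussians are truncated
#' at `trunc_sigmas` standard deviations (default 4, where the amplitude has
#' fallen below 4e-4).
#'
#' @param model a [pseudo_atom_model()].
#' @param dims grid dimensions (nx, ny, nz).
#' @param voxel_size Angstrom per voxel.
#' @param origin grid origin, Angstrom.
#' @param trunc_sigmas truncation radius in units of sigma.
#' @return A [density_volume()].
#' @export
render_model <- function(model, dims, voxel_size = 1, origin = c(0, 0, 0),
                         trunc_sigmas = 4) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  vals <- cpp_render(model$positions, model$weights, model$sigma, dims,
                     voxel_size, as.numeric(origin), trunc_sigmas)
  density_volume(array(vals, dim = dims), voxel_size, origin)
}

# 26-neighbourhood local maxima of a 3D array (borders padded with -Inf)
.local_maxima <- function(a) {
  d <- dim(a)
  p <- array(-Inf, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  out <- array(TRUE, d)
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & (a >= p[ix + dx, iy + dy, iz + dz])
  }
  out
}

.masked_l1_error <- function(v, vhat, maskdata) {
  denom <- sum(abs(v[maskdata > 0]))
  if (denom == 0) stop("masked volume is all zero; no error is defined")
  sum(abs((v - vhat)[maskdata > 0])) / denom
}

#' Relative L1 approximation error of a model over a mask
#'
#' Returns `sum(|V - Vhat|) / sum(|V|)` over the voxels inside the mask, where
#' `Vhat` is the model rendered on the volume's grid. Zero if and only if the
#' rendered model matches the volume exactly on the mask.
#'
#' @param vol a [density_volume()] (the reference).
#' @param model a [pseudo_atom_model()].
#' @param mask a [binary_mask()]; defaults to all voxels.
#' @return The error fraction.
#' @export
approximation_error <- function(vol, model, mask = NULL) {
  stopifnot(inherits(vol, "density_volume"))
  maskdata <- if (is.null(mask)) array(1, dim(vol$data)) else mask$data
  if (!all(dim(maskdata) == dim(vol$data))) stop("mask dims must match volume")
  if (sum(maskdata) == 0) stop("mask is empty")
  vhat <- render_model(model, dim(vol$data), vol$voxel_size, vol$origin)$data
  .masked_l1_error(vol$data, vhat, maskdata)
}

#' Convert a masked volume into pseudo-atoms at a target error
#'
#' Adaptively grows a weighted Gaussian model of the masked density: seed
#' atoms are drawn at voxel centres with probability proportional to density,
#' each growth iteration alternates multiplicative non-negative weight updates
#' with damped Gauss-Newton position refinement, and new atoms are planted at
#' the voxels of largest positive residual until the relative L1 error reaches
#' `target_error`, the atom cap is hit, or the iteration budget is spent. An
#' iteration that fails to improve the error is rolled back, so the recorded
#' error history is non-increasing.
#'
#' @param vol a [density_volume()].
#' @param mask a [binary_mask()] selecting the region to approximate (e.g.
#'   from [apply_threshold_mask()]); `NULL` means all voxels.
#' @param config a [fit_config()].
#' @param verbose print per-iteration progress (atom count and error).
#' @return A [pseudo_atom_model()] with `achieved_error` set and an `history`
#'   attribute (`model$history`) holding the error after each accepted
#'   iteration.
#' @export
fit_pseudo_atoms <- function(vol, mask = NULL, config = fit_config(),
                             verbose = FALSE) {
  stopifnot(inherits(vol, "density_volume"), inherits(config, "fit_config"))
  dims <- dim(vol$data)
  maskdata <- if (is.null(mask)) array(1, dims) else mask$data
  if (!all(dim(maskdata) == dims)) stop("mask dims must match volume")
  v <- vol$data * maskdata
  v[v < 0] <- 0
  vvec <- as.vector(v)
  mvec <- as.vector(maskdata)
  if (sum(vvec) <= 0) stop("masked volume has no positive density to fit")
  sigma <- config$sigma_voxels * vol$voxel_size
  voxel <- vol$voxel_size
  origin <- vol$origin
  idims <- as.integer(dims)

  # voxel centre coordinates for sampling and residual seeding
  voxel_center <- function(flat_idx) {
    ijk <- arrayInd(flat_idx, dims) - 1L
    sweep(ijk * voxel, 2, origin, "+")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  candidates <- which(vvec > 0)
  n0 <- min(config$initial_atoms, length(candidates), config$max_atoms)
  picked <- if (length(candidates) > n0)
    sample(candidates, n0, prob = vvec[candidates]) else candidates
  pos <- voxel_center(picked) +
    matrix(runif(3 * length(picked), -0.25, 0.25) * voxel, ncol = 3)
  w <- pmax(vvec[picked], 1e-8 * max(vvec))

  render_masked <- function(pos, w) {
    cpp_render(pos, w, sigma, idims, voxel, origin, 4) * mvec
  }
  l1 <- function(vhat) sum(abs(vvec - vhat)[mvec > 0]) / sum(abs(vvec[mvec > 0]))

  refine <- function(pos, w, inner_max = NULL) {
    # large models are overparameterized locally: fewer, cheaper rounds
    big <- nrow(pos) > 1500L
    if (is.null(inner_max)) inner_max <- if (big) 5L else 12L
    err_prev <- l1(render_masked(pos, w))
    num <- NULL
    for (r in seq_len(inner_max)) {
      # multiplicative non-negative weight update(s) against the target
      for (wu in seq_len(if (big) 1L else 2L)) {
        vhat <- render_masked(pos, w)
        den <- cpp_backproject(pos, sigma, idims, voxel, origin, vhat, 4)
        if (is.null(num))
          num <- cpp_backproject(pos, sigma, idims, voxel, origin, vvec * mvec, 4)
        w <- pmax(w * num / pmax(den, 1e-30), 1e-300)
      }
      # Gauss-Newton position step with backtracking on the L1 error
      vhat <- render_masked(pos, w)
      err_here <- l1(vhat)
      step <- cpp_position_step(pos, w, sigma, idims, voxel, origin,
                                vhat - vvec * mvec, 4, sigma)
      for (damp in if (big) c(0.8, 0.3) else c(0.8, 0.4, 0.15)) {
        err_try <- l1(render_masked(pos + damp * step, w))
        if (err_try <= err_here) {
          pos <- pos + damp * step
          err_here <- err_try
          num <- NULL  # positions moved; refresh the backprojection of V
          break
        }
      }
      if (err_prev - err_here < config$convergence_tol * max(err_prev, 1e-12)) {
        err_prev <- err_here
        break
      }
      err_prev <- err_here
    }
    list(pos = pos, w = w, err = err_prev)
  }

  # collapse near-coincident Gaussians (closer than 0.75 sigma) into their
  # weight-averaged centre; kept only when the refit does not lose accuracy.
  # Only worthwhile for small models, where a redundant pair distorts the
  # solution; at scale the weight updates handle redundancy and merging
  # would fight the growth schedule.
  try_merge <- function(st) {
    repeat {
      n <- nrow(st$pos)
      if (n < 2L || n > 512L || n >= config$max_atoms) return(st)
      pr <- cpp_pairs_within(st$pos, 0.75 * sigma)
      if (length(pr$i) == 0L) return(st)
      grp <- seq_len(n)
      for (k in seq_along(pr$i)) {
        g <- grp[pr$j[k]]
        grp[grp == g] <- grp[pr$i[k]]
      }
      ug <- match(grp, unique(grp))
      if (max(ug) == n) return(st)
      wsum <- as.numeric(tapply(st$w, ug, sum))
      mpos <- cbind(tapply(st$w * st$pos[, 1], ug, sum),
                    tapply(st$w * st$pos[, 2], ug, sum),
                    tapply(st$w * st$pos[, 3], ug, sum)) / wsum
      cand <- refine(unname(mpos), wsum)
      if (cand$err <= st$err + 1e-12) st <- cand else return(st)
    }
  }

  st <- try_merge(refine(pos, w))
  history <- st$err
  warn_msg <- NULL
  iter <- 1L
  stall <- 0L
  refined_at_cap <- nrow(st$pos) >= config$max_atoms
  while (st$err > config$target_error && iter < config$max_outer_iters) {
    n <- nrow(st$pos)
    if (n >= config$max_atoms && refined_at_cap) {
      warn_msg <- sprintf(
        "target error %.4g unreachable at the %d-atom cap (achieved %.4g)",
        config$target_error, config$max_atoms, st$err)
      break
    }
    iter <- iter + 1L
    if (n < config$max_atoms) {
      batch <- min(max(32L, ceiling(n / 10)), config$max_atoms - n)
      vhat <- render_masked(st$pos, st$w)
      resid <- (vvec - vhat) * mvec
      # seed at local maxima of the residual: adjacent high-residual voxels
      # describe one underfit bump, not several
      peaks <- which(.local_maxima(array(resid, dims)) & resid > 0)
      if (length(peaks) >= batch) {
        take <- peaks[order(resid[peaks], decreasing = TRUE)][seq_len(batch)]
      } else {
        ord <- order(resid, decreasing = TRUE)
        take <- union(peaks, ord[seq_len(min(batch, sum(resid > 0)))])
        take <- take[seq_len(min(batch, length(take)))]
      }
      if (length(take) == 0L) {
        warn_msg <- "no positive residual left to seed new atoms"
        break
      }
      newpos <- voxel_center(take) +
        matrix(runif(3 * length(take), -0.25, 0.25) * voxel, ncol = 3)
      neww <- pmax(resid[take], 1e-8 * max(vvec))
      cand0 <- refine(rbind(st$pos, newpos), c(st$w, neww))
      cand <- try_merge(cand0)
      n_merged <- nrow(cand0$pos) - nrow(cand$pos)
      if (cand$err > st$err + 1e-12) {  # overshoot: retry with gentler seeds
        cand0 <- refine(rbind(st$pos, newpos), c(st$w, 0.25 * neww))
        cand <- try_merge(cand0)
        n_merged <- nrow(cand0$pos) - nrow(cand$pos)
      }
    } else {
      cand <- refine(st$pos, st$w)
      refined_at_cap <- TRUE
      n_merged <- 0L
    }
    # prune collapsed atoms (skip at the cap so the final count is exact)
    keep <- cand$w >= 1e-6 * max(cand$w)
    n_pruned <- 0L
    if (nrow(cand$pos) < config$max_atoms && any(!keep) && sum(keep) >= 1L) {
      n_pruned <- sum(!keep)
      cand$pos <- cand$pos[keep, , drop = FALSE]
      cand$w <- cand$w[keep]
      cand$err <- l1(render_masked(cand$pos, cand$w))
    }
    if (verbose)
      message(sprintf(
        "iter %3d: N %4d -> %4d (merged %d, pruned %d), err %.5f -> %.5f%s",
        iter, n, nrow(cand$pos), n_merged, n_pruned, st$err, cand$err,
        if (cand$err > st$err + 1e-12) " (rolled back)" else ""))
    if (cand$err <= st$err + 1e-12) {
      st <- cand
      refined_at_cap <- nrow(st$pos) >= config$max_atoms
      stall <- 0L
      history <- c(history, st$err)
    } else {
      # rolled back; retry with fresh stochastic jitter before giving up
      stall <- stall + 1L
      if (stall >= 5L) {
        warn_msg <- sprintf("fit stalled at error %.4g (iteration %d rolled back)",
                            st$err, iter)
        break
      }
    }
  }
  if (st$err > config$target_error && is.null(warn_msg) &&
      iter >= config$max_outer_iters)
    warn_msg <- sprintf("iteration budget exhausted at error %.4g", st$err)
  if (!is.null(warn_msg)) warning(warn_msg)

  model <- pseudo_atom_model(st$pos, st$w, sigma, achieved_error = st$err,
                             seed = config$seed, source = "fit_pseudo_atoms")
  model$history <- history
  model$config <- config
  model
}

#' Histogram of per-atom nearest-neighbour distances
#'
#' @param model a [pseudo_atom_model()] with at least 2 atoms.
#' @param n_bins number of equal-width bins.
#' @return An object of class `distance_histogram` with `bin_edges` (A),
#'   `counts` (summing to the atom count) and a `definition` tag.
#' @export
nn_distance_histogram <- function(model, n_bins = 30L) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  n <- nrow(model$positions)
  if (n < 2L) stop("nearest-neighbour distances need at least 2 atoms")
  d <- cpp_nn_distances(model$positions)
  rng <- range(d)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)
  structure(
    list(bin_edges = edges, counts = tabulate(idx, nbins = n_bins),
         definition = "per-atom nearest-neighbor distances"),
    class = "distance_histogram"
  )
}

#' Write a distance histogram as two-column text
#'
#' Columns: bin centre (A) and count, tab-separated with a header.
#'
#' @param hist a `distance_histogram` from [nn_distance_histogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "distance_histogram"))
  centers <- (hist$bin_edges[-1] + head(hist$bin_edges, -1)) / 2
  utils::write.table(
    data.frame(bin_center_A = sprintf("%.6g", centers), count = hist$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Suggest an elastic-network cutoff from neighbour distances
#'
#' Returns a cutoff such that at least `fraction` (default ~95%) of the
#' per-atom nearest-neighbour distances fall strictly below it: the
#' `ceiling(fraction * N)`-th order statistic, inflated by a relative 1e-6 so
#' ties sit strictly inside. If the elastic network at that cutoff is
#' disconnected, the cutoff is raised to the bottleneck edge of the Euclidean
#' minimum spanning tree (plus the same epsilon) so the network is connected,
#' and a message reports the adjustment.
#'
#' @param model a [pseudo_atom_model()] with at least 2 atoms.
#' @param fraction coverage fraction in (0, 1].
#' @return Cutoff distance in Angstrom.
#' @export
suggest_cutoff <- function(model, fraction = 0.95) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  n <- nrow(model$positions)
  if (n < 2L) stop("cutoff suggestion needs at least 2 atoms")
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  d <- sort(cpp_nn_distances(model$positions))
  k <- min(n, ceiling(fraction * n))
  cutoff <- d[k] * (1 + 1e-6)
  bottleneck <- cpp_mst_bottleneck(model$positions)
  if (bottleneck * (1 + 1e-6) > cutoff) {
    message(sprintf(
      "cutoff %.3f A leaves the network disconnected; raised to MST bottleneck %.3f A",
      cutoff, bottleneck * (1 + 1e-6)))
    cutoff <- bottleneck * (1 + 1e-6)
  }
  cutoff
}
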