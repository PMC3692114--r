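# Shared in-code fixtures: small volumes and atom clouds built at test time.

# random pseudo-atom model with positions uniform in a cube
random_model <- function(n, box = 40, sigma = 2, seed = 1) {
  set.seed(seed)
  pseudo_atom_model(matrix(runif(3 * n, -box / 2, box / 2), n, 3),
                    runif(n, 0.5, 1.5), sigma)
}

# well-connected random cloud: points jittered off a compact grid, so every
# atom has several neighbours within the cutoff (no pendant atoms)
connected_cloud <- function(n, spacing = 4, seed = 1) {
  set.seed(seed)
  side <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side)))
  g <- g[seq_len(n), , drop = FALSE] * spacing
  g + matrix(runif(3 * n, -0.2, 0.2) * spacing, n, 3)
}

# tiny deterministic volume with two well-separated density classes
bimodal_volume <- function(seed = 1) {
  set.seed(seed)
  x <- array(0, c(12, 12, 12))
  x[sample(length(x), 500)] <- rnorm(500, 2, 0.3)
  x[sample(which(x == 0), 400)] <- rnorm(400, 8, 0.5)
  x[x < 0] <- 0
  density_volume(x, voxel_size = 1.5)
}

# dense-matrix reference Hessian assembled pair-by-pair (independent of the
# package's vectorized sparse construction)
brute_force_hessian <- function(net) {
  n <- nrow(net$positions)
  h <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges[k, 1]; j <- net$edges[k, 2]
    dr <- net$positions[i, ] - net$positions[j, ]
    blk <- net$spring_constant * outer(dr, dr) / sum(dr^2)
    ri <- 3 * (i - 1) + 1:3; rj <- 3 * (j - 1) + 1:3
    h[ri, ri] <- h[ri, ri] + blk
    h[rj, rj] <- h[rj, rj] + blk
    h[ri, rj] <- h[ri, rj] - blk
    h[rj, ri] <- h[rj, ri] - blk
  }
  h
}
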