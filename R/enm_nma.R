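#' Build a cutoff elastic network over pseudo-atoms
#'
#' Every pair of atoms strictly closer than `cutoff` is joined by a harmonic
#' spring of uniform stiffness whose rest length is the pair distance in the
#' reference conformation, so the reference is the energy minimum by
#' construction (no minimization needed).
#'
#' @param model a [pseudo_atom_model()] or an N x 3 position matrix (A).
#' @param cutoff interaction cutoff distance, Angstrom (> 0); pairs at
#'   exactly the cutoff are not linked.
#' @param spring_constant uniform spring stiffness C (> 0, arbitrary units;
#'   only sets the overall energy scale).
#' @return An object of class `elastic_network` with `positions`, `edges`
#'   (two-column index matrix, i < j), `rest_lengths`, `cutoff`,
#'   `spring_constant` and `n_components` (connected components of the
#'   spring graph).
#' @export
build_network <- function(model, cutoff, spring_constant = 1) {
  pos <- if (inherits(model, "pseudo_atom_model")) model$positions
         else unname(as.matrix(model))
  if (ncol(pos) != 3L || nrow(pos) < 2L)
    stop("network needs an N x 3 position matrix with N >= 2")
  if (!is.finite(cutoff) || cutoff <= 0) stop("`cutoff` must be > 0")
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("`spring_constant` must be > 0")
  pr <- cpp_pairs_within(pos, cutoff)
  edges <- cbind(pr$i, pr$j)
  structure(
    list(positions = pos, edges = edges, rest_lengths = pr$d,
         cutoff = cutoff, spring_constant = spring_constant,
         n_components = .n_components(nrow(pos), edges)),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network> %d atoms, %d springs, cutoff %.3g A\n",
              nrow(x$positions), nrow(x$edges), x$cutoff))
  cat(sprintf("  connected components: %d\n", x$n_components))
  invisible(x)
}

# union-find component count
.n_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Elastic-network potential energy of a conformation
#'
#' \eqn{E = (C/2) \sum_{edges} (d_{ij} - d^0_{ij})^2} where \eqn{d_{ij}} is
#' the pair distance in `positions` and \eqn{d^0_{ij}} the reference rest
#' length. Zero at the reference conformation; invariant under rigid motions.
#'
#' @param net an [build_network()] elastic network.
#' @param positions N x 3 matrix of displaced coordinates, Angstrom.
#' @return Energy (arbitrary units, >= 0).
#' @export
potential_energy <- function(net, positions) {
  stopifnot(inherits(net, "elastic_network"))
  positions <- as.matrix(positions)
  if (!all(dim(positions) == dim(net$positions)))
    stop("`positions` must match the network's N x 3 shape")
  if (nrow(net$edges) == 0L) return(0)
  dif <- positions[net$edges[, 1], , drop = FALSE] -
    positions[net$edges[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dif^2))
  net$spring_constant / 2 * sum((d - net$rest_lengths)^2)
}

#' Analytic elastic-network Hessian
#'
#' Second derivatives of the potential at the reference conformation: each
#' spring contributes the rank-one 3x3 block
#' \eqn{C (\Delta r)(\Delta r)^T / |\Delta r|^2} to its two diagonal blocks
#' and its negative to the off-diagonal blocks. Masses are uniform (unit), so
#' mass weighting is the identity. Rows sum to zero (translation invariance)
#' and the matrix is symmetric positive semidefinite.
#'
#' @param net an [build_network()] elastic network.
#' @param sparse return a `Matrix` sparse symmetric matrix (default) or a
#'   dense base matrix.
#' @return A 3N x 3N matrix.
#' @export
build_hessian <- function(net, sparse = TRUE) {
  stopifnot(inherits(net, "elastic_network"))
  n <- nrow(net$positions)
  e <- net$edges
  ne <- nrow(e)
  if (ne == 0L) {
    h <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(3 * n, 3 * n))
    return(if (sparse) h else as.matrix(h))
  }
  dif <- net$positions[e[, 1], , drop = FALSE] -
    net$positions[e[, 2], , drop = FALSE]
  u <- dif / sqrt(rowSums(dif^2))        # unit bond vectors
  C <- net$spring_constant
  ii <- vector("list", 9L); jj <- vector("list", 9L); xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    blk <- C * u[, a] * u[, b]
    ia <- 3L * (e[, 1] - 1L) + a         # row index, atom i component a
    ib <- 3L * (e[, 1] - 1L) + b
    ja <- 3L * (e[, 2] - 1L) + a
    jb <- 3L * (e[, 2] - 1L) + b
    k <- k + 1L
    ii[[k]] <- c(ia, ja, ia, ja)
    jj[[k]] <- c(jb, ib, ib, jb)
    xx[[k]] <- c(-blk, -blk, blk, blk)
  }
  h <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * n, 3 * n))
  if (sparse) h else as.matrix(h)
}

# Shift-invert Lanczos with full reorthogonalization for the lowest
# eigenpairs of a sparse symmetric PSD matrix. Factors (H + tau I) once with
# a sparse Cholesky and runs Lanczos on its inverse, whose largest Ritz
# values map back to the smallest eigenvalues of H. Deterministic start
# vector; the Krylov dimension is grown until the requested pairs have small
# residuals.
.lowest_eigs_shift_invert <- function(h, n_modes, tol = 1e-9) {
  n <- nrow(h)
  tau <- 1e-6 * max(Matrix::diag(h), 1)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(h) +
                           tau * Matrix::Diagonal(n), LDL = TRUE)
  opinv <- function(x) as.numeric(Matrix::solve(ch, x, system = "A"))
  scale_h <- max(abs(h@x), 1)
  m <- min(n, 2L * n_modes + 30L)
  repeat {
    v <- matrix(0, n, m)
    alpha <- numeric(m)
    beta <- numeric(m)
    v0 <- sin(seq_len(n)) + 0.5
    v[, 1] <- v0 / sqrt(sum(v0^2))
    for (j in seq_len(m)) {
      wv <- opinv(v[, j])
      alpha[j] <- sum(wv * v[, j])
      wv <- wv - alpha[j] * v[, j]
      if (j > 1) wv <- wv - beta[j - 1] * v[, j - 1]
      # full reorthogonalization, twice for stability
      for (pass in 1:2) wv <- wv - v[, seq_len(j), drop = FALSE] %*%
          crossprod(v[, seq_len(j), drop = FALSE], wv)
      b <- sqrt(sum(wv^2))
      if (j < m) {
        if (b < 1e-14) { m <- j; break }
        beta[j] <- b
        v[, j + 1] <- wv / b
      }
    }
    tm <- diag(alpha[seq_len(m)])
    if (m > 1) {
      idx <- seq_len(m - 1)
      tm[cbind(idx, idx + 1)] <- beta[idx]
      tm[cbind(idx + 1, idx)] <- beta[idx]
    }
    ed <- eigen(tm, symmetric = TRUE)
    take <- seq_len(min(n_modes, m))     # largest theta = smallest lambda
    theta <- ed$values[take]
    y <- ed$vectors[, take, drop = FALSE]
    vecs <- v[, seq_len(m), drop = FALSE] %*% y
    lambda <- 1 / theta - tau
    # residual check on the original matrix
    res <- vapply(seq_along(lambda), function(k) {
      r <- as.numeric(h %*% vecs[, k]) - lambda[k] * vecs[, k]
      sqrt(sum(r^2))
    }, numeric(1))
    if (all(res <= tol * scale_h) || m >= n)
      return(list(values = lambda, vectors = vecs))
    m <- min(n, 2L * m)
  }
}

#' Compute elastic-network normal modes
#'
#' Diagonalizes the (unit-mass) Hessian and returns the `n_modes` lowest
#' modes in ascending eigenvalue order, rigid-body modes included (for a
#' connected network the six zero modes come first, so the first flexible
#' mode has index 7). Uses a full dense eigendecomposition for 3N <= 3000 and
#' a shift-invert Lanczos partial solver on the sparse Hessian above that;
#' the two agree to tight tolerance. Mode vectors are unit norm with a
#' deterministic sign (largest-magnitude component positive).
#'
#' @param net an [build_network()] elastic network with at least one spring.
#' @param n_modes number of modes to return (<= 3N).
#' @param method `"auto"`, `"dense"` or `"sparse"`.
#' @return An object of class `normal_mode_set`: `vectors` (3N x M, columns
#'   orthonormal), `eigenvalues` (ascending), `frequencies`
#'   (`sqrt(pmax(eigenvalue, 0))`, arbitrary units), `n_rigid`, `n_atoms`.
#' @export
compute_modes <- function(net, n_modes = 20L, method = c("auto", "dense", "sparse")) {
  stopifnot(inherits(net, "elastic_network"))
  method <- match.arg(method)
  n <- nrow(net$positions)
  if (nrow(net$edges) == 0L) stop("network has no springs; no modes to compute")
  n_modes <- as.integer(n_modes)
  if (n_modes < 1L || n_modes > 3L * n)
    stop("`n_modes` must lie in [1, 3N]")
  if (net$n_components > 1L)
    warning("network has ", net$n_components, " connected components; expect ",
            6L * net$n_components, " near-zero modes")
  if (method == "auto") method <- if (3L * n <= 3000L) "dense" else "sparse"
  if (method == "dense") {
    ed <- eigen(build_hessian(net, sparse = FALSE), symmetric = TRUE)
    ord <- rev(seq_len(3L * n))[seq_len(n_modes)]  # ascending
    vals <- ed$values[ord]
    vecs <- ed$vectors[, ord, drop = FALSE]
  } else {
    sol <- .lowest_eigs_shift_invert(build_hessian(net, sparse = TRUE), n_modes)
    ord <- order(sol$values)
    vals <- sol$values[ord]
    vecs <- sol$vectors[, ord, drop = FALSE]
  }
  # unit norm + deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(vecs))) {
    vecs[, k] <- vecs[, k] / sqrt(sum(vecs[, k]^2))
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  vals[abs(vals) < 1e-12 * max(abs(vals), 1)] <- 0
  structure(
    list(vectors = vecs, eigenvalues = vals,
         frequencies = sqrt(pmax(vals, 0)),
         n_rigid = sum(vals < 1e-6 * max(vals, 1)),
         n_atoms = n, positions = net$positions),
    class = "normal_mode_set"
  )
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("<normal_mode_set> %d modes over %d atoms (%d rigid-body)\n",
              length(x$eigenvalues), x$n_atoms, x$n_rigid))
  cat(sprintf("  eigenvalues %.3g .. %.3g\n",
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Count near-zero (rigid-body) modes
#'
#' @param modes a [compute_modes()] result.
#' @param tol eigenvalue tolerance; defaults to `1e-6 * max(eigenvalue, 1)`.
#' @return Integer count of modes with eigenvalue below `tol`.
#' @export
count_rigid_modes <- function(modes, tol = NULL) {
  stopifnot(inherits(modes, "normal_mode_set"))
  if (is.null(tol)) tol <- 1e-6 * max(modes$eigenvalues, 1)
  sum(modes$eigenvalues < tol)
}

#' Orthonormal basis of the rigid-body subspace
#'
#' Three uniform translations plus three rotations about the centroid,
#' orthonormalized. Any rigid-body displacement of the structure is a linear
#' combination of these six 3N-vectors.
#'
#' @param positions N x 3 reference coordinates.
#' @return 3N x 6 matrix with orthonormal columns.
#' @export
rigid_body_basis <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  ctr <- colMeans(positions)
  rel <- sweep(positions, 2, ctr)
  b <- matrix(0, 3 * n, 6)
  for (a in 1:3) b[seq(a, 3 * n, by = 3), a] <- 1      # translations
  # rotations: u_i = e_a x (r_i - c)
  ax <- diag(3)
  for (a in 1:3) {
    cr <- cbind(ax[a, 2] * rel[, 3] - ax[a, 3] * rel[, 2],
                ax[a, 3] * rel[, 1] - ax[a, 1] * rel[, 3],
                ax[a, 1] * rel[, 2] - ax[a, 2] * rel[, 1])
    b[, 3 + a] <- as.vector(t(cr))
  }
  qr.Q(qr(b))[, seq_len(qr(b)$rank), drop = FALSE]
}

#' Remove the rigid-body component of a displacement vector
#'
#' Projects a 3N displacement onto the orthogonal complement of the six
#' translation/rotation vectors of the reference conformation.
#'
#' @param displacement 3N numeric vector (atom-major: x1,y1,z1,x2,...).
#' @param positions N x 3 reference coordinates.
#' @return The projected 3N vector.
#' @export
project_out_rigid <- function(displacement, positions) {
  b <- rigid_body_basis(positions)
  if (length(displacement) != nrow(b))
    stop("displacement length must be 3N")
  as.numeric(displacement - b %*% crossprod(b, displacement))
}
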