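#' Specification of a synthetic two-domain phantom
#'
#' The phantom emulates the standard protocol for synthetic EM test volumes:
#' a point model is rendered as a grid of Gaussians and low-pass filtered to
#' a stated resolution. Defaults reproduce a 64^3 grid at 2 A/voxel filtered
#' to 10 A, with two anisotropic Gaussian clouds of atoms joined at a hinge
#' halfway between them -- a bilobed map with one clean hinge-bending motion.
#'
#' @param n_atoms atoms per domain.
#' @param separation distance between the two domain centres, Angstrom.
#' @param hinge_axis rotation axis of the hinge motion (unit 3-vector).
#' @param hinge_angle hinge rotation angle, radians.
#' @param dims grid dimensions.
#' @param voxel_size Angstrom per voxel.
#' @param resolution low-pass resolution, Angstrom (must be >=
#'   2 * voxel_size, the Nyquist limit).
#' @param noise_sd additive Gaussian noise standard deviation (density
#'   units; 0 = noiseless).
#' @param seed mandatory integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_atoms = 150L, separation = 32,
                         hinge_axis = c(0, 0, 1), hinge_angle = 0.15,
                         dims = c(64L, 64L, 64L), voxel_size = 2,
                         resolution = 10, noise_sd = 0, seed = 0L) {
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1L) stop("`n_atoms` must be >= 1 per domain")
  if (!is.finite(separation) || separation <= 0)
    stop("`separation` must be > 0")
  if (length(hinge_axis) != 3L || sum(hinge_axis^2) == 0)
    stop("`hinge_axis` must be a nonzero 3-vector")
  if (resolution < 2 * voxel_size)
    stop("`resolution` must be >= 2 * voxel_size (Nyquist)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(seed) || is.na(seed)) stop("`seed` is mandatory")
  structure(
    list(n_atoms = n_atoms, separation = separation,
         hinge_axis = hinge_axis / sqrt(sum(hinge_axis^2)),
         hinge_angle = hinge_angle, dims = as.integer(dims),
         voxel_size = voxel_size, resolution = resolution,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Hinge displacement field for a two-domain phantom
#'
#' Displacement of arbitrary points under the phantom's open-to-closed
#' motion: points on the moving side (x > 0, the second domain's half-space)
#' rotate about the hinge axis through the origin; the fixed side does not
#' move. The global rigid-body component is projected out, so the result is
#' directly comparable with (internal) normal modes.
#'
#' @param positions N x 3 coordinates, Angstrom.
#' @param spec a [phantom_spec()].
#' @return 3N displacement vector (atom-major), rigid-body free.
#' @export
hinge_displacement <- function(positions, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  positions <- as.matrix(positions)
  rot <- .rotation_matrix(spec$hinge_axis, spec$hinge_angle)
  moved <- positions %*% t(rot)
  disp <- (moved - positions) * (positions[, 1] > 0)
  project_out_rigid(as.numeric(t(disp)), positions)
}

#' Generate a synthetic two-domain phantom structure
#'
#' Draws two anisotropic Gaussian clouds of pseudo-atoms centred at
#' `(-separation/2, 0, 0)` and `(+separation/2, 0, 0)` (cloud spreads scale
#' with the separation so the domains just touch at the hinge), with weights
#' uniform in [0.5, 1.5] and sigma equal to the voxel size. Also returns the
#' ground-truth open-to-closed hinge displacement of those atoms.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `model` (ground-truth [pseudo_atom_model()]),
#'   `displacement` (rigid-projected 3N hinge vector for the model's atoms)
#'   and `spec`.
#' @export
make_two_domain_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_atoms
  sds <- spec$separation * c(1 / 3, 1 / 4.5, 1 / 4.5)
  .with_seed(spec$seed, {
    d1 <- cbind(rnorm(n, -spec$separation / 2, sds[1]),
                rnorm(n, 0, sds[2]), rnorm(n, 0, sds[3]))
    d2 <- cbind(rnorm(n, +spec$separation / 2, sds[1]),
                rnorm(n, 0, sds[2]), rnorm(n, 0, sds[3]))
    w <- runif(2 * n, 0.5, 1.5)
    pos <- rbind(d1, d2)
    model <- pseudo_atom_model(pos, w, sigma = spec$voxel_size,
                               seed = spec$seed, source = "two_domain_phantom")
    list(model = model, displacement = hinge_displacement(pos, spec),
         spec = spec)
  })
}

#' Render a structure to a volume at a stated resolution
#'
#' Renders the model's Gaussians onto a centred grid and applies a
#' Fourier-space Gaussian low-pass filter whose amplitude falls to 1/e at
#' spatial frequency `1/resolution`. The filter's zero-frequency gain is 1,
#' so total density is conserved; tiny negative ripples are clamped to 0.
#'
#' @param model a [pseudo_atom_model()].
#' @param dims grid dimensions.
#' @param voxel_size Angstrom per voxel.
#' @param resolution low-pass resolution in Angstrom; `Inf` disables the
#'   filter. Must be >= 2 * voxel_size otherwise.
#' @param origin grid origin; defaults to centring the grid on the
#'   coordinate origin.
#' @return A [density_volume()].
#' @export
structure_to_volume <- function(model, dims = c(64L, 64L, 64L),
                                voxel_size = 2, resolution = 10,
                                origin = NULL) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  dims <- as.integer(dims)
  if (is.null(origin)) origin <- -voxel_size * (dims - 1) / 2
  if (is.finite(resolution) && resolution < 2 * voxel_size)
    stop("`resolution` must be >= 2 * voxel_size (Nyquist)")
  lo <- origin
  hi <- origin + voxel_size * (dims - 1)
  if (any(sweep(model$positions, 2, lo, "<")) ||
      any(sweep(model$positions, 2, hi, ">")))
    warning("some atoms fall outside the grid; their density is clipped")
  # generous truncation radius: keeps Fourier ringing (and hence the mass
  # lost to clamping) below 1e-6 of the total density
  vol <- render_model(model, dims, voxel_size, origin, trunc_sigmas = 8)
  if (!is.finite(resolution)) return(vol)
  x <- vol$data
  freq2 <- function(nn) {
    if (nn == 1L) return(0)
    f <- c(0:(nn %/% 2), -((nn - nn %/% 2 - 1):1)) / (nn * voxel_size)
    f^2
  }
  f2 <- outer(outer(freq2(dims[1]), freq2(dims[2]), "+"), freq2(dims[3]), "+")
  filt <- exp(-f2 * resolution^2)
  xf <- fft(fft(x) * filt, inverse = TRUE) / length(x)
  # the filter has unit zero-frequency gain, so it conserves the total
  # density exactly; clamping the (tiny, Nyquist-ringing) negative ripples
  # would add mass, so the clipped grid is rescaled back to the input total
  out <- pmax(Re(xf), 0)
  s <- sum(out)
  if (s > 0) out <- out * (sum(x) / s)
  density_volume(array(out, dims), voxel_size, origin)
}

#' Add clamped Gaussian noise to a volume
#'
#' Adds zero-mean Gaussian noise of standard deviation `sd` and clamps the
#' result at zero (densities stay non-negative).
#'
#' @param vol a [density_volume()].
#' @param sd noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return A [density_volume()].
#' @export
add_noise <- function(vol, sd, seed = 0L) {
  stopifnot(inherits(vol, "density_volume"))
  if (!is.finite(sd) || sd < 0) stop("`sd` must be >= 0")
  if (sd == 0) return(vol)
  .with_seed(seed, {
    out <- pmax(vol$data + rnorm(length(vol$data), 0, sd), 0)
    density_volume(array(out, dim(vol$data)), vol$voxel_size, vol$origin)
  })
}
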