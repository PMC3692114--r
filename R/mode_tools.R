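#' Specify a combined deformation along normal modes
#'
#' @param mode integer vector of distinct 1-based mode indices (rigid-body
#'   modes included in the numbering).
#' @param amplitude numeric amplitudes, one per mode; dimensionless scales on
#'   the unit-norm mode vectors, so a deformation by amplitude `a` displaces
#'   atom i by `a * |u_i|` Angstrom.
#' @return An object of class `deformation`.
#' @export
deformation <- function(mode, amplitude) {
  mode <- as.integer(mode)
  if (length(mode) != length(amplitude))
    stop("`mode` and `amplitude` must have the same length")
  if (anyDuplicated(mode)) stop("mode indices must be distinct")
  if (any(mode < 1L)) stop("mode indices are 1-based")
  if (!all(is.finite(amplitude))) stop("amplitudes must be finite")
  structure(list(mode = mode, amplitude = as.numeric(amplitude)),
            class = "deformation")
}

#' Deform a structure along a combination of modes
#'
#' Applies \eqn{r'_i = r_i + \sum_n a_n u_{n,i}} where \eqn{u_{n,i}} is atom
#' i's 3-component of unit-norm mode n.
#'
#' @param model a [pseudo_atom_model()] whose positions the modes were
#'   computed for.
#' @param modes a [compute_modes()] result over the same atoms.
#' @param d a [deformation()].
#' @return N x 3 matrix of displaced positions, Angstrom.
#' @export
deform <- function(model, modes, d) {
  stopifnot(inherits(model, "pseudo_atom_model"),
            inherits(modes, "normal_mode_set"),
            inherits(d, "deformation"))
  n <- nrow(model$positions)
  if (modes$n_atoms != n) stop("modes were computed for a different atom count")
  if (any(d$mode > ncol(modes$vectors)))
    stop("unknown mode index ", max(d$mode), " (only ",
         ncol(modes$vectors), " modes computed)")
  disp <- modes$vectors[, d$mode, drop = FALSE] %*% d$amplitude
  model$positions + matrix(disp, ncol = 3, byrow = TRUE)
}

#' Collectivity degree of a mode vector
#'
#' Entropy-based measure of how many atoms a mode displaces significantly:
#' \deqn{\kappa = \frac{1}{N}\exp\Big(-\sum_i \alpha |u_i|^2
#'   \log(\alpha |u_i|^2)\Big), \quad \alpha = 1 / \sum_i |u_i|^2,}
#' where \eqn{|u_i|} is the displacement magnitude of atom i and atoms with
#' zero displacement contribute nothing to the sum. Bounded between 1/N (a
#' single atom moves) and 1 (all atoms move with equal magnitude); invariant
#' to rescaling of the vector.
#'
#' @param u 3N numeric mode vector (atom-major), not all zero.
#' @param n_atoms number of atoms N; defaults to `length(u) / 3`.
#' @return The collectivity in `[1/N, 1]`.
#' @export
collectivity <- function(u, n_atoms = length(u) / 3) {
  if (length(u) %% 3 != 0) stop("`u` must have length 3N")
  n <- as.integer(n_atoms)
  if (n * 3L != length(u)) stop("`n_atoms` inconsistent with length(u)")
  m2 <- colSums(matrix(u^2, nrow = 3))
  tot <- sum(m2)
  if (tot == 0) stop("collectivity of an all-zero vector is undefined")
  p <- m2 / tot
  p <- p[p > 0]
  exp(-sum(p * log(p))) / n
}

#' Collectivity of every computed mode
#'
#' @param modes a [compute_modes()] result.
#' @return A data.frame with one row per mode: `mode` (1-based index),
#'   `eigenvalue`, `frequency`, `collectivity`, and `rigid` (flag for the
#'   near-zero rigid-body modes, which are included but typically ignored).
#' @export
collectivity_report <- function(modes) {
  stopifnot(inherits(modes, "normal_mode_set"))
  m <- ncol(modes$vectors)
  data.frame(
    mode = seq_len(m),
    eigenvalue = modes$eigenvalues,
    frequency = modes$frequencies,
    collectivity = vapply(seq_len(m), function(k)
      collectivity(modes$vectors[, k], modes$n_atoms), numeric(1)),
    rigid = seq_len(m) <= modes$n_rigid
  )
}

#' Write the per-mode collectivity table
#'
#' Tab-separated text: mode, eigenvalue, frequency, collectivity, rigid flag.
#'
#' @param report a [collectivity_report()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collectivity_table <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Animation trajectory along one mode
#'
#' Frame k (k = 0 .. K-1) displaces the reference along the mode by
#' `amplitude * sin(2 * pi * k / K)` -- one full oscillation cycle, so frame
#' 0 is the reference and the loop closes. A `"ramp"` schedule (0 to
#' `amplitude` linearly) is available for non-looping output.
#'
#' @param model a [pseudo_atom_model()].
#' @param modes a [compute_modes()] result for the model.
#' @param mode_index 1-based mode to animate; animating a rigid-body mode
#'   (index <= `modes$n_rigid`) triggers a warning but proceeds.
#' @param amplitude displacement amplitude A (default 50; see
#'   [deformation()] for units).
#' @param n_frames number of frames K (>= 2, default 10).
#' @param schedule `"sine"` (default) or `"ramp"`.
#' @return An object of class `trajectory`: `frames` (list of K N x 3
#'   matrices, frame 1 = reference), `mode_index`, `amplitude`, `phases`
#'   (the amplitude schedule).
#' @export
make_trajectory <- function(model, modes, mode_index, amplitude = 50,
                            n_frames = 10L, schedule = c("sine", "ramp")) {
  stopifnot(inherits(model, "pseudo_atom_model"),
            inherits(modes, "normal_mode_set"))
  schedule <- match.arg(schedule)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("`n_frames` must be >= 2")
  if (!is.finite(amplitude)) stop("`amplitude` must be finite")
  mode_index <- as.integer(mode_index)
  if (mode_index < 1L || mode_index > ncol(modes$vectors))
    stop("unknown mode index ", mode_index)
  if (mode_index <= modes$n_rigid)
    warning("mode ", mode_index, " is a rigid-body mode; the animation is a ",
            "global translation/rotation")
  a <- if (schedule == "sine")
    amplitude * sin(2 * pi * (seq_len(n_frames) - 1L) / n_frames)
  else
    amplitude * (seq_len(n_frames) - 1L) / (n_frames - 1L)
  frames <- lapply(a, function(ak)
    deform(model, modes, deformation(mode_index, ak)))
  structure(
    list(frames = frames, mode_index = mode_index, amplitude = amplitude,
         phases = a),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> mode %d, amplitude %.3g, %d frames of %d atoms\n",
              x$mode_index, x$amplitude, length(x$frames),
              nrow(x$frames[[1]])))
  invisible(x)
}

#' Overlap between modes and an observed conformational change
#'
#' Scores each mode against a target displacement by the normalized inner
#' product \eqn{|u_n \cdot \Delta r| / (|u_n| |\Delta r|)} in `[0, 1]`. The
#' rigid-body component of the target is projected out first so residual
#' superposition errors between the two conformations do not leak into the
#' scores (the two structures should still be superposed beforehand).
#'
#' @param modes a [compute_modes()] result.
#' @param target_displacement 3N numeric vector (atom-major), e.g. closed
#'   minus open coordinates.
#' @return A list with `overlaps` (per-mode), `best` (argmax mode index) and
#'   `target` (the rigid-projected displacement actually scored).
#' @export
mode_overlap <- function(modes, target_displacement) {
  stopifnot(inherits(modes, "normal_mode_set"))
  if (length(target_displacement) != 3L * modes$n_atoms)
    stop("target displacement must have length 3N")
  if (sqrt(sum(target_displacement^2)) == 0)
    stop("target displacement is the zero vector")
  tgt <- project_out_rigid(target_displacement, modes$positions)
  nt <- sqrt(sum(tgt^2))
  if (nt < 1e-12 * sqrt(sum(target_displacement^2)))
    stop("target displacement is purely rigid-body; no internal motion to match")
  ov <- abs(as.numeric(crossprod(modes$vectors, tgt))) / nt
  list(overlaps = ov, best = which.max(ov), target = tgt)
}
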