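# Pseudo-atom PDB dialect: one HETATM per pseudo-atom (element C, residue
# PSA, chain A), coordinates at 3 decimals, the weight stored in the
# occupancy column as weight / weight_scale (2 decimals, floored at 0.01 so
# no atom round-trips to zero), and REMARK 99 records carrying the shared
# Gaussian sigma (required downstream) and the weight scale.

.pdb_hetatm <- function(serial, xyz, occ, bfac = 0) {
  sprintf("HETATM%5d  C   PSA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, serial, xyz[1], xyz[2], xyz[3], occ, bfac)
}

#' Write a pseudo-atom model as PDB
#'
#' See the dialect described in [read_pseudo_pdb()]. The weight scale is the
#' maximum weight, so occupancies span (0, 1].
#'
#' @param model a [pseudo_atom_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pseudo_pdb <- function(model, path) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  n <- nrow(model$positions)
  wscale <- max(model$weights)
  occ <- pmax(round(model$weights / wscale, 2), 0.01)
  lines <- c(
    sprintf("REMARK  99 PSEUDOATOM SIGMA %.6f", model$sigma),
    sprintf("REMARK  99 PSEUDOATOM WEIGHTSCALE %.10g", wscale),
    if (is.finite(model$achieved_error))
      sprintf("REMARK  99 PSEUDOATOM ACHIEVEDERROR %.6f", model$achieved_error),
    vapply(seq_len(n), function(i)
      .pdb_hetatm(i, model$positions[i, ], occ[i]), character(1)),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}

.parse_remark99 <- function(lines, key) {
  pat <- paste0("^REMARK  99 PSEUDOATOM ", key, " ")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  as.numeric(sub(pat, "", hit[1]))
}

#' Read a pseudo-atom PDB file
#'
#' Parses the HETATM dialect written by [write_pseudo_pdb()]: positions from
#' the coordinate columns (0.001 A resolution), weights from occupancy times
#' the `REMARK 99 PSEUDOATOM WEIGHTSCALE` factor, and the shared Gaussian
#' sigma from `REMARK 99 PSEUDOATOM SIGMA` (an error if absent -- sigma is
#' required by every downstream step).
#'
#' @param path PDB file path.
#' @return A [pseudo_atom_model()].
#' @export
read_pseudo_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  sigma <- .parse_remark99(lines, "SIGMA")
  if (is.null(sigma) || !is.finite(sigma))
    stop("missing REMARK 99 PSEUDOATOM SIGMA record in ", path,
         "; the Gaussian sigma is required")
  wscale <- .parse_remark99(lines, "WEIGHTSCALE")
  if (is.null(wscale)) wscale <- 1
  err <- .parse_remark99(lines, "ACHIEVEDERROR")
  at <- grep("^(HETATM|ATOM  )", lines, value = TRUE)
  if (length(at) == 0) stop("no HETATM/ATOM records in ", path)
  bad <- nchar(at) < 60
  if (any(bad))
    stop("malformed atom record in ", path, ": '", at[which(bad)[1]], "'")
  num <- function(from, to) {
    v <- as.numeric(substr(at, from, to))
    if (any(is.na(v)))
      stop("malformed atom record in ", path, ": '", at[which(is.na(v))[1]], "'")
    v
  }
  pos <- cbind(num(31, 38), num(39, 46), num(47, 54))
  w <- num(55, 60) * wscale
  pseudo_atom_model(pos, w, sigma,
                    achieved_error = if (is.null(err)) NA_real_ else err,
                    source = paste0("read_pseudo_pdb:", basename(path)))
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame (1-based model numbers), playable as an
#' animation in VMD/PyMOL. Atom records follow the pseudo-atom dialect of
#' [write_pseudo_pdb()].
#'
#' @param traj a [make_trajectory()] result.
#' @param model the [pseudo_atom_model()] the trajectory deforms (supplies
#'   weights and sigma for the atom records).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, model, path) {
  stopifnot(inherits(traj, "trajectory"), inherits(model, "pseudo_atom_model"))
  n <- nrow(model$positions)
  wscale <- max(model$weights)
  occ <- pmax(round(model$weights / wscale, 2), 0.01)
  out <- c(
    sprintf("REMARK  99 PSEUDOATOM SIGMA %.6f", model$sigma),
    sprintf("REMARK  99 PSEUDOATOM WEIGHTSCALE %.10g", wscale),
    sprintf("REMARK  99 PSEUDOATOM MODE %d AMPLITUDE %.6g", traj$mode_index,
            traj$amplitude)
  )
  for (k in seq_along(traj$frames)) {
    out <- c(out, sprintf("MODEL %8d", k),
             vapply(seq_len(n), function(i)
               .pdb_hetatm(i, traj$frames[[k]][i, ], occ[i]), character(1)),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read frames back from a multi-model PDB
#'
#' @param path file written by [write_trajectory_pdb()].
#' @return List of N x 3 coordinate matrices, one per MODEL block.
#' @export
read_trajectory_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0 || length(starts) != length(ends))
    stop("no complete MODEL/ENDMDL blocks in ", path)
  lapply(seq_along(starts), function(k) {
    at <- grep("^(HETATM|ATOM  )",
               lines[(starts[k] + 1):(ends[k] - 1)], value = TRUE)
    cbind(as.numeric(substr(at, 31, 38)),
          as.numeric(substr(at, 39, 46)),
          as.numeric(substr(at, 47, 54)))
  })
}

#' Write a mode set as plain-text vectors plus a metadata table
#'
#' Each mode goes to `mode_XXX.txt` (3N floats, one per line); eigenvalues,
#' frequencies and the rigid flag go to `metadata.tsv`.
#'
#' @param modes a [compute_modes()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_modes <- function(modes, dir) {
  stopifnot(inherits(modes, "normal_mode_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- ncol(modes$vectors)
  for (k in seq_len(m))
    writeLines(sprintf("%.12e", modes$vectors[, k]),
               file.path(dir, sprintf("mode_%03d.txt", k)))
  meta <- data.frame(
    mode = seq_len(m),
    eigenvalue = sprintf("%.17g", modes$eigenvalues),
    frequency = sprintf("%.17g", modes$frequencies),
    rigid = seq_len(m) <= modes$n_rigid,
    n_atoms = modes$n_atoms
  )
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # reference positions, so overlap analyses can rebuild the rigid subspace
  utils::write.table(
    data.frame(x = sprintf("%.6f", modes$positions[, 1]),
               y = sprintf("%.6f", modes$positions[, 2]),
               z = sprintf("%.6f", modes$positions[, 3])),
    file.path(dir, "positions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read a mode set written by [write_modes()]
#'
#' @param dir directory containing `mode_XXX.txt`, `metadata.tsv` and
#'   `positions.tsv`.
#' @return A `normal_mode_set`; vectors are checked to be unit norm within
#'   1e-6 and of length 3N.
#' @export
read_modes <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("no metadata.tsv in ", dir)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t")
  pos <- unname(as.matrix(utils::read.table(file.path(dir, "positions.tsv"),
                                            header = TRUE, sep = "\t")))
  n <- unique(meta$n_atoms)
  if (length(n) != 1L || nrow(pos) != n)
    stop("inconsistent atom count between metadata.tsv and positions.tsv")
  vecs <- matrix(0, 3 * n, nrow(meta))
  for (k in seq_len(nrow(meta))) {
    f <- file.path(dir, sprintf("mode_%03d.txt", meta$mode[k]))
    v <- scan(f, quiet = TRUE)
    if (length(v) != 3 * n)
      stop("mode vector length ", length(v), " != 3N = ", 3 * n, " in ", f)
    nv <- sqrt(sum(v^2))
    if (abs(nv - 1) > 1e-6)
      stop("mode vector in ", f, " is not unit norm (", signif(nv, 8), ")")
    vecs[, k] <- v
  }
  structure(
    list(vectors = vecs, eigenvalues = meta$eigenvalue,
         frequencies = meta$frequency, n_rigid = sum(meta$rigid),
         n_atoms = as.integer(n), positions = unname(pos)),
    class = "normal_mode_set"
  )
}
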