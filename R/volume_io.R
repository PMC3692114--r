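#' Construct a density volume
#'
#' A density volume is a 3D scalar grid with an isotropic physical voxel size
#' and an origin. The physical position (in Angstrom) of voxel index
#' `(ix, iy, iz)` (0-based) is `origin + voxel_size * c(ix, iy, iz)`; the x
#' index is fastest in memory.
#'
#' @param data 3D numeric array (nx, ny, nz); all values must be finite.
#' @param voxel_size Angstrom per voxel (isotropic, > 0).
#' @param origin length-3 numeric, Angstrom offset of voxel (0,0,0).
#' @return An object of class `density_volume` with elements `data`,
#'   `voxel_size` and `origin`.
#' @export
density_volume <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  if (!all(is.finite(data))) stop("density values must all be finite")
  if (length(voxel_size) != 1L || !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 vector")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "density_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  origin  (%.3g, %.3g, %.3g) A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Construct a binary mask
#'
#' @param data 3D array of 0/1 values.
#' @param voxel_size,origin grid geometry, as in [density_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d inside (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

.guess_format <- function(path, format) {
  if (!identical(format, "auto")) return(match.arg(format, c("mrc", "spider")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "map", "ccp4")) return("mrc")
  if (ext %in% c("vol", "spi", "xmp")) return("spider")
  stop("cannot guess volume format from extension '.", ext,
       "'; pass format = \"mrc\" or \"spider\"")
}

#' Read a density volume from an MRC2014 or SPIDER file
#'
#' Supports MRC2014 mode-2 (float32) files and single-volume 3D SPIDER
#' float32 files. If the header carries no usable voxel size, 1 Angstrom is
#' assumed with a warning.
#'
#' @param path file path.
#' @param format `"mrc"`, `"spider"`, or `"auto"` (guess from extension:
#'   .mrc/.map/.ccp4 vs .vol/.spi/.xmp).
#' @return A [density_volume()].
#' @export
read_volume <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .guess_format(path, format)
  if (format == "mrc") .read_mrc(path) else .read_spider(path)
}

#' Write a density volume to an MRC2014 or SPIDER file
#'
#' Data are stored as float32 (MRC mode 2; SPIDER iform 3), so the round trip
#' is faithful to float32 precision. Masks can be written by converting them
#' with [density_volume()] first (0/1 floats, the SPIDER mask convention).
#'
#' @inheritParams read_volume
#' @param vol a [density_volume()] or [binary_mask()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "auto") {
  if (inherits(vol, "binary_mask"))
    vol <- density_volume(vol$data + 0, vol$voxel_size, vol$origin)
  stopifnot(inherits(vol, "density_volume"))
  format <- .guess_format(path, format)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (format == "mrc") .write_mrc(vol, con) else .write_spider(vol, con)
  invisible(path)
}

# ---- MRC2014 (mode 2, little-endian) ---------------------------------------

.read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("MRC header truncated in ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "double", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3)                                  # nxstart/nystart/nzstart (unused)
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                                  # cell angles
  mapcrs <- ri(3)
  rf(3)                                  # dmin dmax dmean
  ri(2)                                  # ispg, nsymbt
  ri(25)                                 # extra
  origin <- rf(3)
  map_tag <- rawToChar(readBin(con, "raw", 4))
  if (map_tag != "MAP ")
    stop("not an MRC2014 file (bad MAP signature field): ", path)
  if (mode != 2L)
    stop("unsupported MRC mode field ", mode, " (only mode 2, float32)")
  if (any(nxyz < 1L)) stop("invalid MRC dimension field: ", paste(nxyz, collapse = "x"))
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order field MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","))
  n <- prod(nxyz)
  if (sz < 1024 + 4 * n)
    stop("MRC data section truncated: expected ", n, " voxels in ", path)
  if (all(mxyz > 0L) && all(cella > 0)) {
    vox <- cella / mxyz
    if (max(vox) - min(vox) > 1e-4 * max(vox))
      stop("anisotropic voxel sizes are not supported (cell field ",
           paste(signif(vox, 6), collapse = " x "), " A)")
    voxel <- mean(vox)
  } else {
    warning("MRC header carries no voxel size; assuming 1 A/voxel")
    voxel <- 1
  }
  seek(con, 1024)
  vals <- readBin(con, "double", n, size = 4, endian = "little")
  if (length(vals) < n) stop("MRC data section truncated in ", path)
  density_volume(array(vals, dim = nxyz), voxel, origin)
}

.write_mrc <- function(vol, con) {
  d <- dim(vol$data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2L)                          # nx ny nz, mode 2
  wi(c(0L, 0L, 0L))                      # nxstart
  wi(d)                                  # mx my mz
  wf(d * vol$voxel_size)                 # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1L, 2L, 3L))                      # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))
  wi(c(1L, 0L))                          # ispg, nsymbt
  wi(integer(25))                        # extra
  wf(vol$origin)                         # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(as.vector(vol$data)))     # rms
  wi(0L)                                 # nlabl
  writeBin(raw(800), con)                # labels
  wf(as.vector(vol$data))
}

# ---- SPIDER (single 3D volume, float32) ------------------------------------
# Header words (1-based float32): 1 NSLICE, 2 NROW, 5 IFORM (3 = 3D volume),
# 12 NSAM, 13 LABREC, 18-20 XOFF/YOFF/ZOFF (origin, A; our dialect),
# 21 SCALE (A/voxel; our dialect), 22 LABBYT, 23 LENBYT.

.read_spider <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 92) stop("SPIDER header truncated in ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "double", 23, size = 4, endian = "little")
  nz <- hdr[1]; ny <- hdr[2]; iform <- hdr[5]; nx <- hdr[12]
  labbyt <- hdr[22]
  bad_dim <- function(x) !is.finite(x) || x < 1 || x != round(x) || x > 1e5
  if (!is.finite(iform) || iform != 3)
    stop("not a 3D SPIDER volume (IFORM field = ", iform, ") in ", path)
  if (bad_dim(nx) || bad_dim(ny) || bad_dim(nz))
    stop("invalid SPIDER dimension fields (NSAM/NROW/NSLICE) in ", path)
  lenbyt <- 4 * nx
  labrec <- ceiling(1024 / lenbyt)
  expected_labbyt <- labrec * lenbyt
  if (!is.finite(labbyt) || labbyt != expected_labbyt)
    stop("inconsistent SPIDER LABBYT field (", labbyt, ", expected ",
         expected_labbyt, ") in ", path)
  n <- nx * ny * nz
  if (sz < labbyt + 4 * n)
    stop("SPIDER data section truncated: expected ", n, " voxels in ", path)
  origin <- hdr[18:20]
  voxel <- hdr[21]
  if (!is.finite(voxel) || voxel <= 0) {
    warning("SPIDER header carries no voxel size; assuming 1 A/voxel")
    voxel <- 1
  }
  seek(con, labbyt)
  vals <- readBin(con, "double", n, size = 4, endian = "little")
  if (length(vals) < n) stop("SPIDER data section truncated in ", path)
  density_volume(array(vals, dim = c(nx, ny, nz)), voxel, origin)
}

.write_spider <- function(vol, con) {
  d <- dim(vol$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  lenbyt <- 4 * nx
  labrec <- ceiling(1024 / lenbyt)
  labbyt <- labrec * lenbyt
  hdr <- numeric(labbyt / 4)
  hdr[1] <- nz
  hdr[2] <- ny
  hdr[3] <- ny * nz                      # IREC: records in the data section
  hdr[5] <- 3                            # IFORM: 3D volume
  hdr[6] <- 1                            # IMAMI: statistics present
  hdr[7] <- max(vol$data)
  hdr[8] <- min(vol$data)
  hdr[9] <- mean(vol$data)
  hdr[10] <- stats::sd(as.vector(vol$data))
  hdr[12] <- nx
  hdr[13] <- labrec
  hdr[18:20] <- vol$origin
  hdr[21] <- vol$voxel_size
  hdr[22] <- labbyt
  hdr[23] <- lenbyt
  writeBin(as.numeric(hdr), con, size = 4, endian = "little")
  writeBin(as.numeric(as.vector(vol$data)), con, size = 4, endian = "little")
}

# ---- thresholding ----------------------------------------------------------

#' Automatic density threshold (Otsu) for masking
#'
#' First guess of a masking threshold: Otsu's method (maximum between-class
#' variance) over a 256-bin histogram of the strictly positive voxel values.
#'
#' @param vol a [density_volume()].
#' @param n_bins number of histogram bins.
#' @return A single density value, strictly between the smallest and largest
#'   positive density.
#' @export
auto_threshold <- function(vol, n_bins = 256L) {
  stopifnot(inherits(vol, "density_volume"))
  v <- vol$data[vol$data > 0]
  if (length(unique(as.vector(vol$data))) < 2L || length(v) == 0L ||
      length(unique(v)) < 2L)
    stop("no threshold separates a constant volume")
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  # between-class variance for a cut after bin k, k = 1 .. n_bins - 1
  w0k <- w0[-n_bins]; m0k <- m0[-n_bins]
  valid <- w0k > 0 & w0k < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0k[valid] - m0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  k <- which.max(bcv)
  thr <- breaks[k + 1L]
  # keep strictly inside the positive density range
  min(max(thr, rng[1] + .Machine$double.eps * abs(rng[1])), rng[2])
}

#' Apply a density threshold as a 3D mask
#'
#' Voxels whose density falls below the threshold are set to zero; the mask
#' marks the voxels that are kept (`density >= threshold`). The masked volume
#' equals the input volume multiplied elementwise by the mask.
#'
#' @param vol a [density_volume()].
#' @param threshold density value.
#' @return A list with `volume` (masked [density_volume()]) and `mask`
#'   ([binary_mask()]).
#' @export
apply_threshold_mask <- function(vol, threshold) {
  stopifnot(inherits(vol, "density_volume"), is.finite(threshold))
  keep <- vol$data >= threshold
  mask <- array(as.numeric(keep), dim = dim(vol$data))
  out <- vol$data
  out[!keep] <- 0
  list(
    volume = density_volume(out, vol$voxel_size, vol$origin),
    mask = binary_mask(mask, vol$voxel_size, vol$origin)
  )
}

#' Downsample a volume by block averaging
#'
#' Averages `factor^3` blocks of voxels; the voxel size is multiplied by
#' `factor` and the origin is moved to the centre of the first block so voxel
#' positions stay physical. Dimensions not divisible by `factor` are
#' zero-padded first (with a message).
#'
#' @param vol a [density_volume()].
#' @param factor positive integer.
#' @return A [density_volume()].
#' @export
downsample <- function(vol, factor) {
  stopifnot(inherits(vol, "density_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  newd <- ceiling(d / factor)
  padd <- newd * factor
  x <- vol$data
  if (any(padd != d)) {
    message("padding ", paste(d, collapse = "x"), " grid with zeros to ",
            paste(padd, collapse = "x"), " before downsampling")
    xp <- array(0, dim = padd)
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    x <- xp
  }
  dim(x) <- c(factor, newd[1], factor, newd[2], factor, newd[3])
  out <- apply(x, c(2, 4, 6), mean)
  density_volume(out, vol$voxel_size * factor,
                 vol$origin + vol$voxel_size * (factor - 1) / 2)
}

#' Axis slices and orthogonal sum projections
#'
#' @param vol a [density_volume()].
#' @param axis `"x"`, `"y"` or `"z"`: the axis along which slices are taken
#'   (a z slice is an x-y image, etc.).
#' @return A list with `slices` (list of 2D matrices, one per voxel plane
#'   along `axis`) and `projections` (named list `x`, `y`, `z` of 2D sum
#'   projections along each axis).
#' @export
slices_and_projections <- function(vol, axis = "z") {
  stopifnot(inherits(vol, "density_volume"))
  axis <- match.arg(axis, c("x", "y", "z"))
  ax <- match(axis, c("x", "y", "z"))
  d <- dim(vol$data)
  slices <- lapply(seq_len(d[ax]), function(k) {
    switch(axis,
           x = vol$data[k, , ],
           y = vol$data[, k, ],
           z = vol$data[, , k])
  })
  projections <- list(
    x = apply(vol$data, c(2, 3), sum),
    y = apply(vol$data, c(1, 3), sum),
    z = apply(vol$data, c(1, 2), sum)
  )
  list(slices = slices, projections = projections)
}
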