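test_that("MRC and SPIDER round trips preserve grid, voxel size and origin", {
  set.seed(3)
  v <- density_volume(array(runif(64^2), c(64, 8, 8)), voxel_size = 2,
                      origin = c(-64, -8, -8))
  for (ext in c(".mrc", ".vol")) {
    p <- tempfile(fileext = ext)
    write_volume(v, p)
    r <- read_volume(p)
    expect_identical(dim(r$data), c(64L, 8L, 8L))
    expect_equal(r$voxel_size, 2)
    expect_equal(r$origin, c(-64, -8, -8))
    # float32 storage: relative error bounded by single precision
    expect_lt(max(abs(r$data - v$data)), 1e-6)
    # writers are idempotent: write(read(write(x))) is byte-identical
    p2 <- tempfile(fileext = ext)
    write_volume(r, p2)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("a written 64-cube MRC header reports 64^3 dims at 2 A, read independently", {
  v <- density_volume(array(0.5, c(64, 64, 64)), voxel_size = 2)
  p <- tempfile(fileext = ".mrc")
  write_volume(v, p)
  # parse header words directly, independent of the package reader
  con <- file(p, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 28)
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "double", 3, size = 4, endian = "little")
  expect_identical(nxyz, c(64L, 64L, 64L))
  expect_identical(mode, 2L)
  expect_equal(cella / mxyz, c(2, 2, 2))
  expect_identical(dim(read_volume(p)$data), c(64L, 64L, 64L))
})

test_that("gemmi (independent reader) agrees with the MRC writer", {
  skip_if_not(nzchar(Sys.which("python")))
  set.seed(11)
  v <- density_volume(array(runif(512), c(8, 8, 8)), voxel_size = 1.5)
  p <- tempfile(fileext = ".mrc")
  write_volume(v, p)
  out <- system2("python", c("-c", shQuote(paste0(
    "import gemmi; m = gemmi.read_ccp4_map('", p, "'); ",
    "import numpy as np; a = np.array(m.grid, copy=False); ",
    "print(a.shape[0], a.shape[1], a.shape[2], ",
    "round(m.grid.unit_cell.a / m.grid.nu, 6), round(float(a.sum()), 4))"))),
    stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(parts[1:3]), c(8L, 8L, 8L))
  expect_equal(as.numeric(parts[4]), 1.5)
  expect_equal(as.numeric(parts[5]), sum(v$data), tolerance = 1e-4)
})

test_that("truncated and malformed volume files raise format errors, not partial data", {
  v <- density_volume(array(1, c(8, 8, 8)), voxel_size = 1)
  p <- tempfile(fileext = ".mrc")
  write_volume(v, p)
  raw <- readBin(p, "raw", file.size(p))
  pt <- tempfile(fileext = ".mrc")
  writeBin(raw[1:1200], pt)              # header plus a sliver of data
  expect_error(read_volume(pt), "truncated")
  bad <- raw
  bad[209:212] <- as.raw(c(0, 0, 0, 0))  # clobber the MAP signature
  pb <- tempfile(fileext = ".mrc")
  writeBin(bad, pb)
  expect_error(read_volume(pb), "MAP signature")
  ps <- tempfile(fileext = ".vol")
  write_volume(v, ps)
  sraw <- readBin(ps, "raw", file.size(ps))
  pst <- tempfile(fileext = ".vol")
  writeBin(sraw[seq_len(length(sraw) - 100)], pst)
  expect_error(read_volume(pst), "truncated")
  expect_error(read_volume(tempfile(fileext = ".mrc")), "not found")
})

test_that("anisotropic voxel sizes are rejected", {
  v <- density_volume(array(1, c(4, 4, 4)))
  p <- tempfile(fileext = ".mrc")
  write_volume(v, p)
  raw <- readBin(p, "raw", file.size(p))
  con <- rawConnection(raw(0), "w")
  writeBin(raw[1:40], con)
  writeBin(c(4, 8, 4), con, size = 4, endian = "little")  # cella broken
  writeBin(raw[53:length(raw)], con)
  out <- rawConnectionValue(con)
  close(con)
  pa <- tempfile(fileext = ".mrc")
  writeBin(out, pa)
  expect_error(read_volume(pa), "anisotropic")
})

test_that("Otsu threshold maximizes between-class variance (brute-force oracle)", {
  vol <- bimodal_volume()
  thr <- auto_threshold(vol)
  pos <- vol$data[vol$data > 0]
  expect_gt(thr, min(pos))
  expect_lt(thr, max(pos))
  # the two classes around 2 and 8 must be separated
  expect_gt(thr, 3)
  expect_lt(thr, 7)
  # exhaustive oracle: scan every bin edge, compute the between-class
  # variance directly from the raw values
  edges <- seq(min(pos), max(pos), length.out = 257)[2:256]
  bcv <- vapply(edges, function(t) {
    lo <- pos[pos < t]; hi <- pos[pos >= t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  best <- edges[which.max(bcv)]
  expect_equal(thr, best, tolerance = (max(pos) - min(pos)) / 128)
  expect_error(auto_threshold(density_volume(array(1, c(4, 4, 4)))),
               "constant")
})

test_that("threshold masking zeroes sub-threshold voxels and factorizes", {
  vol <- bimodal_volume()
  thr <- 5
  res <- apply_threshold_mask(vol, thr)
  expect_true(all(res$mask$data %in% c(0, 1)))
  expect_identical(res$mask$data == 1, vol$data >= thr)
  # masked volume = volume x mask, elementwise
  expect_equal(res$volume$data, vol$data * res$mask$data)
  # degenerate thresholds
  all_in <- apply_threshold_mask(vol, min(vol$data) - 1)
  expect_equal(all_in$volume$data, vol$data)
  expect_true(all(all_in$mask$data == 1))
  none <- apply_threshold_mask(vol, max(vol$data) + 1)
  expect_true(all(none$volume$data == 0))
  expect_true(all(none$mask$data == 0))
})

test_that("downsampling block-averages, conserves the mean, and scales the voxel", {
  set.seed(5)
  v <- density_volume(array(runif(8^3), c(8, 8, 8)), voxel_size = 1.5)
  d <- downsample(v, 2)
  expect_identical(dim(d$data), c(4L, 4L, 4L))
  expect_equal(d$voxel_size, 3)
  expect_equal(mean(d$data), mean(v$data))
  # brute-force triple-loop oracle
  ref <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    ref[i, j, k] <- mean(v$data[(2 * i - 1):(2 * i),
                                (2 * j - 1):(2 * j),
                                (2 * k - 1):(2 * k)])
  expect_equal(d$data, ref)
  expect_identical(downsample(v, 1), v)
  cv <- density_volume(array(7, c(4, 4, 4)), voxel_size = 2)
  expect_true(all(downsample(cv, 2)$data == 7))
  expect_error(downsample(v, 0), "positive")
})

test_that("slices count matches the axis extent and projections conserve the sum", {
  set.seed(6)
  v <- density_volume(array(runif(6 * 5 * 4), c(6, 5, 4)))
  sp <- slices_and_projections(v, "z")
  expect_length(sp$slices, 4)
  expect_identical(dim(sp$slices[[1]]), c(6L, 5L))
  for (ax in c("x", "y", "z"))
    expect_equal(sum(sp$projections[[ax]]), sum(v$data))
  # a single nonzero voxel projects to a single nonzero pixel on each axis
  one <- array(0, c(6, 5, 4)); one[2, 3, 1] <- 9
  spo <- slices_and_projections(density_volume(one))
  for (ax in c("x", "y", "z"))
    expect_equal(sum(spo$projections[[ax]] != 0), 1)
})
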