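# Minimal MRC2014 volume I/O.
#
# The MRC header is 1024 bytes of 32-bit words; data follow, column (x) fastest.
# Only the fields needed for density volumes and binary masks are interpreted:
# nx/ny/nz, mode, mx/my/mz, cell dimensions (for the voxel size), nsymbt
# (extended header to skip), the MAP magic and the machine stamp.

MRC_HEADER_BYTES <- 1024L

half_to_double <- function(u) {
  # IEEE 754 binary16 stored as unsigned 16-bit integers.
  stopifnot(all(u >= 0), all(u < 65536))
  sign <- ifelse(u >= 32768L, -1, 1)
  u <- u %% 32768L
  expo <- u %/% 1024L
  frac <- u %% 1024L
  val <- ifelse(
    expo == 0L,
    sign * frac / 1024 * 2^-14,
    ifelse(
      expo == 31L,
      ifelse(frac == 0L, sign * Inf, NaN),
      sign * (1 + frac / 1024) * 2^(expo - 15)
    )
  )
  val
}

read_mrc_header <- function(raw_hdr) {
  endian <- "little"
  machst <- as.integer(raw_hdr[213:214])
  if (identical(machst, c(17L, 17L))) endian <- "big"
  ints <- readBin(raw_hdr, "integer", n = 256L, size = 4L, endian = endian)
  flts <- readBin(raw_hdr, "numeric", n = 256L, size = 4L, endian = endian)
  list(
    nx = ints[1], ny = ints[2], nz = ints[3],
    mode = ints[4],
    mx = ints[8], my = ints[9], mz = ints[10],
    xlen = flts[11], ylen = flts[12], zlen = flts[13],
    nsymbt = ints[24],
    map = rawToChar(raw_hdr[209:212]),
    endian = endian
  )
}

read_mrc_volume <- function(path) {
  if (!file.exists(path)) {
    stop("MRC file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = MRC_HEADER_BYTES)
  if (length(raw_hdr) < MRC_HEADER_BYTES) {
    stop("file too short to contain an MRC header: ", path, call. = FALSE)
  }
  h <- read_mrc_header(raw_hdr)
  if (h$nx < 1 || h$ny < 1 || h$nz < 1) {
    stop("invalid MRC dimensions (", h$nx, ", ", h$ny, ", ", h$nz, ")",
         call. = FALSE)
  }
  if (h$nz == 1L) {
    stop("not a 3D volume: file has a single section (2D image)", call. = FALSE)
  }
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  n <- as.numeric(h$nx) * h$ny * h$nz
  vec <- switch(
    as.character(h$mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                            endian = h$endian)),
    "1" = as.double(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                            endian = h$endian)),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = h$endian),
    "12" = half_to_double(readBin(con, "integer", n = n, size = 2L,
                                  signed = FALSE, endian = h$endian)),
    stop("unsupported MRC mode ", h$mode,
         " (supported: 0, 1, 2, 12)", call. = FALSE)
  )
  if (length(vec) < n) {
    stop("MRC data truncated: expected ", n, " voxels, read ", length(vec),
         call. = FALSE)
  }
  vox <- aperm(array(vec, dim = c(h$nx, h$ny, h$nz)), c(3L, 2L, 1L))
  voxel_size <- NULL
  if (h$mx > 0 && is.finite(h$xlen) && h$xlen > 0) {
    voxel_size <- h$xlen / h$mx
  }
  list(voxels = vox, voxel_size = voxel_size)
}

write_mrc_volume <- function(path, vox, mode = 2L, voxel_size = NULL) {
  stopifnot(length(dim(vox)) == 3L, mode %in% c(0L, 1L, 2L))
  d <- dim(vox)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  vs <- if (is.null(voxel_size)) 1 else voxel_size
  dat <- as.vector(aperm(vox, c(3L, 2L, 1L)))

  hdr_int <- integer(256)
  hdr_dbl <- numeric(256)
  hdr_int[1:4] <- c(nx, ny, nz, mode)
  hdr_int[8:10] <- c(nx, ny, nz)
  hdr_dbl[11:13] <- c(nx, ny, nz) * vs
  hdr_dbl[14:16] <- 90                       # cell angles
  hdr_int[17:19] <- c(1L, 2L, 3L)            # mapc, mapr, maps
  hdr_dbl[20:22] <- c(min(dat), max(dat), mean(dat))
  hdr_int[23] <- 1L                          # ispg: volume
  hdr_dbl[55] <- stats::sd(dat)              # rms

  raw_hdr <- raw(MRC_HEADER_BYTES)
  int_words <- c(1:10, 17:19, 23, 24)
  for (w in int_words) {
    raw_hdr[(4 * w - 3):(4 * w)] <- writeBin(hdr_int[w], raw(), size = 4L,
                                             endian = "little")
  }
  dbl_words <- c(11:16, 20:22, 55)
  for (w in dbl_words) {
    raw_hdr[(4 * w - 3):(4 * w)] <- writeBin(hdr_dbl[w], raw(), size = 4L,
                                             endian = "little")
  }
  raw_hdr[209:212] <- charToRaw("MAP ")
  raw_hdr[213:216] <- as.raw(c(0x44, 0x44, 0x00, 0x00))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw_hdr, con)
  if (mode == 0L) {
    writeBin(as.integer(dat), con, size = 1L)
  } else if (mode == 1L) {
    writeBin(as.integer(dat), con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(dat), con, size = 4L, endian = "little")
  }
  invisible(NULL)
}
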