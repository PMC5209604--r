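# MRC2014 I/O. The header is 1024 bytes of 4-byte words; data follow
# immediately (no extended header is written; one is skipped on read via
# NSYMBT). Only little-endian files with axis order MAPC,MAPR,MAPS = 1,2,3
# are handled, and only an isotropic voxel size is accepted.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC/CCP4 density map
#'
#' Reads an MRC2014-format map (modes 0, 1, 2 and 6; integer modes are
#' promoted to double). The voxel size is taken from the cell dimensions
#' divided by the grid sampling and must be isotropic. The origin is taken
#' from the ORIGIN header record; if that record is all zero but NXSTART /
#' NYSTART / NZSTART are not, the start indices times the voxel size are used
#' instead.
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A [density_map].
#' @seealso [write_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) < MRC_HEADER_BYTES)
    stop("not an MRC file (shorter than the 1024-byte header): ", path,
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # cell angles
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", 1, size = 4, endian = "little")  # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "raw", 100)                                 # extra (words 25-49)
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  map_id <- readChar(con, 4, useBytes = TRUE)

  if (any(nxyz < 1L) || any(nxyz > 1e5) || mode < 0L)
    stop("unreadable MRC header in ", path, call. = FALSE)
  if (nchar(map_id) == 4 && map_id != "MAP ")
    stop("unreadable MRC header (bad MAP stamp) in ", path, call. = FALSE)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported axis order (MAPC,MAPR,MAPS must be 1,2,3)", call. = FALSE)

  mxyz[mxyz == 0L] <- nxyz[mxyz == 0L]
  vox <- cella / mxyz
  if (any(vox <= 0))
    vox <- rep(1, 3)  # headerless cell: fall back to unit voxels
  if (diff(range(vox)) > 1e-4 * max(vox))
    stop("anisotropic voxel size not supported (", paste(signif(vox, 6),
         collapse = " x "), " A)", call. = FALSE)
  voxel_size <- mean(vox)
  if (all(origin == 0) && any(nstart != 0L))
    origin <- nstart * voxel_size

  nvox <- prod(as.double(nxyz))
  seek(con, MRC_HEADER_BYTES + max(nsymbt, 0L))
  values <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.double(readBin(con, "integer", nvox, size = 2, signed = TRUE,
                            endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    "6" = as.double(readBin(con, "integer", nvox, size = 2, signed = FALSE,
                            endian = "little")),
    stop("unsupported MRC data mode: ", mode, call. = FALSE))
  if (length(values) < nvox)
    stop("truncated MRC data section in ", path, call. = FALSE)
  density_map(array(values, dim = nxyz), voxel_size = voxel_size,
              origin = origin)
}

#' Write a density map as MRC2014 (mode 2, float32)
#'
#' Cell dimensions are written as `dims * voxel_size`, the grid sampling
#' equals the grid size, and the physical origin goes into the ORIGIN record.
#'
#' @param map A [density_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  d <- map$dims
  vals <- as.vector(map$data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  wi(d)                        # nx ny nz
  wi(2L)                       # mode 2 = float32
  wi(c(0L, 0L, 0L))            # nxstart nystart nzstart
  wi(d)                        # mx my mz
  wf(d * map$voxel_size)       # cell dimensions (A)
  wf(c(90, 90, 90))            # cell angles
  wi(c(1L, 2L, 3L))            # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))                # ispg, nsymbt
  writeBin(raw(100), con)      # extra words 25-49
  wf(map$origin)               # origin x y z
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(vals))          # rms
  wi(0L)                       # nlabl
  writeBin(raw(800L), con)     # labels
  wf(vals)
  invisible(path)
}
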