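#' Read an MRC/CCP4 density map
#'
#' Reads an MRC2014 / CCP4 volume into the package's canonical axis
#' convention: the returned value array is indexed `[x, y, z]` regardless of
#' the file's MAPC/MAPR/MAPS axis permutation. Voxel spacing is taken as
#' `CELLA / (MX, MY, MZ)`; the grid origin (center of voxel (0,0,0)) is taken
#' from the ORIGIN header words when any are nonzero, otherwise from the
#' NXSTART-style words times the spacing.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_map()] (mask unset).
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) < 1024) stop("file too small to hold an MRC header: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  invisible(readBin(con, "integer", n = 25, size = 4, endian = "little"))
  origin_hdr <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  invisible(readBin(con, "raw", n = 4))                       # MACHST
  invisible(readBin(con, "numeric", n = 1, size = 4, endian = "little"))
  invisible(readBin(con, "raw", n = 1024 - 224))              # NLABL + labels

  n_crs <- ints1[1:3]; mode <- ints1[4]
  nstart_crs <- ints1[5:7]; m_xyz <- ints1[8:10]
  if (any(n_crs < 1) || any(!mapcrs %in% 1:3) || anyDuplicated(mapcrs))
    stop("corrupt MRC header in ", path)
  if (!grepl("^MAP", map_tag))
    warning("missing 'MAP ' tag in ", path, "; attempting to read anyway")

  nvox <- prod(as.double(n_crs))
  seek(con, where = 1024 + max(0L, ispg_nsym[2]), origin = "start")
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, " (non-volumetric or complex)"))
  if (length(vals) != nvox) stop("truncated MRC data in ", path)

  file_arr <- array(vals, dim = n_crs)           # dims in column/row/section order
  canon <- aperm(file_arr, match(1:3, mapcrs))   # dims in x/y/z order
  shape_xyz <- dim(canon)

  if (any(m_xyz < 1)) m_xyz <- shape_xyz
  spacing <- cella / m_xyz
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  nstart_xyz <- integer(3); nstart_xyz[mapcrs] <- nstart_crs
  origin <- if (any(origin_hdr != 0)) origin_hdr else nstart_xyz * spacing

  density_map(grid_spec(origin = origin, spacing = spacing, shape = shape_xyz),
              canon)
}

#' Write a density map as MRC/CCP4
#'
#' Writes mode-2 (float32) MRC2014 with ISPG = 1, full cell parameters
#' (`CELLA = spacing * shape`), and the origin recorded both in the ORIGIN
#' words and in the NXSTART-style words (rounded to voxels).
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @param axis_order integer(3), the MAPC/MAPR/MAPS permutation to write
#'   (default `c(1, 2, 3)`, i.e. x fastest). Other permutations are mainly
#'   useful for interoperability testing; [read_map()] canonicalizes them.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, axis_order = c(1L, 2L, 3L)) {
  stopifnot(inherits(map, "density_map"))
  axis_order <- as.integer(axis_order)
  if (!all(sort(axis_order) == 1:3)) stop("axis_order must be a permutation of 1:3")
  g <- map$grid
  file_arr <- aperm(map$values, axis_order)
  n_crs <- dim(file_arr)
  nstart_xyz <- as.integer(round(g$origin / g$spacing))
  nstart_crs <- nstart_xyz[axis_order]

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n_crs); wi(2L)                         # NX NY NZ, MODE
  wi(nstart_crs); wi(g$shape)               # NxSTART, MX MY MZ
  wf(g$spacing * g$shape); wf(c(90, 90, 90))  # CELLA, CELLB
  wi(axis_order)                            # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(1L, 0L))                             # ISPG, NSYMBT
  wi(rep(0L, 2)); writeBin(charToRaw("MRCO"), con); wi(20140L)  # EXTTYP, NVERSION
  wi(rep(0L, 21))                           # remaining extra words
  wf(g$origin)                              # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(map$values))
  wi(0L)                                    # NLABL
  writeBin(raw(800), con)                   # labels
  wf(as.numeric(file_arr))
  invisible(path)
}
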