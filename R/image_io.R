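#' Read a 3D scalar volume from NIfTI or MetaImage
#'
#' Supports `.nii`/`.nii.gz` (via RNifti) and `.mha`/`.mhd` MetaImage files.
#' Only axis-aligned geometry is accepted; an oblique direction matrix is an
#' error. World coordinates follow the grid convention of [volume3d()].
#'
#' @param path file path.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  if (is_metaimage(path)) {
    m <- read_metaimage(path)
    if (m$channels != 1L)
      stop("read_volume: expected scalar image, got ", m$channels, " channels")
    if (length(dim(m$data)) != 3L)
      stop("read_volume: expected a 3D volume, got ", length(dim(m$data)),
           " dimensions")
    return(volume3d(m$data, spacing = m$spacing, origin = m$origin))
  }
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img, path)
  a <- plain_array(img)
  a <- drop_trailing_units(a)
  if (length(dim(a)) != 3L)
    stop("read_volume: expected a 3D volume, got ", length(dim(a)),
         " non-singleton dimensions in ", path)
  volume3d(a, spacing = geo$spacing, origin = geo$origin)
}

#' Write a 3D scalar volume
#' @param vol a [volume3d()].
#' @param path destination; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (is_metaimage(path)) {
    write_metaimage(vol$data, vol$spacing, vol$origin, path)
  } else {
    write_nifti_geom(vol$data, vol$spacing, vol$origin, path)
  }
  invisible(path)
}

#' Read a 3-component displacement field
#'
#' Vector NIfTI images are stored as 5D (nx, ny, nz, 1, 3); MetaImage as
#' 3-channel voxel data. Displacements are in mm along world axes and are
#' backward-mapping (see [vectorfield3d()]).
#'
#' @param path file path.
#' @return A [vectorfield3d()].
#' @export
read_dvf <- function(path) {
  if (!file.exists(path)) stop("read_dvf: file not found: ", path)
  if (is_metaimage(path)) {
    m <- read_metaimage(path)
    if (m$channels != 3L)
      stop("read_dvf: expected 3 vector components, got ", m$channels)
    return(vectorfield3d(m$data, spacing = m$spacing, origin = m$origin))
  }
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img, path)
  a <- plain_array(img)
  d <- dim(a)
  if (length(d) == 5L && d[4] == 1L) { dim(a) <- d[c(1:3, 5)]; d <- dim(a) }
  if (length(d) != 4L || d[4] != 3L)
    stop("read_dvf: expected 3 vector components, got dims ",
         paste(d, collapse = "x"))
  vectorfield3d(a, spacing = geo$spacing, origin = geo$origin)
}

#' Write a 3-component displacement field
#' @param field a [vectorfield3d()].
#' @param path destination (`.nii`, `.nii.gz`, `.mha`).
#' @return `path`, invisibly.
#' @export
write_dvf <- function(field, path) {
  stopifnot(inherits(field, "vectorfield3d"))
  if (is_metaimage(path)) {
    write_metaimage(field$u, field$spacing, field$origin, path, channels = 3L)
  } else {
    u <- field$u
    dim(u) <- c(dim(u)[1:3], 1L, 3L)
    write_nifti_geom(u, field$spacing, field$origin, path, intent = 1007L)
  }
  invisible(path)
}

#' Read / write landmark tables
#'
#' Landmarks are 2D in-plane positions on cine frames, one row per
#' (landmark, frame), with columns `id, plane, frame, x_mm, y_mm`. Plane is
#' `"sagittal"` or `"coronal"`; frame indices are 0-based.
#'
#' @param path CSV file path.
#' @return A data.frame with the columns above.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("read_landmarks: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("read_landmarks: empty landmark file ", path)
    return(data.frame(id = character(), plane = character(),
                      frame = integer(), x_mm = numeric(), y_mm = numeric()))
  }
  need <- c("id", "plane", "frame", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("read_landmarks: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$plane), c("sagittal", "coronal"))
  if (length(bad))
    stop("read_landmarks: unknown plane label(s): ", paste(bad, collapse = ", "))
  df[need]
}

#' @rdname read_landmarks
#' @param landmarks data.frame with columns `id, plane, frame, x_mm, y_mm`.
#' @export
write_landmarks <- function(landmarks, path) {
  bad <- setdiff(unique(landmarks$plane), c("sagittal", "coronal"))
  if (length(bad))
    stop("write_landmarks: unknown plane label(s): ", paste(bad, collapse = ", "))
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

# ---- NIfTI helpers -----------------------------------------------------

# strip RNifti image attributes down to a plain numeric array
plain_array <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim(a))
}

write_nifti_geom <- function(arr, spacing, origin, path, intent = 0L) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  xf <- diag(c(spacing, 1))
  xf[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
}

nifti_geometry <- function(img, path) {
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
    stop("unsupported geometry: oblique direction matrix in ", path,
         " (only axis-aligned volumes are supported)")
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  list(spacing = spacing, origin = xf[1:3, 4])
}

drop_trailing_units <- function(a) {
  d <- dim(a)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(a) <- d
  }
  a
}

# ---- MetaImage (.mha/.mhd) ---------------------------------------------

is_metaimage <- function(path) grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_metaimage: no ElementDataFile in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, ndims)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, ndims)
  channels <- if (!is.null(hdr$ElementNumberOfChannels))
    as.integer(hdr$ElementNumberOfChannels) else 1L
  type <- hdr$ElementType
  n <- prod(dims) * channels
  raw_reader <- switch(type,
    MET_DOUBLE = function(c) readBin(c, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = function(c) readBin(c, "double", n, size = 4, endian = "little"),
    MET_SHORT  = function(c) readBin(c, "integer", n, size = 2, endian = "little"),
    MET_USHORT = function(c) readBin(c, "integer", n, size = 2, signed = FALSE,
                                     endian = "little"),
    MET_UCHAR  = function(c) readBin(c, "integer", n, size = 1, signed = FALSE),
    stop("read_metaimage: unsupported ElementType ", type))
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("read_metaimage: only ElementDataFile = LOCAL is supported")
  vals <- as.numeric(raw_reader(con))
  if (length(vals) != n)
    stop("read_metaimage: truncated data in ", path)
  # channel-interleaved on disk -> (dims..., channels)
  if (channels > 1L) {
    a <- array(vals, c(channels, dims))
    a <- aperm(a, c(seq_len(ndims) + 1L, 1L))
  } else {
    a <- array(vals, dims)
  }
  list(data = a, spacing = spacing, origin = origin, channels = channels)
}

write_metaimage <- function(arr, spacing, origin, path, channels = 1L) {
  dims <- dim(arr)
  if (channels > 1L) {
    ndims <- length(dims) - 1L
    stopifnot(dims[length(dims)] == channels)
    arr <- aperm(arr, c(length(dims), seq_len(ndims)))
    dims <- dims[seq_len(ndims)]
  } else ndims <- length(dims)
  hdr <- c(
    "ObjectType = Image",
    paste0("NDims = ", ndims),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("DimSize = ", paste(dims, collapse = " ")),
    paste0("ElementSpacing = ", paste(format(spacing, digits = 17), collapse = " ")),
    paste0("Offset = ", paste(format(origin, digits = 17), collapse = " ")),
    if (channels > 1L) paste0("ElementNumberOfChannels = ", channels),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}
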