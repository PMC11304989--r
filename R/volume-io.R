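#' Read a CT volume from disk
#'
#' Supports MetaImage (`.mhd` with a companion `.raw`) and NIfTI
#' (`.nii` / `.nii.gz`). Geometry (spacing, origin) is taken from the file
#' header; the voxel grid is returned in `(z, y, x)` axis order. Files with
#' non-identity direction cosines are rejected: the package's coordinate
#' model assumes axis-aligned LPS geometry throughout.
#'
#' @param path Path to a `.mhd`, `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
#' @seealso [write_volume()]
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("volume file not found: ", path, call. = FALSE)
  }
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", basename(path)))
  switch(ext,
    ".mhd" = read_mhd(path),
    ".nii" = ,
    ".nii.gz" = read_nifti_volume(path),
    stop("unsupported volume format: ", basename(path),
         " (expected .mhd, .nii or .nii.gz)", call. = FALSE)
  )
}

#' Write a CT volume to disk
#'
#' The inverse of [read_volume()]. MetaImage output stores voxels as 32-bit
#' IEEE floats (`MET_FLOAT`) in little-endian order, which preserves
#' normalized intensities in `[-1, 1]` without clipping; NIfTI output goes
#' through the RNifti writer with float32 storage.
#'
#' @param vol A [ct_volume()].
#' @param path Destination path ending in `.mhd`, `.nii` or `.nii.gz`. For
#'   MetaImage the `.raw` payload is written next to the header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_ct_volume(vol))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", basename(path)))
  switch(ext,
    ".mhd" = write_mhd(vol, path),
    ".nii" = ,
    ".nii.gz" = write_nifti_volume(vol, path),
    stop("unsupported volume format: ", basename(path), call. = FALSE)
  )
  invisible(path)
}

# --- MetaImage ---------------------------------------------------------------
# Minimal MHD dialect: text header with `Key = Value` lines plus a raw
# little-endian payload. DimSize/ElementSpacing/Offset are in (x, y, z) order
# in the header, flipped to the internal (z, y, x) on read.

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[lengths(kv) >= 2L]
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  hdr <- stats::setNames(vals, keys)

  need <- function(field) {
    if (is.na(hdr[field]) || !nzchar(hdr[field])) {
      stop("MetaImage header missing field `", field, "` in ", path,
           call. = FALSE)
    }
    hdr[[field]]
  }
  num3 <- function(field) {
    v <- as.numeric(strsplit(need(field), "[[:space:]]+")[[1]])
    if (length(v) != 3L || any(is.na(v))) {
      stop("MetaImage field `", field, "` must hold 3 numbers in ", path,
           call. = FALSE)
    }
    v
  }

  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L)) {
    stop("only 3D MetaImage volumes are supported (NDims = ", ndims, ")",
         call. = FALSE)
  }
  if (!is.na(hdr["TransformMatrix"])) {
    tm <- as.numeric(strsplit(hdr[["TransformMatrix"]], "[[:space:]]+")[[1]])
    if (!isTRUE(all(abs(tm - as.vector(diag(3))) < 1e-9))) {
      stop("non-identity direction cosines are not supported (TransformMatrix)",
           call. = FALSE)
    }
  }
  dim_xyz <- as.integer(num3("DimSize"))
  spacing_xyz <- num3("ElementSpacing")
  origin_xyz <- if (!is.na(hdr["Offset"])) num3("Offset") else c(0, 0, 0)
  etype <- need("ElementType")
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    stop("embedded (LOCAL) MetaImage payloads are not supported", call. = FALSE)
  }
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) {
    stop("MetaImage payload not found: ", raw_path, call. = FALSE)
  }

  type_info <- switch(etype,
    MET_FLOAT = list(what = "numeric", size = 4L),
    MET_DOUBLE = list(what = "numeric", size = 8L),
    MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
    MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
    stop("unsupported ElementType: ", etype, call. = FALSE)
  )
  n <- prod(dim_xyz)
  expected_bytes <- n * type_info$size
  actual_bytes <- file.info(raw_path)$size
  if (actual_bytes < expected_bytes) {
    stop("truncated MetaImage payload: ", raw_path, " holds ", actual_bytes,
         " bytes, header promises ", expected_bytes, call. = FALSE)
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = type_info$what, n = n, size = type_info$size,
                  signed = isTRUE(type_info$signed) || type_info$size > 2L,
                  endian = "little")
  # raw payload is x-fastest; fill (x, y, z) then permute to (z, y, x)
  arr_xyz <- array(as.numeric(vals), dim = dim_xyz)
  data <- aperm(arr_xyz, c(3, 2, 1))
  ct_volume(data, spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}

write_mhd <- function(vol, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(vol$data)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format_g(rev(vol$origin)), collapse = " ")),
    paste("ElementSpacing =", paste(format_g(rev(vol$spacing)), collapse = " ")),
    paste("DimSize =", paste(rev(d), collapse = " ")),
    "ElementType = MET_FLOAT",
    paste("ElementDataFile =", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(vol$data, c(3, 2, 1))), con, size = 4L,
           endian = "little")
}

format_g <- function(x) formatC(x, format = "g", digits = 17)

# --- NIfTI -------------------------------------------------------------------
# RNifti stores arrays (x, y, z)-fastest; permute to the internal (z, y, x).

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("only 3D NIfTI volumes are supported: ", path, call. = FALSE)
  }
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3L || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0)) {
    stop("NIfTI header missing valid pixdim in ", path, call. = FALSE)
  }
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  scaled <- abs(rot) / pmax(pix[1:3], .Machine$double.eps)
  if (!isTRUE(all(abs(scaled - diag(3)) < 1e-6))) {
    stop("non-identity direction cosines are not supported in ", path,
         call. = FALSE)
  }
  # qform/sform translation, sign-folded to LPS-style axis-aligned offsets
  origin_xyz <- as.numeric(xf[1:3, 4]) * sign(diag(rot))
  data <- aperm(as.array(img), c(3, 2, 1))
  ct_volume(data, spacing = rev(pix[1:3]), origin = rev(origin_xyz))
}

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(3, 2, 1))
  sp <- rev(vol$spacing)
  org <- rev(vol$origin)
  attr(arr, "pixdim") <- sp   # must be set before conversion
  img <- RNifti::asNifti(arr, datatype = "float")
  xf <- diag(4)
  diag(xf)[1:3] <- sp
  xf[1:3, 4] <- org
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
}
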