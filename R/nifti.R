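#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, `.nii.gz`),
#' preserving the voxel-to-world affine via the sform. Only 3D scalar
#' volumes are supported; this is deliberately a minimal implementation for
#' the formats the pipeline itself produces plus the common scalar
#' datatypes (uint8, int16, int32, float32, float64).
#'
#' @param path file path; gzip is inferred from the `.gz` suffix.
#' @param space space tag to attach to the returned volume.
#' @return `read_nifti` returns a `vol3d`.
#' @export
read_nifti <- function(path, space = c("native", "template")) {
  space <- match.arg(space)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  rd <- function(what, n, off, size, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (rd("integer", 1, 0, 4, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 0, 4, endian) != 348L)
      stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported")
  dims <- rd("integer", 8, 40, 2, endian)
  if (dims[1] < 3 || any(dims[5:8][seq_len(max(0, dims[1] - 3))] > 1))
    if (dims[1] > 3 && any(dims[5:(dims[1] + 1)] > 1))
      stop("only 3D volumes are supported")
  d <- pmax(dims[2:4], 1L)
  datatype <- rd("integer", 1, 70, 2, endian)
  pixdim <- rd("numeric", 8, 76, 4, endian)
  vox_offset <- rd("numeric", 1, 108, 4, endian)
  scl_slope <- rd("numeric", 1, 112, 4, endian)
  scl_inter <- rd("numeric", 1, 116, 4, endian)
  sform_code <- rd("integer", 1, 254, 2, endian)
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vals) < n) stop("truncated NIfTI data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  v2w <- diag(4)
  if (sform_code > 0) {
    v2w[1, ] <- rd("numeric", 4, 280, 4, endian)
    v2w[2, ] <- rd("numeric", 4, 296, 4, endian)
    v2w[3, ] <- rd("numeric", 4, 312, 4, endian)
  } else {
    diag(v2w)[1:3] <- abs(pixdim[2:4])
  }
  vs <- sqrt(colSums(v2w[1:3, 1:3]^2))
  vol3d(array(vals, d), voxel_size = vs, v2w = v2w, space = space)
}

#' @rdname read_nifti
#' @param img `vol3d` to write.
#' @param datatype `"float32"` (images) or `"uint8"` (binary masks).
#' @return `write_nifti` returns `path` invisibly.
#' @export
write_nifti <- function(img, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(img, "vol3d"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  hdr <- raw(348)
  put <- function(hdr, x, off, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  d <- dim(img$data)
  hdr <- put(hdr, 348L, 0, 4)
  hdr <- put(hdr, c(3L, d, 1L, 1L, 1L, 1L), 40, 2)
  dtcode <- if (datatype == "float32") c(16L, 32L) else c(2L, 8L)
  hdr <- put(hdr, dtcode[1], 70, 2)
  hdr <- put(hdr, dtcode[2], 72, 2)
  hdr <- put(hdr, c(1, img$voxel_size, 1, 1, 1, 1), 76, 4, "double")
  hdr <- put(hdr, 352, 108, 4, "double")   # vox_offset
  hdr <- put(hdr, 1, 112, 4, "double")     # scl_slope
  hdr <- put(hdr, 0, 116, 4, "double")     # scl_inter
  hdr <- put(hdr, 0L, 252, 2)              # qform_code
  hdr <- put(hdr, 2L, 254, 2)              # sform_code (aligned)
  hdr <- put(hdr, img$v2w[1, ], 280, 4, "double")
  hdr <- put(hdr, img$v2w[2, ], 296, 4, "double")
  hdr <- put(hdr, img$v2w[3, ], 312, 4, "double")
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  writeBin(hdr, con)
  writeBin(raw(4), con)  # extension flag
  if (datatype == "float32") {
    writeBin(as.numeric(img$data), con, size = 4, endian = "little")
  } else {
    vals <- as.integer(round(img$data))
    if (any(vals < 0 | vals > 255)) stop("uint8 output requires values 0..255")
    writeBin(vals, con, size = 1, endian = "little")
  }
  invisible(path)
}
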