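# Minimal MetaImage (.mha, local data) reader/writer for HU grids and masks.
# ASCII key = value header followed by a raw little-endian voxel block
# (MET_SHORT for HU, MET_UCHAR for masks), x fastest as in the standard.

#' Write an HU grid or mask to a MetaImage (.mha) file
#'
#' @param x An `hu_grid`, or a logical/integer 3-D array (written as
#'   MET_UCHAR mask when logical).
#' @param path Output file path.
#' @param spacing,origin Geometry when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_mha <- function(x, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(x, "hu_grid")) {
    vals <- x$values; spacing <- x$spacing; origin <- x$origin
    type <- "MET_SHORT"; size <- 2L
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (is.logical(x)) {
      vals <- array(as.integer(x), dim(x)); type <- "MET_UCHAR"; size <- 1L
    } else {
      vals <- x; type <- "MET_SHORT"; size <- 2L
    }
  } else {
    stop_invalid("x must be an hu_grid or a 3-D array")
  }
  d <- dim(vals)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(origin, scientific = FALSE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %s", paste(format(spacing, scientific = FALSE), collapse = " ")),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", type),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(vals), con, size = size, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mha) file written by [write_mha()]
#'
#' @param path File path.
#' @param as What to return: an `hu_grid` (MET_SHORT) or a logical `mask`
#'   (MET_UCHAR); `"auto"` picks by element type.
#' @return An `hu_grid` or a logical array with attributes `spacing`, `origin`.
#' @export
read_mha <- function(path, as = c("auto", "grid", "mask")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop_invalid("truncated MetaImage header in %s", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop_invalid("malformed MetaImage header line: %s", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL")) {
    stop_invalid("only ElementDataFile = LOCAL is supported")
  }
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  if (identical(type, "MET_SHORT")) {
    raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
    if (as == "mask") stop_invalid("%s holds MET_SHORT, not a mask", path)
    hu_grid(array(raw, dims), spacing, origin)
  } else if (identical(type, "MET_UCHAR")) {
    raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE, endian = "little")
    if (as == "grid") stop_invalid("%s holds MET_UCHAR, not an HU grid", path)
    structure(array(raw > 0L, dims), spacing = spacing, origin = origin)
  } else {
    stop_invalid("unsupported ElementType: %s", type)
  }
}
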