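#' Read a pattern or field from disk
#'
#' 2D patterns are read from PNG or TIFF images; color images load as 3-band
#' patterns, 8-bit channels are mapped back to the integer range `[0, 255]`
#' (16-bit to `[0, 65535]`). 3D fields use a simple language-portable
#' container: a flat little-endian binary array (`.bin`, int32 or float64)
#' next to a plain-text `.meta` sidecar holding `shape`, `dtype`,
#' `value_range`, and optionally `iteration`.
#'
#' @param path file path. For `kind = "field"` either the `.bin` or the
#'   `.meta` file may be named.
#' @param kind `"image"` (2D raster) or `"field"` (3D voxel array).
#' @return a [grid_pattern()].
#' @seealso [write_pattern()]
#' @export
read_pattern <- function(path, kind = c("image", "field")) {
  kind <- match.arg(kind)
  if (!file.exists(path) && kind == "image")
    stop("cannot read '", path, "': no such file", call. = FALSE)
  if (kind == "image") read_image_pattern(path) else read_field_pattern(path)
}

read_image_pattern <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    img <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)", call. = FALSE)
  }
  # readPNG/readTIFF normalize to [0,1]; recover the integer code values
  depth <- attr(img, "bitdepth")
  maxv <- if (!is.null(depth)) 2^depth - 1 else 255
  img <- round(img * maxv)
  if (length(dim(img)) == 2L) {
    grid_pattern(img, value_range = c(0, maxv))
  } else {
    nb <- dim(img)[3]
    if (nb == 4L) { img <- img[, , 1:3, drop = FALSE]; nb <- 3L }  # drop alpha
    bands <- lapply(seq_len(nb), function(b) img[, , b])
    nms <- if (nb == 3L) c("red", "green", "blue") else NULL
    grid_pattern(bands, value_range = c(0, maxv), band_names = nms)
  }
}

field_paths <- function(path) {
  base <- sub("\\.(bin|meta)$", "", path)
  list(bin = paste0(base, ".bin"), meta = paste0(base, ".meta"))
}

read_field_pattern <- function(path) {
  fp <- field_paths(path)
  if (!file.exists(fp$meta))
    stop("missing metadata sidecar '", fp$meta, "'", call. = FALSE)
  meta <- read_meta_file(fp$meta)
  shape <- as.integer(strsplit(meta[["shape"]], "[ ,x]+")[[1]])
  if (length(shape) != 3L)
    stop("field metadata declares a non-3D shape", call. = FALSE)
  dtype <- meta[["dtype"]]
  n <- prod(shape)
  con <- file(fp$bin, "rb"); on.exit(close(con))
  vals <- switch(dtype,
    int32   = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unsupported dtype '", dtype, "'", call. = FALSE)
  )
  if (length(vals) != n) stop("field file shorter than declared shape", call. = FALSE)
  arr <- array(as.numeric(vals), dim = shape)
  vr <- if (!is.null(meta[["value_range"]]))
    as.numeric(strsplit(meta[["value_range"]], "[ ,]+")[[1]]) else NULL
  p <- grid_pattern(arr, value_range = vr)
  if (!is.null(meta[["iteration"]])) attr(p, "iteration") <- as.integer(meta[["iteration"]])
  p
}

read_meta_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(x) trimws(paste(x[-1], collapse = ":")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1))
  vals
}

#' Write a pattern or field to disk
#'
#' 2D patterns are written as PNG (integer values are scaled into the 8- or
#' 16-bit code range implied by `value_range`); 3D fields as the flat-binary
#' container described in [read_pattern()]. Integer patterns round-trip
#' bit-exactly.
#'
#' @param pattern a [grid_pattern()].
#' @param path output path; extension `.png` for images, `.bin` for fields.
#' @param iteration optional iteration index recorded in a field's metadata.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path, iteration = NULL) {
  stopifnot(is_grid_pattern(pattern))
  if (grid_dim(pattern) == 2L) {
    maxv <- max(pattern$value_range[, 2])
    bits <- if (maxv > 255) 16L else 8L
    top <- 2^bits - 1
    arr <- simplify2array(pattern$bands)
    if (n_bands(pattern) == 1L) dim(arr) <- grid_shape(pattern)
    png::writePNG(arr / top, target = path)
  } else {
    if (n_bands(pattern) != 1L)
      stop("3D field output supports a single band", call. = FALSE)
    fp <- field_paths(path)
    v <- pattern$bands[[1]]
    integral <- is_integer_quantized(pattern) && max(abs(v)) < 2^31
    con <- file(fp$bin, "wb")
    if (integral) writeBin(as.integer(v), con, size = 4L, endian = "little")
    else writeBin(as.numeric(v), con, size = 8L, endian = "little")
    close(con)
    meta <- c(
      paste("shape:", paste(dim(v), collapse = " ")),
      paste("dtype:", if (integral) "int32" else "float64"),
      paste("value_range:", paste(pattern$value_range[1, ], collapse = " "))
    )
    if (!is.null(iteration)) meta <- c(meta, paste("iteration:", iteration))
    writeLines(meta, fp$meta)
  }
  invisible(path)
}
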