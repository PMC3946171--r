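# Readers and writers for the toolkit's formats: single-channel TIFFs
# (one file per stain, as exported by spectral-unmixing software), 16-bit
# label-map TIFFs, CSV feature tables and JSON models/reports.

#' Read / write a single-channel image
#'
#' Channels are stored one file per stain as single-channel TIFFs holding
#' integer gray values at the stated bit depth. `read_channel()` returns the
#' integer gray values as a numeric matrix; the write/read roundtrip is
#' lossless.
#'
#' @param path TIFF (or PNG for reading) file path.
#' @param image numeric matrix of integer gray values.
#' @param bit_depth 8 or 16.
#' @return `read_channel()`: numeric matrix; `write_channel()`: the path,
#'   invisibly.
#' @export
read_channel <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("Reading PNG requires the png package.", call. = FALSE)
    }
    m <- png::readPNG(path)
    round(m * 255)
  } else {
    m <- tiff::readTIFF(path, as.is = TRUE)
    m
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L) {
      stop("Expected a single-channel image: ", path, call. = FALSE)
    }
    img <- img[, , 1L]
  }
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @rdname read_channel
#' @export
write_channel <- function(image, path, bit_depth = 8) {
  if (!bit_depth %in% c(8, 16)) {
    stop("`bit_depth` must be 8 or 16.", call. = FALSE)
  }
  max_gray <- 2^bit_depth - 1
  if (any(image < 0 | image > max_gray)) {
    stop("Image values exceed the bit depth.", call. = FALSE)
  }
  tiff::writeTIFF(round(image) / max_gray, path,
                  bits.per.sample = bit_depth, compression = "none")
  invisible(path)
}

#' Read a named set of channels into a multi-channel image
#'
#' All channel files must have identical shapes.
#'
#' @param channel_paths named character vector (channel name -> file path).
#' @param pixel_size_um physical pixel size (0.25 um/px at 400X).
#' @return list of class `mc_image`: `channels` (named list of matrices) and
#'   `pixel_size_um`.
#' @export
read_channels <- function(channel_paths, pixel_size_um = 0.25) {
  if (is.null(names(channel_paths)) || any(names(channel_paths) == "")) {
    stop("`channel_paths` must be a named vector.", call. = FALSE)
  }
  if (anyDuplicated(names(channel_paths))) {
    stop("Channel names must be unique.", call. = FALSE)
  }
  channels <- lapply(channel_paths, read_channel)
  shapes <- vapply(channels, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1L) {
    stop("Channel shape mismatch: ",
         paste(sprintf("%s (%s)", names(shapes), shapes), collapse = ", "),
         call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "mc_image")
}

#' Read / write a label map as a 16-bit TIFF
#'
#' @param labels integer label map (ids up to 65535).
#' @param path file path.
#' @return `read_label_map()`: integer matrix; `write_label_map()`: the path,
#'   invisibly.
#' @export
write_label_map <- function(labels, path) {
  write_channel(labels, path, bit_depth = 16)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- read_channel(path)
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

#' Read / write a feature table as CSV
#'
#' The header starts with `cell_id, image_id` (plus optional `cluster_id`,
#' `label`), followed by feature columns. Floating-point values are written
#' with 15 significant digits so the roundtrip is lossless to the printed
#' precision. Duplicate (image_id, cell_id) keys and malformed headers are
#' errors.
#'
#' @param data feature table.
#' @param path CSV file path.
#' @return `read_feature_table()`: tibble; `write_feature_table()`: the path,
#'   invisibly.
#' @export
write_feature_table <- function(data, path) {
  lead <- intersect(c("cell_id", "image_id", "cluster_id", "label"),
                    names(data))
  data <- data[, c(lead, setdiff(names(data), lead))]
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"cell_id" %in% names(out)) {
    stop("Malformed feature table: no `cell_id` column in ", path,
         call. = FALSE)
  }
  key <- if ("image_id" %in% names(out)) {
    paste(out$image_id, out$cell_id)
  } else {
    as.character(out$cell_id)
  }
  if (anyDuplicated(key)) {
    stop("Duplicate (image_id, cell_id) keys in ", path, call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("Duplicate column names in ", path, call. = FALSE)
  }
  out
}
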