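# Per-cell analyte quantification: extranuclear background subtraction,
# compartment-specific expression measurement, threshold positivity calls and
# per-image / per-tumor summaries.

#' Analyte measurement configuration
#'
#' @param analyte_name name used in reports.
#' @param compartment `"nuclear"` (mean corrected intensity within the
#'   nucleus; appropriate for nuclear analytes such as Ki67 and p-STAT3) or
#'   `"nuclear_dilated"` (mean within the nucleus dilated by `dilation_px`;
#'   appropriate for analytes like p-ERK found in the nucleus and adjacent
#'   cytoplasm, quantified within a two-pixel perimeter beyond nuclear
#'   boundaries, i.e. 0.5 micron at 400X).
#' @param dilation_px dilation in pixels (default 2).
#' @param background_subtract apply extranuclear background subtraction.
#' @param threshold positivity cutoff in corrected intensity units; a cell is
#'   positive iff its expression is strictly greater.
#' @return an object of class `analyte_config`.
#' @export
analyte_config <- function(analyte_name = "analyte",
                           compartment = c("nuclear", "nuclear_dilated"),
                           dilation_px = 2L, background_subtract = TRUE,
                           threshold = 0) {
  compartment <- match.arg(compartment)
  assert_count(dilation_px, "dilation_px", min = 0L)
  assert_flag(background_subtract, "background_subtract")
  assert_number(threshold, "threshold", min = 0)
  structure(list(analyte_name = analyte_name, compartment = compartment,
                 dilation_px = as.integer(dilation_px),
                 background_subtract = background_subtract,
                 threshold = threshold),
            class = "analyte_config")
}

dilate_mask <- function(mask, px) {
  if (px == 0L) return(mask)
  brush <- EBImage::makeBrush(2L * px + 1L, shape = "disc")
  as.matrix(EBImage::dilate(mask * 1, brush)) > 0.5
}

#' Subtract the average extranuclear background from an analyte channel
#'
#' Estimates the background as the mean pixel intensity over all extranuclear
#' pixels (outside every nucleus dilated by `dilation_px`, so perinuclear
#' analyte bleed does not inflate the estimate) and subtracts it from the
#' whole image, clamping at zero. Images without spurious background are left
#' essentially unchanged; a constant offset added outside nuclei is removed.
#'
#' @param channel numeric analyte channel.
#' @param labels integer label map of the nuclei.
#' @param dilation_px nuclei are dilated this much before being excluded from
#'   the background region.
#' @return list with `corrected` (matrix, non-negative) and `background`
#'   (scalar estimate).
#' @export
background_subtract <- function(channel, labels, dilation_px = 2L) {
  stopifnot(all(dim(channel) == dim(labels)))
  extranuclear <- !dilate_mask(labels > 0L, dilation_px)
  if (!any(extranuclear)) {
    stop("No extranuclear pixels: cannot estimate the background.",
         call. = FALSE)
  }
  bg <- mean(channel[extranuclear])
  list(corrected = pmax(channel - bg, 0), background = bg)
}

# dilation labels claimed by the nearer nucleus (simultaneous ring growth,
# 4-neighborhood rounds; ties to the lower id)
dilated_label_map <- function(labels, px) {
  if (px == 0L) return(labels)
  h <- nrow(labels); w <- ncol(labels)
  out <- labels
  big <- .Machine$integer.max
  for (round in seq_len(px)) {
    pad <- matrix(big, h + 2L, w + 2L)
    inner <- out
    inner[inner == 0L] <- big
    pad[2:(h + 1L), 2:(w + 1L)] <- inner
    grown <- pmin(pad[1:h, 2:(w + 1L)], pad[3:(h + 2L), 2:(w + 1L)],
                  pad[2:(h + 1L), 1:w], pad[2:(h + 1L), 3:(w + 2L)])
    upd <- out == 0L & grown < big
    out[upd] <- grown[upd]
  }
  out
}

#' Measure per-cell analyte expression
#'
#' Mean corrected intensity in the configured compartment: the nucleus
#' itself, or the nucleus dilated by `dilation_px` (dilation pixels claimed
#' by the nearer nucleus on overlap, ties to the lower id).
#'
#' @param corrected numeric analyte channel (typically the output of
#'   [background_subtract()]).
#' @param labels integer label map.
#' @param config an [analyte_config()].
#' @return tibble with `cell_id` and `value`.
#' @export
measure_expression <- function(corrected, labels, config = analyte_config()) {
  stopifnot(all(dim(corrected) == dim(labels)))
  comp_map <- if (config$compartment == "nuclear_dilated") {
    dilated_label_map(labels, config$dilation_px)
  } else {
    labels
  }
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) {
    return(tibble::tibble(cell_id = integer(0), value = numeric(0)))
  }
  idx <- which(comp_map > 0L)
  lab <- comp_map[idx]
  sums <- tapply(corrected[idx], lab, sum)
  counts <- tapply(corrected[idx], lab, length)
  tibble::tibble(cell_id = ids,
                 value = as.numeric(sums[as.character(ids)]) /
                   as.numeric(counts[as.character(ids)]))
}

#' Threshold positivity calls
#'
#' A cell is analyte-positive iff its expression value is strictly greater
#' than the threshold.
#'
#' @param values numeric vector of per-cell expression values.
#' @param threshold finite cutoff.
#' @return logical vector.
#' @export
classify_positive <- function(values, threshold) {
  assert_number(threshold, "threshold")
  values > threshold
}

#' Summarise analyte positivity per image and per tumor
#'
#' Per image: the fraction of all cells in the target class (EC fraction) and
#' the analyte-positive fraction among that class (reported as `NA` when the
#' image contains no cell of the class, rather than 0). Per tumor: median and
#' 25th/75th percentiles of the per-image fractions.
#'
#' @param cells data frame with one row per cell and columns `image_id`,
#'   `tumor_id`, `cell_class` (e.g. `"EC"` / `"non-EC"`), `positive`
#'   (logical).
#' @param target_class class whose analyte positivity is summarised.
#' @return object of class `analyte_report`: list with `per_image` and
#'   `per_tumor` tibbles.
#' @export
summarize_analyte <- function(cells, target_class = "EC") {
  cells <- tibble::as_tibble(cells)
  needed <- c("image_id", "tumor_id", "cell_class", "positive")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0L) {
    stop("Missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  per_image <- cells |>
    dplyr::group_by(.data$tumor_id, .data$image_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      class_fraction = mean(.data$cell_class == target_class),
      positive_fraction = {
        inc <- .data$cell_class == target_class
        if (any(inc)) mean(.data$positive[inc]) else NA_real_
      },
      .groups = "drop")
  per_tumor <- per_image |>
    tidyr::pivot_longer(c("class_fraction", "positive_fraction"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$tumor_id, .data$quantity) |>
    dplyr::summarise(
      median = stats::median(.data$value, na.rm = TRUE),
      q25 = unname(stats::quantile(.data$value, 0.25, na.rm = TRUE)),
      q75 = unname(stats::quantile(.data$value, 0.75, na.rm = TRUE)),
      n_images = sum(!is.na(.data$value)),
      .groups = "drop")
  structure(list(per_image = per_image, per_tumor = per_tumor,
                 target_class = target_class),
            class = "analyte_report")
}

#' @export
print.analyte_report <- function(x, ...) {
  cat("<analyte_report> target class:", x$target_class, "\n")
  print(x$per_tumor)
  invisible(x)
}
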