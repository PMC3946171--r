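# Per-nucleus measurements: intrinsic features (shape, size, intensity,
# texture) from the nuclear channel, and associative features (inside and
# perinuclear-ring statistics) from every other channel.

region_pixel_list <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) return(list())
  split(which(labels > 0L), labels[labels > 0L])[as.character(ids)]
}

# convex-hull area over pixel centers (shoelace formula); for digitally
# rendered convex shapes the ratio area / hull_area sits near 1 and is capped
# there by the caller
hull_area <- function(rows, cols) {
  pts <- cbind(rows, cols)
  ch <- grDevices::chull(pts)
  hp <- pts[ch, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(length(rows))
  x <- hp[, 2L]; y <- hp[, 1L]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

#' Intrinsic per-nucleus features
#'
#' For every nucleus in the label map: `area` (pixels), `perimeter` (count of
#' region pixels 4-adjacent to the outside), `elongation` (square root of the
#' eigenvalue ratio of the second central moment matrix, i.e. major/minor
#' axis ratio), `eccentricity`, `convexity` (area / convex-hull area),
#' `mean_intensity`, `total_intensity`, `intensity_var` and `gradient_energy`
#' (mean squared central-difference gradient magnitude inside the nucleus,
#' a chromatin-texture surrogate).
#'
#' @param labels integer label map.
#' @param nuclear numeric matrix of the nuclear channel (same shape).
#' @return tibble with `cell_id` and the feature columns (empty for an empty
#'   label map).
#' @export
intrinsic_features <- function(labels, nuclear) {
  stopifnot(all(dim(labels) == dim(nuclear)))
  px <- region_pixel_list(labels)
  if (length(px) == 0L) {
    return(tibble::tibble(cell_id = integer(0)))
  }
  h <- nrow(labels); w <- ncol(labels)

  # central-difference gradient magnitude squared (replicated borders)
  gx <- nuclear[, c(2:w, w)] - nuclear[, c(1L, 1:(w - 1L))]
  gy <- nuclear[c(2:h, h), ] - nuclear[c(1L, 1:(h - 1L)), ]
  grad2 <- (gx / 2)^2 + (gy / 2)^2

  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- labels
  inner <- pad[2:(h + 1L), 2:(w + 1L)]
  boundary <- (pad[1:h, 2:(w + 1L)] != inner) |
    (pad[3:(h + 2L), 2:(w + 1L)] != inner) |
    (pad[2:(h + 1L), 1:w] != inner) |
    (pad[2:(h + 1L), 3:(w + 2L)] != inner)

  purrr::imap_dfr(px, function(idx, id) {
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    area <- length(idx)
    m <- region_moments(rows, cols)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 1e-12)
    vals <- nuclear[idx]
    total <- sum(vals)
    tibble::tibble(
      cell_id = as.integer(id),
      area = area,
      perimeter = sum(boundary[idx]),
      elongation = sqrt(ev[1L] / ev[2L]),
      eccentricity = sqrt(pmax(1 - ev[2L] / ev[1L], 0)),
      convexity = min(area / hull_area(rows, cols), 1),
      mean_intensity = total / area,
      total_intensity = total,
      intensity_var = sum((vals - total / area)^2) / area,
      gradient_energy = mean(grad2[idx])
    )
  })
}

#' Associative per-nucleus features for a non-nuclear channel
#'
#' For every nucleus: `<name>_average` (mean channel intensity inside the
#' nucleus), `<name>_total` (sum inside) and `<name>_surround` (mean intensity
#' in the perinuclear ring obtained by dilating the nucleus by `ring_width`
#' pixels and excluding pixels of any nucleus). An endothelial-cell nucleus
#' sitting in a CD34-bright vessel wall shows a high `cd34_surround`. When a
#' nucleus' ring is entirely occupied by neighbouring nuclei the surround is
#' 0 and `<name>_surround_empty` is set.
#'
#' @param labels integer label map.
#' @param channel numeric matrix (same shape).
#' @param channel_name prefix for the feature columns (e.g. `"cd34"`).
#' @param ring_width ring width in pixels (>= 1); the default 2 px mirrors
#'   the two-pixel perimeter convention used for membrane-proximal markers.
#' @return tibble with `cell_id` and the three feature columns plus the
#'   `_surround_empty` flag.
#' @export
associative_features <- function(labels, channel, channel_name,
                                 ring_width = 2L) {
  stopifnot(all(dim(labels) == dim(channel)))
  assert_count(ring_width, "ring_width", min = 1L)
  px <- region_pixel_list(labels)
  if (length(px) == 0L) return(tibble::tibble(cell_id = integer(0)))
  h <- nrow(labels); w <- ncol(labels)
  any_nucleus <- labels > 0L
  brush <- EBImage::makeBrush(2L * ring_width + 1L, shape = "disc")

  out <- purrr::imap_dfr(px, function(idx, id) {
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    # dilate within a padded bounding box only
    r0 <- max(1L, min(rows) - ring_width); r1 <- min(h, max(rows) + ring_width)
    c0 <- max(1L, min(cols) - ring_width); c1 <- min(w, max(cols) + ring_width)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
    dil <- as.matrix(EBImage::dilate(sub, brush)) > 0.5
    ring <- dil & !(any_nucleus[r0:r1, c0:c1])
    ring_vals <- channel[r0:r1, c0:c1][ring]
    vals <- channel[idx]
    total <- sum(vals)
    tibble::tibble(
      cell_id = as.integer(id),
      average = total / length(idx),
      total = total,
      surround = if (length(ring_vals) > 0L) mean(ring_vals) else 0,
      surround_empty = length(ring_vals) == 0L
    )
  })
  names(out)[-1L] <- paste0(channel_name, "_", names(out)[-1L])
  out
}

#' Assemble feature row sets into one feature table
#'
#' Joins per-nucleus row sets (each with a `cell_id` column) on `cell_id` and
#' stamps the image id. Row sets must cover exactly the same cell ids and
#' must not share feature column names; violations are errors rather than
#' silent missing values.
#'
#' @param row_sets list of tibbles, each with `cell_id` plus feature columns.
#' @param image_id identifier stored in the `image_id` column.
#' @return a feature table tibble keyed by (`image_id`, `cell_id`).
#' @export
assemble_features <- function(row_sets, image_id = 1L) {
  stopifnot(is.list(row_sets), length(row_sets) > 0L)
  ids <- lapply(row_sets, function(x) sort(x$cell_id))
  for (i in seq_along(ids)[-1L]) {
    if (!identical(ids[[1L]], ids[[i]])) {
      off <- c(setdiff(ids[[1L]], ids[[i]]), setdiff(ids[[i]], ids[[1L]]))
      stop("Row sets cover different cell ids: ",
           paste(utils::head(off, 10L), collapse = ", "), call. = FALSE)
    }
  }
  cols <- unlist(lapply(row_sets, function(x) setdiff(names(x), "cell_id")))
  dup <- unique(cols[duplicated(cols)])
  if (length(dup) > 0L) {
    stop("Feature column collision across row sets: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- purrr::reduce(row_sets, dplyr::inner_join, by = "cell_id")
  num <- out[vapply(out, is.numeric, logical(1))]
  if (any(!is.finite(as.matrix(num)))) {
    stop("Non-finite feature values after assembly.", call. = FALSE)
  }
  dplyr::mutate(out, image_id = image_id, .before = 1L)
}

#' Full feature table for one multi-channel image
#'
#' Convenience wrapper: intrinsic features from the nuclear channel plus
#' associative features from every other channel, assembled into one table.
#'
#' @param labels integer label map.
#' @param channels named list of channel matrices; must include `nuclear`.
#' @param image_id image identifier.
#' @param ring_width associative ring width in pixels.
#' @return a feature table tibble.
#' @export
compute_features <- function(labels, channels, image_id = 1L,
                             ring_width = 2L) {
  if (is.null(channels$nuclear)) {
    stop("`channels` must contain a `nuclear` channel.", call. = FALSE)
  }
  if (max(labels) == 0L) {
    return(tibble::tibble(image_id = integer(0), cell_id = integer(0)))
  }
  sets <- list(intrinsic_features(labels, channels$nuclear))
  for (ch in setdiff(names(channels), "nuclear")) {
    sets <- c(sets, list(associative_features(labels, channels[[ch]], ch,
                                              ring_width)))
  }
  out <- assemble_features(sets, image_id = image_id)
  # the empty-ring flags are bookkeeping, not classifier features
  flags <- dplyr::select(out, "cell_id", dplyr::ends_with("_surround_empty"))
  out <- dplyr::select(out, -dplyr::ends_with("_surround_empty"))
  attr(out, "surround_flags") <- flags
  out
}
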