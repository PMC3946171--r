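#' Specification for a synthetic multi-channel tissue image
#'
#' Describes a rendered field of view emulating a spectrally-unmixed,
#' multiplex-stained tumor section: a nuclear (hematoxylin-like) channel of
#' elliptical nuclei on a dim background, a CD34 channel bright only in a
#' perinuclear ring around endothelial-cell (EC) nuclei, and an analyte
#' (DAB-like) channel bright inside analyte-positive nuclei with an optional
#' constant extranuclear background. EC nuclei are distinguished geometrically
#' by elongation (major/minor axis ratio `ec_elongation`); non-EC nuclei are
#' near-circular.
#'
#' @param height,width image size in pixels.
#' @param n_nuclei number of nuclei to place (no two nuclei overlap).
#' @param nucleus_radius_mean,nucleus_radius_sd equivalent-circle radius of
#'   nuclei, in pixels (mean and standard deviation across nuclei).
#' @param ec_fraction proportion of EC nuclei in (0, 1); the EC count is
#'   `round(ec_fraction * n_nuclei)`.
#' @param ec_elongation major/minor axis ratio of EC nuclei (> 1).
#' @param cd34_ring_intensity mean gray level of the CD34 ring (8-bit scale).
#' @param cd34_ring_width width of the perinuclear CD34 ring in pixels.
#' @param cd34_background dim nonspecific CD34 level everywhere else
#'   (residual unmixing bleed; keeps the channel informative inside nuclei
#'   without making non-EC cells CD34-bright).
#' @param analyte_positive_fraction proportion of analyte-positive nuclei;
#'   exactly `round(analyte_positive_fraction * n_nuclei)` nuclei are
#'   positive, drawn uniformly.
#' @param analyte_intensity mean gray level added inside analyte-positive
#'   nuclei.
#' @param analyte_background constant gray level added everywhere in the
#'   analyte channel (models spurious nonspecific DAB background staining,
#'   which covers nuclei and stroma alike).
#' @param nuclear_intensity,nuclear_background mean gray levels of nucleus
#'   interiors and of the background in the nuclear channel.
#' @param noise_model `"poisson"` (photon-like noise: each pixel drawn from a
#'   Poisson with the rendered mean) or `"gaussian"` (additive, sd
#'   `gaussian_sd`) or `"none"`.
#' @param gaussian_sd standard deviation for `noise_model = "gaussian"`.
#' @param bit_depth 8 or 16; all intensities must fit the bit depth.
#' @param pixel_size_um physical pixel size in micrometres (0.25 at 400X).
#' @param seed integer seed; identical specs render identical images.
#' @return an object of class `image_spec`.
#' @seealso [make_image()]
#' @export
image_spec <- function(height = 200, width = 200, n_nuclei = 20,
                       nucleus_radius_mean = 7, nucleus_radius_sd = 1,
                       ec_fraction = 0.25, ec_elongation = 2.5,
                       cd34_ring_intensity = 200, cd34_ring_width = 2,
                       cd34_background = 3,
                       analyte_positive_fraction = 0.3,
                       analyte_intensity = 150, analyte_background = 0,
                       nuclear_intensity = 180, nuclear_background = 10,
                       noise_model = c("poisson", "gaussian", "none"),
                       gaussian_sd = 5, bit_depth = 8,
                       pixel_size_um = 0.25, seed = 1L) {
  assert_count(height, "height", min = 16L)
  assert_count(width, "width", min = 16L)
  assert_count(n_nuclei, "n_nuclei", min = 1L)
  assert_number(nucleus_radius_mean, "nucleus_radius_mean", min = 2,
                open_min = TRUE)
  assert_number(nucleus_radius_sd, "nucleus_radius_sd", min = 0)
  assert_number(ec_fraction, "ec_fraction", min = 0, max = 1,
                open_min = TRUE, open_max = TRUE)
  assert_number(ec_elongation, "ec_elongation", min = 1)
  assert_count(cd34_ring_width, "cd34_ring_width", min = 1L)
  assert_number(analyte_positive_fraction, "analyte_positive_fraction",
                min = 0, max = 1)
  assert_number(analyte_background, "analyte_background", min = 0)
  noise_model <- match.arg(noise_model)
  if (!bit_depth %in% c(8, 16)) {
    stop("`bit_depth` must be 8 or 16.", call. = FALSE)
  }
  max_gray <- 2^bit_depth - 1
  assert_number(cd34_background, "cd34_background", min = 0)
  for (v in c(cd34_ring_intensity = cd34_ring_intensity,
              cd34_background = cd34_background,
              analyte_intensity = analyte_intensity,
              analyte_background = analyte_background,
              nuclear_intensity = nuclear_intensity,
              nuclear_background = nuclear_background)) {
    if (v < 0 || v > max_gray) {
      stop("Channel intensities must lie within the bit depth.", call. = FALSE)
    }
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_nuclei = as.integer(n_nuclei),
         nucleus_radius_mean = nucleus_radius_mean,
         nucleus_radius_sd = nucleus_radius_sd,
         ec_fraction = ec_fraction, ec_elongation = ec_elongation,
         cd34_ring_intensity = cd34_ring_intensity,
         cd34_ring_width = as.integer(cd34_ring_width),
         cd34_background = cd34_background,
         analyte_positive_fraction = analyte_positive_fraction,
         analyte_intensity = analyte_intensity,
         analyte_background = analyte_background,
         nuclear_intensity = nuclear_intensity,
         nuclear_background = nuclear_background,
         noise_model = noise_model, gaussian_sd = gaussian_sd,
         bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um, seed = as.integer(seed)),
    class = "image_spec"
  )
}

# Ellipse membership: pixel centers (row r, col c) inside the rotated ellipse
# centered at (cy, cx) with semi-axes a >= b and orientation theta.
ellipse_mask_idx <- function(height, width, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(height, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(width, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  if (nrow(inside) == 0L) return(integer(0))
  (cols[inside[, 2L]] - 1L) * height + rows[inside[, 1L]]
}

#' Render a synthetic multi-channel image with ground truth
#'
#' Places non-overlapping elliptical nuclei uniformly at random, renders the
#' nuclear, CD34 and analyte channel means, applies the configured noise
#' model, and returns both the image and the exact ground truth used to
#' render it (label map, EC status and analyte status per nucleus).
#'
#' Exactly `round(ec_fraction * n_nuclei)` nuclei are EC; EC nuclei are
#' ellipses with axis ratio `ec_elongation`, non-EC nuclei have axis ratio
#' drawn uniformly in \[1, 1.15\]. Exactly
#' `round(analyte_positive_fraction * n_nuclei)` nuclei are analyte-positive,
#' drawn uniformly across classes.
#'
#' @param spec an [image_spec()].
#' @return a list of class `mc_image_truth` with elements
#'   * `channels`: named list of numeric matrices (`nuclear`, `cd34`,
#'     `analyte`) holding integer gray values;
#'   * `truth`: list with `label_map` (integer matrix, 0 = background,
#'     k = pixels of nucleus k), `cell_types` (tibble `cell_id`, `type`) and
#'     `analyte_status` (tibble `cell_id`, `positive`);
#'   * `pixel_size_um`, `spec`.
#' @examples
#' img <- make_image(image_spec(n_nuclei = 6, seed = 3))
#' table(img$truth$cell_types$type)
#' @export
make_image <- function(spec) {
  if (!inherits(spec, "image_spec")) {
    stop("`spec` must be created by image_spec().", call. = FALSE)
  }
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width; n <- spec$n_nuclei
    margin <- spec$cd34_ring_width + 2

    n_ec <- round(spec$ec_fraction * n)
    is_ec <- rep(FALSE, n)
    is_ec[sample.int(n, n_ec)] <- TRUE

    # equivalent-circle radius per nucleus; elongation preserves area
    radius <- pmax(2, stats::rnorm(n, spec$nucleus_radius_mean,
                                   spec$nucleus_radius_sd))
    ratio <- ifelse(is_ec, spec$ec_elongation, stats::runif(n, 1, 1.15))
    a <- radius * sqrt(ratio)
    b <- radius / sqrt(ratio)
    theta <- stats::runif(n, 0, pi)

    # rejection-sample centers so bounding circles (+ margin) are disjoint
    cy <- numeric(n); cx <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("Could not place ", n, " non-overlapping nuclei in a ",
             h, "x", w, " frame; reduce `n_nuclei` or nucleus size.",
             call. = FALSE)
      }
      k <- placed + 1L
      pad <- a[k] + margin
      if (h - 2 * pad <= 1 || w - 2 * pad <= 1) {
        stop("Nuclei do not fit inside the frame; enlarge the image.",
             call. = FALSE)
      }
      y <- stats::runif(1, 1 + pad, h - pad)
      x <- stats::runif(1, 1 + pad, w - pad)
      ok <- TRUE
      if (placed > 0L) {
        d2 <- (cy[seq_len(placed)] - y)^2 + (cx[seq_len(placed)] - x)^2
        ok <- all(d2 > (a[seq_len(placed)] + a[k] + margin)^2)
      }
      if (ok) {
        cy[k] <- y; cx[k] <- x
        placed <- k
      }
    }

    label_map <- matrix(0L, h, w)
    ring_owner <- matrix(0L, h, w)
    for (k in seq_len(n)) {
      idx <- ellipse_mask_idx(h, w, cy[k], cx[k], a[k], b[k], theta[k])
      label_map[idx] <- k
      ridx <- ellipse_mask_idx(h, w, cy[k], cx[k],
                               a[k] + spec$cd34_ring_width,
                               b[k] + spec$cd34_ring_width, theta[k])
      ring_owner[ridx] <- k
    }
    ring_owner[label_map > 0L] <- 0L  # ring excludes nucleus interiors

    # analyte positivity: exact rounded count, uniform across classes
    positive <- rep(FALSE, n)
    n_pos <- round(spec$analyte_positive_fraction * n)
    if (n_pos > 0L) positive[sample.int(n, n_pos)] <- TRUE

    nuclear <- matrix(spec$nuclear_background, h, w)
    nuclear[label_map > 0L] <- spec$nuclear_intensity

    cd34 <- matrix(spec$cd34_background, h, w)
    ec_ring <- ring_owner > 0L & matrix(is_ec[pmax(ring_owner, 1L)], h, w)
    cd34[ec_ring] <- spec$cd34_ring_intensity

    analyte <- matrix(spec$analyte_background, h, w)
    pos_px <- label_map > 0L & matrix(positive[pmax(label_map, 1L)], h, w)
    analyte[pos_px] <- analyte[pos_px] + spec$analyte_intensity

    max_gray <- 2^spec$bit_depth - 1
    add_noise <- function(m) {
      out <- switch(spec$noise_model,
        poisson = matrix(stats::rpois(length(m), lambda = m), nrow(m)),
        gaussian = round(m + stats::rnorm(length(m), sd = spec$gaussian_sd)),
        none = round(m)
      )
      matrix(pmin(pmax(out, 0), max_gray), nrow(m))
    }

    structure(
      list(
        channels = list(nuclear = add_noise(nuclear),
                        cd34 = add_noise(cd34),
                        analyte = add_noise(analyte)),
        truth = list(
          label_map = label_map,
          cell_types = tibble::tibble(
            cell_id = seq_len(n),
            type = ifelse(is_ec, "EC", "non-EC")),
          analyte_status = tibble::tibble(
            cell_id = seq_len(n),
            positive = positive)
        ),
        pixel_size_um = spec$pixel_size_um,
        spec = spec
      ),
      class = "mc_image_truth"
    )
  })
}

#' Write a rendered image set to disk
#'
#' Writes one single-channel TIFF per channel (`<stem>_<channel>.tif`), the
#' ground-truth label map as a 16-bit TIFF (`<stem>_labels.tif`) and the
#' cell-type / analyte-status tables as JSON (`<stem>_truth.json`).
#'
#' @param img result of [make_image()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return (invisibly) named character vector of the files written.
#' @export
write_image_set <- function(img, dir, stem = "image") {
  stopifnot(inherits(img, "mc_image_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bit <- img$spec$bit_depth
  files <- character(0)
  for (ch in names(img$channels)) {
    path <- file.path(dir, paste0(stem, "_", ch, ".tif"))
    write_channel(img$channels[[ch]], path, bit_depth = bit)
    files[ch] <- path
  }
  lab_path <- file.path(dir, paste0(stem, "_labels.tif"))
  write_channel(img$truth$label_map, lab_path, bit_depth = 16)
  files["labels"] <- lab_path
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(
    list(cell_types = img$truth$cell_types,
         analyte_status = img$truth$analyte_status,
         pixel_size_um = img$pixel_size_um),
    truth_path, auto_unbox = TRUE, digits = NA)
  files["truth"] <- truth_path
  invisible(files)
}
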