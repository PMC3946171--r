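# End-to-end convenience: from rendered (or loaded) multi-channel images to a
# pooled feature table with ground-truth classes, ready for active learning.

#' Segment a set of images and pool their features with ground truth
#'
#' For each image: segments the nuclear channel, computes intrinsic and
#' associative features, matches each segmented nucleus to the ground-truth
#' nucleus with the largest pixel overlap, and labels it +1 (EC) or -1 from
#' the matched truth (regions matching background count as non-EC). Rows are
#' pooled across images with globally unique `cell_id`s (the per-image id is
#' kept in `nucleus_id`).
#'
#' @param images list of [make_image()] results (or lists with `channels` and
#'   `truth`).
#' @param config a [seg_config()].
#' @param ring_width associative-feature ring width in pixels.
#' @return a feature table tibble with `cell_id`, `image_id`, `nucleus_id`,
#'   `truth_id`, `jaccard`, `label` and feature columns.
#' @export
build_ec_pool <- function(images, config = seg_config(), ring_width = 2L) {
  stopifnot(is.list(images), length(images) > 0L)
  per_image <- purrr::imap(images, function(img, i) {
    labels <- segment_nuclei(img$channels$nuclear, config)
    if (max(labels) == 0L) return(NULL)
    feats <- compute_features(labels, img$channels, image_id = i,
                              ring_width = ring_width)
    match <- match_labels(labels, img$truth$label_map)
    types <- img$truth$cell_types
    match$label <- ifelse(
      match$truth_id > 0L &
        types$type[match(match$truth_id, types$cell_id)] == "EC", 1, -1)
    dplyr::inner_join(match, feats, by = "cell_id") |>
      dplyr::rename(nucleus_id = "cell_id") |>
      dplyr::mutate(image_id = i, .before = 1L)
  })
  pool <- dplyr::bind_rows(per_image)
  if (nrow(pool) == 0L) {
    stop("Segmentation found no nuclei in any image.", call. = FALSE)
  }
  dplyr::mutate(pool, cell_id = dplyr::row_number(), .before = 1L)
}

#' Sensitivity/specificity of an active-learning run against ground truth
#'
#' Classifies every pool cell outside the labeled training set with the
#' state's model and scores it against the hidden `label` column.
#'
#' @param state an `al_state` from [run_active_learning()].
#' @param pool the feature table the state was trained on (with `label`).
#' @return one-row tibble from [classification_metrics()] plus `n_evaluated`.
#' @export
evaluate_ec_classification <- function(state, pool) {
  held <- !pool$cell_id %in% state$labeled$cell_id
  eval_pool <- pool[held, , drop = FALSE]
  pred <- predict(state$model, eval_pool)
  out <- classification_metrics(confusion(eval_pool$label, pred$label))
  dplyr::mutate(out, n_evaluated = nrow(eval_pool))
}
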