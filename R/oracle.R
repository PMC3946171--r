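#' Build a simulated labeling oracle from ground truth
#'
#' Replaces the human trainer in active-learning runs: given ground truth, the
#' oracle is a function mapping a vector of cell ids to labels in \{-1, +1\}.
#' An optional flip probability models rater inconsistency (each query is
#' independently answered with the wrong label with that probability).
#'
#' @param truth either a labeled feature table (columns `cell_id`, `label` in
#'   \{-1, +1\}), or the `truth` element of [make_image()] (its `cell_types`
#'   tibble is used; `"EC"` maps to +1), or a tibble with `cell_id` and
#'   `type`/`label`.
#' @param flip_probability probability in \[0, 1\] of answering with the
#'   flipped label; 0 gives a perfectly consistent rater.
#' @param seed integer seed driving the flips (only used when
#'   `flip_probability > 0`).
#' @return a function `oracle(ids)` returning a numeric vector of labels.
#'   Unknown ids raise an error.
#' @examples
#' tbl <- make_feature_dataset(tabular_spec(n_cells = 50, seed = 2))
#' oracle <- simulated_oracle(tbl)
#' oracle(c(1, 5, 9)) == tbl$label[c(1, 5, 9)]
#' @export
simulated_oracle <- function(truth, flip_probability = 0, seed = 1L) {
  assert_number(flip_probability, "flip_probability", min = 0, max = 1)
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$cell_types)) {
    truth <- truth$cell_types
  }
  if (!is.data.frame(truth) || is.null(truth$cell_id)) {
    stop("`truth` must be a data frame with a `cell_id` column.",
         call. = FALSE)
  }
  labels <- if (!is.null(truth$label)) {
    assert_pm1(truth$label, "truth$label")
  } else if (!is.null(truth$type)) {
    ifelse(truth$type == "EC", 1, -1)
  } else {
    stop("`truth` must carry a `label` or `type` column.", call. = FALSE)
  }
  lookup <- stats::setNames(labels, truth$cell_id)
  # dedicated RNG stream so flips are reproducible and independent of callers
  rng <- new.env(parent = emptyenv())
  rng$state <- with_seed(seed, .Random.seed)
  function(ids) {
    key <- as.character(ids)
    missing_ids <- key[!key %in% names(lookup)]
    if (length(missing_ids) > 0L) {
      stop("Oracle queried for unknown cell id(s): ",
           paste(utils::head(missing_ids, 5L), collapse = ", "),
           call. = FALSE)
    }
    out <- unname(lookup[key])
    if (flip_probability > 0) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", rng$state, envir = globalenv())
      flip <- stats::runif(length(out)) < flip_probability
      rng$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
      out[flip] <- -out[flip]
    }
    out
  }
}
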