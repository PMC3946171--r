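#' Specification for a synthetic two-class feature table
#'
#' Describes a Gaussian two-class dataset of per-cell features: a handful of
#' informative features whose class means differ by `effect_size` within-class
#' standard deviations, plus pure-noise features identically distributed in
#' both classes. Cells are grouped into "images" (clusters) that share an
#' additive mean shift, emulating images from different regions of the same
#' tumor.
#'
#' @param n_cells total number of cells (>= 4).
#' @param n_informative number of informative features (>= 1).
#' @param n_noise number of uninformative features.
#' @param effect_size separation of class means in units of the within-class
#'   standard deviation (1 for each feature).
#' @param ec_fraction proportion of positive-class (endothelial) cells,
#'   strictly in (0, 1). The positive count is `round(ec_fraction * n_cells)`.
#' @param n_clusters number of image groups.
#' @param cluster_sd standard deviation of the per-cluster additive shift
#'   applied to every feature (0 disables cluster effects).
#' @param seed integer seed; identical specs generate byte-identical tables.
#' @return an object of class `tabular_spec`.
#' @seealso [make_feature_dataset()]
#' @export
tabular_spec <- function(n_cells = 1000, n_informative = 4, n_noise = 40,
                         effect_size = 2, ec_fraction = 0.25,
                         n_clusters = 5, cluster_sd = 0.2, seed = 1L) {
  assert_count(n_cells, "n_cells", min = 4L)
  assert_count(n_informative, "n_informative", min = 1L)
  assert_count(n_noise, "n_noise", min = 0L)
  assert_number(effect_size, "effect_size", min = 0)
  assert_number(ec_fraction, "ec_fraction", min = 0, max = 1,
                open_min = TRUE, open_max = TRUE)
  assert_count(n_clusters, "n_clusters", min = 1L)
  assert_number(cluster_sd, "cluster_sd", min = 0)
  n_pos <- round(ec_fraction * n_cells)
  if (n_pos < 1 || n_pos > n_cells - 1) {
    stop("`ec_fraction` leaves one class empty at this `n_cells`.",
         call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise),
         effect_size = effect_size, ec_fraction = ec_fraction,
         n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd,
         seed = as.integer(seed)),
    class = "tabular_spec"
  )
}

#' Generate a synthetic per-cell feature table with known labels
#'
#' Draws a two-class Gaussian dataset per a [tabular_spec()]. Informative
#' features `inf_1..inf_k` have class means at `+/- effect_size / 2` (so the
#' class-mean difference equals `effect_size` within-class standard
#' deviations); noise features `noise_1..noise_m` are standard normal in both
#' classes. Cells are assigned uniformly at random to `n_clusters` image
#' groups; each cluster adds a shared `N(0, cluster_sd^2)` shift to every
#' feature of its cells. The true label is kept in the `label` column
#' (+1 = endothelial) so callers can build oracles and score held-out
#' accuracy; strip it to obtain an unlabeled pool.
#'
#' @param spec a [tabular_spec()].
#' @return a tibble with columns `cell_id`, `image_id`, `label` and one column
#'   per feature.
#' @examples
#' tbl <- make_feature_dataset(tabular_spec(n_cells = 100, seed = 7))
#' dplyr::count(tbl, label)
#' @export
make_feature_dataset <- function(spec) {
  if (!inherits(spec, "tabular_spec")) {
    stop("`spec` must be created by tabular_spec().", call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_cells
    p_inf <- spec$n_informative
    p_noise <- spec$n_noise
    n_pos <- round(spec$ec_fraction * n)

    label <- rep(-1, n)
    label[sample.int(n, n_pos)] <- 1

    half <- spec$effect_size / 2
    X_inf <- matrix(stats::rnorm(n * p_inf), n, p_inf) +
      outer(label, rep(half, p_inf))
    X_noise <- if (p_noise > 0) {
      matrix(stats::rnorm(n * p_noise), n, p_noise)
    } else {
      matrix(0, n, 0)
    }
    X <- cbind(X_inf, X_noise)

    cluster <- sample.int(spec$n_clusters, n, replace = TRUE)
    if (spec$cluster_sd > 0) {
      shifts <- matrix(stats::rnorm(spec$n_clusters * ncol(X),
                                    sd = spec$cluster_sd),
                       spec$n_clusters, ncol(X))
      X <- X + shifts[cluster, , drop = FALSE]
    }

    colnames(X) <- c(
      if (p_inf > 0) paste0("inf_", seq_len(p_inf)),
      if (p_noise > 0) paste0("noise_", seq_len(p_noise))
    )
    tibble::as_tibble(as.data.frame(X)) |>
      dplyr::mutate(cell_id = seq_len(n),
                    image_id = cluster,
                    label = label,
                    .before = 1L)
  })
}

#' Feature column names of a feature table
#'
#' Every column that is not one of the bookkeeping columns (`cell_id`,
#' `image_id`, `cluster_id`, `tumor_id`, `label`, and the ground-truth
#' bookkeeping of pooled image tables: `nucleus_id`, `truth_id`, `jaccard`).
#'
#' @param data a feature table (data frame).
#' @return character vector of feature column names.
#' @export
feature_names <- function(data) {
  setdiff(names(data),
          c("cell_id", "image_id", "cluster_id", "tumor_id", "label",
            "nucleus_id", "truth_id", "jaccard"))
}
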