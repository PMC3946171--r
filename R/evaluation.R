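# Classifier/rater agreement: confusion-matrix metrics, Cohen's kappa,
# pairwise kappa matrices, multi-rater agreement partitions, and a
# cluster (per-image) bootstrap for interval estimates.

#' Confusion counts for binary classifications
#'
#' Positive class is +1 (endothelial cell).
#'
#' @param truth,predicted aligned vectors with values in \{-1, +1\}.
#' @return tibble with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length.", call. = FALSE)
  }
  truth <- assert_pm1(truth, "truth")
  predicted <- assert_pm1(predicted, "predicted")
  tibble::tibble(
    TP = sum(truth == 1 & predicted == 1),
    FP = sum(truth == -1 & predicted == 1),
    TN = sum(truth == -1 & predicted == -1),
    FN = sum(truth == 1 & predicted == -1)
  )
}

#' Sensitivity, specificity, PPV and NPV from confusion counts
#'
#' Sensitivity = TP/(TP+FN); Specificity = TN/(TN+FP); PPV = TP/(TP+FP);
#' NPV = TN/(TN+FN). A ratio with a zero denominator is reported as `NA`
#' (undefined), not 0.
#'
#' @param counts one-row data frame with `TP`, `FP`, `TN`, `FN`.
#' @return tibble with the four proportions and the counts.
#' @export
classification_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, tibble::tibble(
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    ppv = ratio(TP, TP + FP),
    npv = ratio(TN, TN + FN),
    TP = TP, FP = FP, TN = TN, FN = FN
  ))
}

#' Cohen's kappa for two binary raters
#'
#' \eqn{\kappa = (P_o - P_e) / (1 - P_e)} where \eqn{P_o} is the observed
#' agreement proportion and \eqn{P_e} the agreement expected by chance from
#' the raters' marginal positive proportions. Any non-constant rating agrees
#' perfectly with itself (kappa 1); two raters at chance level get kappa 0.
#' When both raters are constant and equal, \eqn{P_e = 1} and kappa is
#' undefined (`NA`).
#'
#' @param rating_a,rating_b aligned vectors in \{-1, +1\}.
#' @return scalar kappa in \[-1, 1\], or `NA` when undefined.
#' @examples
#' cohen_kappa(c(1, 1, 1, -1), c(1, 1, -1, -1))  # 0.5
#' @export
cohen_kappa <- function(rating_a, rating_b) {
  if (length(rating_a) != length(rating_b)) {
    stop("Ratings must be aligned vectors of equal length.", call. = FALSE)
  }
  a <- assert_pm1(rating_a, "rating_a")
  b <- assert_pm1(rating_b, "rating_b")
  po <- mean(a == b)
  pa <- mean(a == 1); pb <- mean(b == 1)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Pairwise kappa matrix for several raters
#'
#' @param ratings named list of aligned rating vectors in \{-1, +1\}.
#' @return symmetric numeric matrix with unit diagonal (for non-constant
#'   raters).
#' @export
kappa_matrix <- function(ratings) {
  stopifnot(is.list(ratings), length(ratings) >= 2L)
  lens <- lengths(ratings)
  if (length(unique(lens)) != 1L) {
    stop("All rating vectors must be aligned (equal length).", call. = FALSE)
  }
  r <- length(ratings)
  nm <- names(ratings)
  if (is.null(nm)) nm <- paste0("rater_", seq_len(r))
  out <- matrix(NA_real_, r, r, dimnames = list(nm, nm))
  for (i in seq_len(r)) {
    for (j in i:r) {
      k <- cohen_kappa(ratings[[i]], ratings[[j]])
      out[i, j] <- k
      out[j, i] <- k
    }
  }
  out
}

#' Agreement partition over the union-positive subset
#'
#' Cells rated negative by every rater are excluded; among the rest, counts
#' how many cells are called positive by exactly 1, 2, ..., R raters (the
#' Venn-diagram bins: the "all R" fraction is the proportion classified
#' positive by every rater).
#'
#' @param ratings list of aligned rating vectors in \{-1, +1\}.
#' @return tibble with `n_raters_positive`, `count`, `fraction` (fractions
#'   sum to 1 over the union-positive subset; empty tibble if no cell is
#'   positive for any rater).
#' @export
agreement_partition <- function(ratings) {
  stopifnot(is.list(ratings), length(ratings) >= 1L)
  mat <- do.call(cbind, lapply(ratings, function(x) assert_pm1(x) == 1))
  npos <- rowSums(mat)
  npos <- npos[npos > 0]
  r <- length(ratings)
  if (length(npos) == 0L) {
    return(tibble::tibble(n_raters_positive = integer(0), count = integer(0),
                          fraction = numeric(0)))
  }
  counts <- tabulate(npos, nbins = r)
  tibble::tibble(n_raters_positive = seq_len(r), count = counts,
                 fraction = counts / length(npos))
}

#' Cluster bootstrap confidence interval for a classification metric
#'
#' Nuclei from the same image are correlated, so cells are resampled by
#' image (cluster): `n_boot` times, images are drawn with replacement, the
#' metric is recomputed on the pooled cells, and the 2.5/97.5 percentiles of
#' the bootstrap distribution are returned. Resamples where the metric is
#' undefined are redrawn (bounded retries, with a warning).
#'
#' @param truth,predicted aligned label vectors in \{-1, +1\}.
#' @param image_ids cluster identifier per cell (>= 2 distinct values).
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`,
#'   `"accuracy"`.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return tibble with `estimate` (plug-in value), `lower`, `upper`,
#'   `n_boot`.
#' @export
cluster_bootstrap_ci <- function(truth, predicted, image_ids,
                                 metric = c("sensitivity", "specificity",
                                            "ppv", "npv", "accuracy"),
                                 n_boot = 2000L, seed = 1L) {
  metric <- match.arg(metric)
  truth <- assert_pm1(truth, "truth")
  predicted <- assert_pm1(predicted, "predicted")
  clusters <- unique(image_ids)
  if (length(clusters) < 2L) {
    stop("Cluster bootstrap needs at least two images.", call. = FALSE)
  }
  metric_fun <- function(tr, pr) {
    if (metric == "accuracy") return(mean(tr == pr))
    classification_metrics(confusion(tr, pr))[[metric]]
  }
  by_cluster <- split(seq_along(truth), image_ids)
  estimate <- metric_fun(truth, predicted)
  vals <- with_seed(seed, {
    out <- numeric(n_boot)
    retries <- 0L
    max_retries <- 100L * n_boot
    b <- 1L
    while (b <= n_boot) {
      take <- sample(names(by_cluster), length(by_cluster), replace = TRUE)
      idx <- unlist(by_cluster[take], use.names = FALSE)
      v <- metric_fun(truth[idx], predicted[idx])
      if (is.na(v)) {
        retries <- retries + 1L
        if (retries > max_retries) {
          warning("Metric undefined in too many resamples; interval based ",
                  "on ", b - 1L, " resamples.", call. = FALSE)
          out <- out[seq_len(b - 1L)]
          break
        }
        next
      }
      out[b] <- v
      b <- b + 1L
    }
    if (retries > 0L && retries <= max_retries) {
      warning(retries, " resample(s) with undefined metric were redrawn.",
              call. = FALSE)
    }
    out
  })
  qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  tibble::tibble(metric = metric, estimate = estimate,
                 lower = qs[1L], upper = qs[2L], n_boot = length(vals))
}
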