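# Hybrid nuclear segmentation: minimum-error Poisson thresholding (see
# threshold.R), multiscale Laplacian-of-Gaussian seed detection on the binary
# mask, steepest-ascent local-maximum clustering, and score-based merging of
# oversplit fragments. Everything here is deterministic.

#' Segmentation configuration
#'
#' @param scale_min,scale_max smallest and largest LoG sigma, in pixels. A
#'   nucleus of equivalent-circle radius `r` responds most strongly near
#'   `sigma = r / sqrt(2)`, so the ladder should bracket that value for the
#'   expected nucleus sizes.
#' @param n_scales number of geometric ladder steps between the two.
#' @param min_size,max_size area bounds in pixels; regions outside are dropped
#'   before merging.
#' @param use_graphcut refine the binarization with an exact graph cut rather
#'   than morphology.
#' @param smoothness Potts pairwise weight of the graph cut.
#' @param merge_alpha weight of the size-prior term in the region score
#'   (1 - merge_alpha weighs the ellipse-fit term).
#' @param size_prior_mean prior mean nucleus area in pixels; `NULL` fits it
#'   from the median area of the initial label map.
#' @param size_prior_sd standard deviation of the log-area prior.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(scale_min = 2.5, scale_max = 8, n_scales = 6L,
                       min_size = 40L, max_size = 4000L,
                       use_graphcut = FALSE, smoothness = 1,
                       merge_alpha = 0.5, size_prior_mean = NULL,
                       size_prior_sd = 0.6) {
  assert_number(scale_min, "scale_min", min = 0.5)
  assert_number(scale_max, "scale_max", min = scale_min)
  assert_count(n_scales, "n_scales", min = 1L)
  assert_count(min_size, "min_size", min = 1L)
  assert_count(max_size, "max_size", min = min_size + 1L)
  assert_flag(use_graphcut, "use_graphcut")
  assert_number(merge_alpha, "merge_alpha", min = 0, max = 1)
  structure(
    list(scale_min = scale_min, scale_max = scale_max,
         n_scales = as.integer(n_scales),
         min_size = as.integer(min_size), max_size = as.integer(max_size),
         use_graphcut = use_graphcut, smoothness = smoothness,
         merge_alpha = merge_alpha, size_prior_mean = size_prior_mean,
         size_prior_sd = size_prior_sd),
    class = "seg_config"
  )
}

log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  ax <- (-half):half
  r2 <- outer(ax^2, ax^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)  # zero-sum so flat regions give zero response
}

# convolution with edge replication, valid even when the kernel is larger
# than the image (the image is padded by the kernel half-width first)
filter_replicate <- function(image, kernel) {
  half <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  ri <- c(rep(1L, half), seq_len(h), rep(h, half))
  ci <- c(rep(1L, half), seq_len(w), rep(w, half))
  padded <- image[ri, ci]
  out <- as.matrix(EBImage::filter2(padded, kernel, boundary = "circular"))
  out[half + seq_len(h), half + seq_len(w)]
}

#' Multiscale Laplacian-of-Gaussian seed detection
#'
#' Convolves `image` with scale-normalised LoG kernels on a geometric sigma
#' ladder, takes the across-scale maximum of the (sign-flipped, so bright
#' blobs are positive) responses, and returns local maxima inside `mask` as
#' seed points. Seeds closer to a stronger seed than their own detected scale
#' are suppressed. Seeds are returned in row-major order.
#'
#' @param image numeric matrix; in the hybrid pipeline this is the binarized
#'   nuclear mask, so seeds mark shape centers rather than intensity peaks.
#' @param mask logical matrix restricting where seeds may lie.
#' @param config a [seg_config()].
#' @return list with `seeds` (tibble `seed_id`, `row`, `col`, `sigma`,
#'   `response`) and `response` (the across-scale maximum response matrix).
#' @export
multiscale_log_seeds <- function(image, mask, config = seg_config()) {
  h <- nrow(image); w <- ncol(image)
  if (!any(mask)) {
    return(list(seeds = tibble::tibble(seed_id = integer(0), row = integer(0),
                                       col = integer(0), sigma = numeric(0),
                                       response = numeric(0)),
                response = matrix(0, h, w)))
  }
  sigmas <- exp(seq(log(config$scale_min), log(config$scale_max),
                    length.out = config$n_scales))
  best <- matrix(-Inf, h, w)
  best_sigma <- matrix(sigmas[1L], h, w)
  for (s in sigmas) {
    # log_kernel omits the Gaussian's 1/(2*pi*sigma^2) factor, so the plain
    # convolution already carries the sigma^2 scale normalisation; -1/(2*pi)
    # flips the sign for bright blobs and restores the constant
    resp <- -filter_replicate(image, log_kernel(s)) / (2 * pi)
    upd <- resp > best
    best[upd] <- resp[upd]
    best_sigma[upd] <- s
  }

  # local maxima over the 8-neighborhood (padded with -Inf)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- best
  is_max <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    is_max <- is_max & (best >= nb)
  }
  is_max <- is_max & mask & (best > 1e-8)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(list(seeds = tibble::tibble(seed_id = integer(0), row = integer(0),
                                       col = integer(0), sigma = numeric(0),
                                       response = numeric(0)),
                response = best))
  }
  resp <- best[is_max]
  sig <- best_sigma[is_max]
  # greedy non-maximum suppression, strongest first; row-major tie order
  rm_order <- (cand[, 1L] - 1L) * w + cand[, 2L]
  ord <- order(-resp, rm_order)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) {
      keep <- i
      next
    }
    d2 <- (cand[keep, 1L] - cand[i, 1L])^2 + (cand[keep, 2L] - cand[i, 2L])^2
    if (all(d2 >= sig[i]^2)) keep <- c(keep, i)
  }
  keep <- keep[order(rm_order[keep])]  # deterministic row-major output
  seeds <- tibble::tibble(seed_id = seq_along(keep),
                          row = cand[keep, 1L], col = cand[keep, 2L],
                          sigma = sig[keep], response = resp[keep])
  list(seeds = seeds, response = best)
}

#' Assign mask pixels to seeds by steepest ascent (local-maximum clustering)
#'
#' Every foreground pixel is assigned the label of the seed reached by
#' steepest ascent on the response field: pixels are processed in decreasing
#' response order and take the label of their best already-labeled 4-neighbor
#' (ties to the lower label id). Pixels whose ascent path reaches a non-seed
#' local maximum are assigned to the nearest seed (Euclidean distance, ties
#' to the lower seed id). The background is untouched, so the result is a
#' partition of the mask.
#'
#' @param response numeric matrix (e.g. the LoG max response).
#' @param seeds seed tibble from [multiscale_log_seeds()].
#' @param mask logical matrix of foreground pixels.
#' @return integer label map (0 = background, k = pixels of seed k).
#' @export
local_max_clustering <- function(response, seeds, mask) {
  h <- nrow(response); w <- ncol(response)
  labels <- matrix(0L, h, w)
  if (!any(mask)) return(labels)
  if (nrow(seeds) == 0L) {
    warning("No seeds inside a non-empty mask; returning a single region.",
            call. = FALSE)
    labels[mask] <- 1L
    return(labels)
  }
  labels[cbind(seeds$row, seeds$col)] <- seeds$seed_id

  idx <- which(mask)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  ord <- order(-response[idx], (rr - 1L) * w + cc)
  idx <- idx[ord]; rr <- rr[ord]; cc <- cc[ord]
  unlabeled <- labels[idx] == 0L

  for (sweep in seq_len(100L)) {
    changed <- FALSE
    todo <- which(unlabeled)
    for (t in todo) {
      r <- rr[t]; c <- cc[t]
      best_lab <- 0L
      best_resp <- -Inf
      for (k in 1:4) {
        nr <- r + c(-1L, 1L, 0L, 0L)[k]
        nc <- c + c(0L, 0L, -1L, 1L)[k]
        if (nr < 1L || nr > h || nc < 1L || nc > w) next
        lab <- labels[nr, nc]
        if (lab == 0L) next
        rsp <- response[nr, nc]
        if (rsp > best_resp || (rsp == best_resp && lab < best_lab)) {
          best_resp <- rsp
          best_lab <- lab
        }
      }
      if (best_lab > 0L) {
        labels[r, c] <- best_lab
        unlabeled[t] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed || !any(unlabeled)) break
  }
  if (any(unlabeled)) {
    # isolated plateaus with no path to a seed: nearest seed, ties to lower id
    for (t in which(unlabeled)) {
      d2 <- (seeds$row - rr[t])^2 + (seeds$col - cc[t])^2
      labels[rr[t], cc[t]] <- seeds$seed_id[order(d2, seeds$seed_id)[1L]]
    }
  }
  labels
}

# second central moments of a pixel set, with the 1/12 pixel-extent term
region_moments <- function(rows, cols) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  srr <- sum((rows - mr)^2) / n + 1 / 12
  scc <- sum((cols - mc)^2) / n + 1 / 12
  src <- sum((rows - mr) * (cols - mc)) / n
  matrix(c(srr, src, src, scc), 2L)
}

#' Plausibility score of a candidate nucleus region
#'
#' A surrogate for a trained nucleus-appearance model, combining a log-normal
#' size prior with an ellipse-fit quality term:
#' `merge_alpha * dnorm(log(area), log(size_prior_mean), size_prior_sd, log = TRUE)
#'  + (1 - merge_alpha) * min(area / ellipse_area, 1)`,
#' where `ellipse_area = 4 * pi * sqrt(det(M))` is the area of the ellipse
#' with the region's second central moments `M`. Compact, elliptical regions
#' of prior-typical size score highest; dumbbells and fragments score lower.
#'
#' @param pixels integer vector of linear pixel indices of the region.
#' @param image the intensity image (unused by this geometric surrogate; kept
#'   for interface stability with intensity-aware scoring models).
#' @param config a [seg_config()]; `size_prior_mean` must be set.
#' @return scalar score (higher = more nucleus-like).
#' @export
region_score <- function(pixels, image, config = seg_config()) {
  if (length(pixels) == 0L) stop("Empty region.", call. = FALSE)
  h <- nrow(image)
  rows <- ((pixels - 1L) %% h) + 1L
  cols <- ((pixels - 1L) %/% h) + 1L
  area <- length(pixels)
  m <- region_moments(rows, cols)
  ellipse_area <- 4 * pi * sqrt(max(det(m), 0))
  q <- if (ellipse_area > 0) min(area / ellipse_area, 1) else 1
  mu <- config$size_prior_mean
  if (is.null(mu)) {
    stop("`size_prior_mean` is unset; supply it or let merge_refinement() ",
         "fit it from the initial label map.", call. = FALSE)
  }
  size_term <- stats::dnorm(log(area), log(mu), config$size_prior_sd,
                            log = TRUE)
  config$merge_alpha * size_term + (1 - config$merge_alpha) * q
}

# ascending (min id, max id) pairs of 4-adjacent distinct labels
adjacent_pairs <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  right <- cbind(as.vector(labels[, -w]), as.vector(labels[, -1L]))
  down <- cbind(as.vector(labels[-h, ]), as.vector(labels[-1L, ]))
  pairs <- rbind(right, down)
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  unique(pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE])
}

#' Merge oversplit fragments by comparing region scores
#'
#' Visits adjacent region pairs (sharing at least one 4-adjacent boundary
#' pixel) in ascending (min id, max id) order and merges a pair whenever the
#' merged region scores higher than both parts; sweeps repeat until no merge
#' applies. Because a merge only ever replaces two regions by a
#' higher-scoring one, the minimum region score in the map never decreases.
#' Labels are relabelled contiguously (ascending original id) on return.
#'
#' @param initial integer label map (a partition).
#' @param image intensity image passed through to [region_score()].
#' @param config a [seg_config()]; a `NULL` `size_prior_mean` is fitted as
#'   the median region area of `initial`.
#' @return integer label map with contiguous ids.
#' @export
merge_refinement <- function(initial, image, config = seg_config()) {
  labels <- initial
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  px <- split(which(labels > 0L), labels[labels > 0L])
  if (is.null(config$size_prior_mean)) {
    config$size_prior_mean <- stats::median(lengths(px))
  }
  scores <- vapply(px, region_score, numeric(1), image = image,
                   config = config)
  repeat {
    pairs <- adjacent_pairs(labels)
    merged_any <- FALSE
    for (i in seq_len(nrow(pairs))) {
      a <- as.character(pairs[i, 1L]); b <- as.character(pairs[i, 2L])
      if (is.null(px[[a]]) || is.null(px[[b]])) next  # consumed this sweep
      union_px <- c(px[[a]], px[[b]])
      s_union <- region_score(union_px, image, config)
      if (s_union > max(scores[[a]], scores[[b]])) {
        labels[px[[b]]] <- as.integer(a)
        px[[a]] <- union_px
        px[[b]] <- NULL
        scores[[a]] <- s_union
        scores <- scores[names(scores) != b]
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  relabel_contiguous(labels)
}

#' Relabel a label map with contiguous ids 1..K (ascending original id)
#' @param labels integer label map.
#' @return integer label map.
#' @export
relabel_contiguous <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) return(labels)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  out <- labels
  out[labels > 0L] <- lut[labels[labels > 0L] + 1L]
  out
}

#' Segment nuclei in a nuclear-channel image
#'
#' The full hybrid pipeline: minimum-error Poisson-mixture thresholding,
#' binarization refinement (morphological or graph-cut), multiscale LoG seed
#' detection on the binary mask, steepest-ascent local-maximum clustering,
#' size filtering (regions outside `[min_size, max_size]` dropped), and
#' score-based fragment merging. Deterministic: the same image always yields
#' the same label map.
#'
#' @param nuclear numeric matrix: the nuclear (hematoxylin) channel.
#' @param config a [seg_config()].
#' @return integer label map (0 = background, ids contiguous 1..K). A blank
#'   or single-valued image yields an all-zero map.
#' @examples
#' img <- make_image(image_spec(n_nuclei = 8, seed = 2))
#' labs <- segment_nuclei(img$channels$nuclear)
#' max(labs)
#' @export
segment_nuclei <- function(nuclear, config = seg_config()) {
  fit <- tryCatch(
    poisson_minimum_error_threshold(image_histogram(nuclear)),
    error = function(e) NULL)
  if (is.null(fit)) return(matrix(0L, nrow(nuclear), ncol(nuclear)))
  mask <- binarize(nuclear, fit, use_graphcut = config$use_graphcut,
                   smoothness = config$smoothness)
  if (!any(mask)) return(matrix(0L, nrow(nuclear), ncol(nuclear)))
  sd <- multiscale_log_seeds(mask * 1, mask, config)
  labels <- local_max_clustering(sd$response, sd$seeds, mask)
  # size filter before merging
  areas <- tabulate(labels[labels > 0L])
  drop_ids <- which(areas < config$min_size | areas > config$max_size)
  if (length(drop_ids) > 0L) {
    labels[labels %in% drop_ids] <- 0L
    labels <- relabel_contiguous(labels)
  }
  if (!any(labels > 0L)) return(labels)
  merge_refinement(labels, nuclear, config)
}

#' Region summary of a label map
#'
#' @param labels integer label map.
#' @return tibble with `cell_id`, `centroid_row`, `centroid_col`, `area`.
#' @export
label_map_table <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) {
    return(tibble::tibble(cell_id = integer(0), centroid_row = numeric(0),
                          centroid_col = numeric(0), area = integer(0)))
  }
  h <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  tibble::tibble(
    cell_id = ids,
    centroid_row = as.numeric(tapply(rows, lab, mean)),
    centroid_col = as.numeric(tapply(cols, lab, mean)),
    area = as.integer(tabulate(lab)[ids])
  )
}

#' Match segmented regions to ground-truth regions
#'
#' For each predicted region, finds the ground-truth region with the largest
#' pixel overlap and reports the Jaccard index of the pair. Regions whose
#' majority overlap is background get `truth_id = 0` and Jaccard 0.
#'
#' @param pred,truth integer label maps of identical shape.
#' @return tibble with `cell_id` (predicted id), `truth_id`, `jaccard`.
#' @export
match_labels <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  ids <- setdiff(sort(unique(as.vector(pred))), 0L)
  purrr::map_dfr(ids, function(k) {
    pk <- pred == k
    tt <- truth[pk]
    best <- as.integer(names(which.max(table(tt))))
    if (best == 0L) {
      return(tibble::tibble(cell_id = k, truth_id = 0L, jaccard = 0))
    }
    inter <- sum(tt == best)
    uni <- sum(pk) + sum(truth == best) - inter
    tibble::tibble(cell_id = k, truth_id = best, jaccard = inter / uni)
  })
}
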