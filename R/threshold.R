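# Foreground/background separation of the nuclear channel: the gray-level
# histogram is modelled as a two-component mixture of Poisson distributions
# and the threshold is chosen by minimum-error thresholding (exhaustive
# search over the joint negative log-likelihood of the split).

#' Gray-level histogram of an integer-valued image
#'
#' @param image numeric matrix of non-negative gray values (rounded to
#'   integers).
#' @return integer vector of counts; element `g + 1` counts gray level `g`.
#' @export
image_histogram <- function(image) {
  g <- round(as.vector(image))
  if (any(g < 0)) stop("Gray levels must be non-negative.", call. = FALSE)
  tabulate(g + 1L, nbins = max(g) + 1L)
}

#' Minimum-error threshold under a two-component Poisson mixture
#'
#' Models the histogram as a mixture of two Poisson distributions split at a
#' threshold `T`: gray levels `g <= T` belong to the background component and
#' `g > T` to the foreground. For every candidate `T` the class priors
#' \eqn{P_0, P_1} and means \eqn{\mu_0 < \mu_1} are the empirical values of
#' the split, and the criterion is the total negative log-likelihood
#' \deqn{J(T) = \sum_{g \le T} h(g)\,[-\ln P_0 - \ln \mathrm{Pois}(g;\mu_0)]
#'            + \sum_{g > T}  h(g)\,[-\ln P_1 - \ln \mathrm{Pois}(g;\mu_1)].}
#' The returned threshold is the exhaustive argmin (smallest `T` on ties).
#'
#' @param histogram vector of gray-level counts (element `g + 1` = count of
#'   gray `g`), with at least two occupied bins.
#' @return object of class `poisson_mixture_fit`: `threshold`, `priors`
#'   (`P0`, `P1`), `means` (`mu0`, `mu1`), `criterion` (J at the optimum) and
#'   `criterion_curve` (J over all candidates, named by T).
#' @examples
#' h <- image_histogram(matrix(c(rpois(500, 5), rpois(200, 50)), 70))
#' poisson_minimum_error_threshold(h)$threshold
#' @export
poisson_minimum_error_threshold <- function(histogram) {
  h <- as.numeric(histogram)
  if (any(h < 0) || any(!is.finite(h))) {
    stop("Histogram counts must be finite and non-negative.", call. = FALSE)
  }
  if (sum(h > 0) < 2L) {
    stop("Degenerate histogram: need at least two occupied gray levels.",
         call. = FALSE)
  }
  g <- seq_along(h) - 1
  n_total <- sum(h)
  cum_n <- cumsum(h)
  cum_s <- cumsum(g * h)
  cum_lf <- cumsum(h * lgamma(g + 1))
  tot_s <- cum_s[length(h)]
  tot_lf <- cum_lf[length(h)]

  # candidates: split points with mass on both sides
  cand <- which(cum_n > 0 & cum_n < n_total)
  n0 <- cum_n[cand];        n1 <- n_total - n0
  s0 <- cum_s[cand];        s1 <- tot_s - s0
  mu0 <- s0 / n0;           mu1 <- s1 / n1
  p0 <- n0 / n_total;       p1 <- n1 / n_total
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  J <- -n0 * log(p0) - (xlogy(s0, mu0) - n0 * mu0) + (cum_lf[cand]) +
       -n1 * log(p1) - (xlogy(s1, mu1) - n1 * mu1) + (tot_lf - cum_lf[cand])

  best <- which.min(J)  # smallest candidate on ties
  structure(
    list(threshold = g[cand[best]],
         priors = c(P0 = p0[best], P1 = p1[best]),
         means = c(mu0 = mu0[best], mu1 = mu1[best]),
         criterion = J[best],
         criterion_curve = stats::setNames(J, g[cand])),
    class = "poisson_mixture_fit"
  )
}

#' @export
print.poisson_mixture_fit <- function(x, ...) {
  cat("<poisson_mixture_fit> T =", x$threshold,
      sprintf("| P0 = %.3f, mu0 = %.2f | P1 = %.3f, mu1 = %.2f\n",
              x$priors["P0"], x$means["mu0"], x$priors["P1"], x$means["mu1"]))
  invisible(x)
}

# Poisson negative log-likelihood per gray level for one mixture class,
# clamped to keep graph capacities finite.
pois_class_cost <- function(g, prior, mu, clamp = 1e6) {
  ll <- if (mu > 0) g * log(mu) - mu - lgamma(g + 1) else ifelse(g == 0, 0, -Inf)
  pmin(-log(prior) - ll, clamp)
}

#' Binarize an image given a Poisson-mixture fit
#'
#' The initial mask keeps pixels strictly above the threshold. Refinement is
#' either a binary graph cut (data term = per-class Poisson negative
#' log-likelihoods, Potts smoothness term, solved exactly by max-flow) or a
#' light morphological clean-up (hole filling plus removal of isolated
#' foreground pixels); both leave a noise-free mask unchanged.
#'
#' @param image numeric gray-value matrix.
#' @param fit a [poisson_minimum_error_threshold()] fit of this image's
#'   histogram.
#' @param use_graphcut refine with the graph cut instead of morphology.
#' @param smoothness Potts pairwise weight of the graph cut (0 reproduces the
#'   pure threshold mask).
#' @param refine apply any refinement at all (FALSE returns the raw
#'   threshold mask).
#' @return logical matrix (TRUE = foreground).
#' @export
binarize <- function(image, fit, use_graphcut = FALSE, smoothness = 1,
                     refine = TRUE) {
  stopifnot(inherits(fit, "poisson_mixture_fit"))
  mask <- image > fit$threshold
  if (!refine) return(mask)
  if (use_graphcut) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("Graph-cut refinement requires a max-flow backend (igraph), ",
           "which is not available.", call. = FALSE)
    }
    return(graphcut_binarize(image, fit, smoothness))
  }
  m <- matrix(as.numeric(EBImage::fillHull(mask * 1)) > 0.5,
              nrow(image), ncol(image))
  # despeckle: drop foreground pixels with no 4-connected foreground neighbor
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  nb <- pad[1:h, 2:(w + 1L)] | pad[3:(h + 2L), 2:(w + 1L)] |
    pad[2:(h + 1L), 1:w] | pad[2:(h + 1L), 3:(w + 2L)]
  m & nb
}

# Exact binary MRF segmentation via s-t min-cut. Nodes = pixels + source
# (foreground terminal) + sink (background terminal). A pixel ending on the
# source side is foreground; the cut then pays cap(p -> t) which is set to the
# foreground data cost, and symmetric for background. 4-neighbor Potts edges.
graphcut_binarize <- function(image, fit, smoothness) {
  h <- nrow(image); w <- ncol(image)
  n <- h * w
  g <- round(as.vector(image))
  cost_bg <- pois_class_cost(g, fit$priors["P0"], fit$means["mu0"])
  cost_fg <- pois_class_cost(g, fit$priors["P1"], fit$means["mu1"])
  src <- n + 1L; snk <- n + 2L

  edges <- list(
    rbind(rep(src, n), seq_len(n)),  # s -> p, cap = cost of labeling p bg
    rbind(seq_len(n), rep(snk, n))   # p -> t, cap = cost of labeling p fg
  )
  caps <- list(cost_bg, cost_fg)
  if (smoothness > 0) {
    idx <- matrix(seq_len(n), h, w)
    right <- cbind(as.vector(idx[, -w]), as.vector(idx[, -1L]))
    down <- cbind(as.vector(idx[-h, ]), as.vector(idx[-1L, ]))
    nb <- rbind(right, down)
    edges <- c(edges, list(t(nb), t(nb[, 2:1])))
    caps <- c(caps, list(rep(smoothness, nrow(nb)), rep(smoothness, nrow(nb))))
  }
  el <- do.call(cbind, edges)
  graph <- igraph::graph_from_edgelist(t(el), directed = TRUE)
  flow <- igraph::max_flow(graph, source = src, target = snk,
                           capacity = unlist(caps))
  fg <- rep(FALSE, n)
  part1 <- as.integer(flow$partition1)
  fg[part1[part1 <= n]] <- TRUE
  matrix(fg, h, w)
}
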