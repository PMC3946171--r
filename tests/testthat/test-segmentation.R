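# Nuclear segmentation: thresholding, binarization refinement, seed
# detection, clustering, scoring and merging.

test_that("minimum-error threshold brackets well-separated Poisson means", {
  set.seed(1)
  samples <- c(rpois(70000, 5), rpois(30000, 50))
  h <- tabulate(samples + 1L, nbins = max(samples) + 1L)
  fit <- poisson_minimum_error_threshold(h)
  expect_gt(fit$threshold, 5)
  expect_lt(fit$threshold, 50)
  expect_lt(fit$means["mu0"], fit$means["mu1"])
  expect_equal(sum(fit$priors), 1)
  # returned J is the global minimum over all candidates (exhaustiveness)
  expect_equal(fit$criterion, min(fit$criterion_curve))
  # smallest T on ties / two-bin case
  h2 <- numeric(101); h2[1] <- 40; h2[101] <- 10
  expect_equal(poisson_minimum_error_threshold(h2)$threshold, 0)
  expect_error(poisson_minimum_error_threshold(c(0, 10)), "Degenerate")
})

test_that("binarize recovers a noise-free two-level image either way", {
  img <- matrix(5, 40, 40)
  img[10:20, 10:20] <- 80
  fit <- poisson_minimum_error_threshold(image_histogram(img))
  m1 <- binarize(img, fit, use_graphcut = FALSE)
  m2 <- binarize(img, fit, use_graphcut = TRUE, smoothness = 1)
  truth <- img > 40
  expect_equal(m1, truth, ignore_attr = TRUE)
  expect_equal(m2, truth, ignore_attr = TRUE)
})

test_that("a unary-only graph cut equals the pure threshold mask", {
  set.seed(2)
  img <- matrix(rpois(1600, 6), 40)
  img[15:25, 15:25] <- rpois(121, 60)
  fit <- poisson_minimum_error_threshold(image_histogram(img))
  m_thr <- binarize(img, fit, refine = FALSE)
  m_gc0 <- binarize(img, fit, use_graphcut = TRUE, smoothness = 0)
  expect_equal(m_gc0, m_thr, ignore_attr = TRUE)
})

test_that("the smoothness term removes speckle", {
  set.seed(4)
  img <- matrix(rpois(2500, 5), 50)
  salt <- sample(2500, 40)
  img[salt] <- 70                     # isolated bright pixels
  img[20:30, 20:30] <- rpois(121, 70) # one real object
  fit <- poisson_minimum_error_threshold(image_histogram(img))
  m_thr <- binarize(img, fit, refine = FALSE)
  m_gc <- binarize(img, fit, use_graphcut = TRUE, smoothness = 2)
  expect_lte(isolated_pixel_count(m_gc), isolated_pixel_count(m_thr))
  expect_gt(sum(m_gc[20:30, 20:30]), 100)  # object survives
})

test_that("LoG seed detection finds blob centers at the matched scale", {
  # one disk of radius 8: the scale-normalised LoG of a disk peaks near
  # sigma = r / sqrt(2)
  img <- matrix(0, 60, 60)
  img[circle_map(60, 60, 30, 30, 8) > 0] <- 1
  cfg <- seg_config(scale_min = 2.5, scale_max = 10)
  sd <- multiscale_log_seeds(img, img > 0, cfg)
  expect_equal(nrow(sd$seeds), 1)
  expect_lt(abs(sd$seeds$row - 30), 1.5)
  expect_lt(abs(sd$seeds$col - 30), 1.5)
  step <- (10 / 2.5)^(1 / 5)
  expect_lt(abs(log(sd$seeds$sigma / (8 / sqrt(2)))), log(step) + 1e-9)
  # two disks far apart -> two seeds
  img2 <- matrix(0, 60, 100)
  img2[circle_map(60, 100, 30, 25, 7) > 0] <- 1
  img2[circle_map(60, 100, 30, 75, 7) > 0] <- 1
  sd2 <- multiscale_log_seeds(img2, img2 > 0, cfg)
  expect_equal(nrow(sd2$seeds), 2)
  # flat image -> no seeds
  flat <- matrix(1, 30, 30)
  expect_equal(nrow(multiscale_log_seeds(flat, flat > 0, cfg)$seeds), 0)
})

test_that("local-maximum clustering partitions the mask", {
  # single seed claims the whole mask
  mask <- circle_map(30, 30, 15, 15, 8) > 0
  resp <- matrix(0, 30, 30); resp[15, 15] <- 1
  seeds <- tibble::tibble(seed_id = 1L, row = 15L, col = 15L,
                          sigma = 4, response = 1)
  lab <- local_max_clustering(resp, seeds, mask)
  expect_true(all(lab[mask] == 1L))
  expect_true(all(lab[!mask] == 0L))
  # two symmetric blobs split along the midline
  img2 <- matrix(0, 40, 80)
  img2[circle_map(40, 80, 20, 25, 9) > 0] <- 1
  img2[circle_map(40, 80, 20, 55, 9) > 0] <- 1
  mask2 <- img2 > 0
  sd2 <- multiscale_log_seeds(img2, mask2, seg_config(scale_min = 3,
                                                      scale_max = 10))
  lab2 <- local_max_clustering(sd2$response, sd2$seeds, mask2)
  sizes <- tabulate(lab2[lab2 > 0])
  expect_length(sizes, 2)
  expect_lt(abs(diff(sizes)) / sum(sizes), 0.02)
  # warning fallback with no seeds
  expect_warning(
    lab3 <- local_max_clustering(resp, seeds[0, ], mask), "No seeds")
  expect_true(all(lab3[mask] == 1L))
})

test_that("region scores prefer single ellipses over dumbbells and specks", {
  img <- matrix(0, 60, 120)
  cfg <- seg_config(size_prior_mean = 220, size_prior_sd = 0.6)
  ellipse <- which(circle_map(60, 120, 30, 30, 8.4) > 0)   # ~ prior size
  lobe_a <- which(circle_map(60, 120, 30, 80, 8.4) > 0)
  lobe_b <- which(circle_map(60, 120, 30, 96, 8.4) > 0)
  dumbbell <- union(lobe_a, lobe_b)
  s_ell <- region_score(ellipse, img, cfg)
  s_dumb <- region_score(dumbbell, img, cfg)
  expect_gt(s_ell, s_dumb)
  # 1-pixel region: strongly negative size prior
  expect_lt(region_score(which(rect_map(60, 120, 5, 5, 5, 5) > 0), img, cfg),
            s_ell - 5)
})

test_that("merging joins oversplit fragments but not separate nuclei", {
  # one elliptical nucleus artificially split into left/right fragments
  whole <- circle_map(50, 50, 25, 25, 9)
  split_map <- whole
  split_map[, 26:50][split_map[, 26:50] > 0] <- 2L
  img <- matrix(0, 50, 50); img[whole > 0] <- 100
  cfg <- seg_config(size_prior_mean = sum(whole > 0), size_prior_sd = 0.6)
  merged <- merge_refinement(split_map, img, cfg)
  expect_equal(max(merged), 1L)
  expect_equal(merged > 0, whole > 0)
  # two well-separated nuclei stay separate (they are not even adjacent)
  two <- circle_map(50, 80, 25, 20, 8) + 2L * circle_map(50, 80, 25, 60, 8)
  merged2 <- merge_refinement(two, matrix(0, 50, 80), cfg)
  expect_equal(max(merged2), 2L)
  # adjacent full-size nuclei stay separate: the union is implausibly large
  # and poorly elliptical
  adj <- circle_map(50, 80, 25, 30, 9) + 2L * circle_map(50, 80, 25, 49, 9)
  merged3 <- merge_refinement(adj, matrix(0, 50, 80), cfg)
  expect_equal(max(merged3), 2L)
  # idempotence
  expect_identical(merge_refinement(merged, img, cfg), merged)
})

test_that("merging never lowers the minimum region score", {
  img <- make_image(image_spec(n_nuclei = 12, seed = 21))
  nuc <- img$channels$nuclear
  fit <- poisson_minimum_error_threshold(image_histogram(nuc))
  mask <- binarize(nuc, fit)
  sd <- multiscale_log_seeds(mask * 1, mask, seg_config())
  initial <- local_max_clustering(sd$response, sd$seeds, mask)
  cfg <- seg_config(size_prior_mean = median(tabulate(initial[initial > 0])))
  score_min <- function(lab) {
    px <- split(which(lab > 0), lab[lab > 0])
    min(vapply(px, region_score, numeric(1), image = nuc, config = cfg))
  }
  merged <- merge_refinement(initial, nuc, cfg)
  expect_gte(score_min(merged), score_min(initial) - 1e-9)
})

test_that("the full pipeline recovers the rendered nuclei", {
  img <- make_image(image_spec(n_nuclei = 20, seed = 6))
  labs <- segment_nuclei(img$channels$nuclear)
  n <- max(labs)
  expect_gte(n, 18)  # within 10% of 20
  expect_lte(n, 22)
  m <- match_labels(labs, img$truth$label_map)
  expect_gte(mean(m$jaccard), 0.7)
  # partition invariants: contiguous ids, background preserved
  expect_setequal(sort(unique(as.vector(labs))), 0:n)
  expect_true(all(labs[img$channels$nuclear < 15] == 0 |
                    img$truth$label_map[labs > 0][1] >= 0))
  # determinism
  expect_identical(labs, segment_nuclei(img$channels$nuclear))
  # blank image -> no nuclei
  expect_equal(max(segment_nuclei(matrix(0, 50, 50))), 0)
})
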