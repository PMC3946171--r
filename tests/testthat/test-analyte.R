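# Analyte quantification: background subtraction, compartments, positivity
# and per-image / per-tumor summaries.

test_that("a constant extranuclear offset is estimated and removed", {
  img0 <- make_image(image_spec(n_nuclei = 10, analyte_background = 0,
                                noise_model = "none", seed = 17))
  img30 <- make_image(image_spec(n_nuclei = 10, analyte_background = 30,
                                 noise_model = "none", seed = 17))
  lm <- img0$truth$label_map
  bs <- background_subtract(img30$channels$analyte, lm)
  expect_equal(bs$background, 30, tolerance = 0.5)
  v0 <- measure_expression(img0$channels$analyte, lm, analyte_config())
  v30 <- measure_expression(bs$corrected, lm, analyte_config())
  expect_equal(v30$value, v0$value, tolerance = 1)
  # zero-background image: essentially unchanged
  bs0 <- background_subtract(img0$channels$analyte, lm)
  expect_lt(bs0$background, 1)
  expect_lt(max(abs(bs0$corrected - pmax(img0$channels$analyte -
                                           bs0$background, 0))), 1e-12)
  # all-zero channel
  bsz <- background_subtract(matrix(0, 50, 50), matrix(0L, 50, 50))
  expect_equal(bsz$background, 0)
  expect_true(all(bsz$corrected == 0))
  expect_true(all(bs$corrected >= 0))
})

test_that("shift invariance holds under noise too", {
  spec0 <- image_spec(n_nuclei = 12, analyte_background = 0, seed = 18)
  spec30 <- image_spec(n_nuclei = 12, analyte_background = 30, seed = 18)
  img0 <- make_image(spec0); img30 <- make_image(spec30)
  lm <- img0$truth$label_map
  v0 <- measure_expression(
    background_subtract(img0$channels$analyte, lm)$corrected, lm,
    analyte_config())
  v30 <- measure_expression(
    background_subtract(img30$channels$analyte, lm)$corrected, lm,
    analyte_config())
  # per-cell values agree within Poisson-noise tolerance
  expect_lt(max(abs(v30$value - v0$value)), 5)
})

test_that("background subtraction needs extranuclear pixels", {
  expect_error(background_subtract(matrix(1, 5, 5), matrix(1L, 5, 5)),
               "extranuclear")
})

test_that("compartments measure where they claim to", {
  lm <- circle_map(40, 40, 20, 20, 8)
  ch <- matrix(0, 40, 40)
  ch[lm > 0] <- 42
  v <- measure_expression(ch, lm, analyte_config(compartment = "nuclear"))
  expect_equal(v$value, 42)
  # membrane-proximal signal only in the 2-px ring beyond the boundary
  ring <- (circle_map(40, 40, 20, 20, 10) > 0) & !(lm > 0)
  ch2 <- matrix(0, 40, 40)
  ch2[ring] <- 90
  v_nuc <- measure_expression(ch2, lm, analyte_config(compartment = "nuclear"))
  v_dil <- measure_expression(ch2, lm,
                              analyte_config(compartment = "nuclear_dilated",
                                             dilation_px = 2))
  expect_gt(v_dil$value, v_nuc$value)
  # zero dilation is identical to the nuclear compartment
  v_dil0 <- measure_expression(ch2, lm,
                               analyte_config(compartment = "nuclear_dilated",
                                              dilation_px = 0))
  expect_equal(v_dil0$value, v_nuc$value)
})

test_that("dilated compartments are claimed by the nearer nucleus", {
  lm <- matrix(0L, 10, 20)
  lm[4:6, 4:6] <- 1L
  lm[4:6, 12:14] <- 2L
  dil <- alcyto:::dilated_label_map(lm, 2L)
  # pixels adjacent to nucleus 1 belong to 1, never to 2
  expect_true(all(dil[4:6, 7:8] == 1L))
  expect_true(all(dil[4:6, 10:11] == 2L))
  expect_true(all(dil[lm > 0] == lm[lm > 0]))
})

test_that("positivity is a strict threshold", {
  expect_equal(classify_positive(c(5, 10, 15), 10), c(FALSE, FALSE, TRUE))
  expect_equal(classify_positive(c(0, 2), 0), c(FALSE, TRUE))
  expect_true(all(!classify_positive(c(1, 2, 3), 99)))
})

test_that("summaries compute the worked example and order percentiles", {
  cells <- tibble::tibble(
    image_id = rep(1, 10), tumor_id = rep("t1", 10),
    cell_class = c(rep("EC", 4), rep("non-EC", 6)),
    positive = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6)))
  rep1 <- summarize_analyte(cells)
  expect_equal(rep1$per_image$class_fraction, 0.4)
  expect_equal(rep1$per_image$positive_fraction, 0.5)
  # identical images: median = q25 = q75
  cells3 <- dplyr::bind_rows(cells, dplyr::mutate(cells, image_id = 2),
                             dplyr::mutate(cells, image_id = 3))
  rep3 <- summarize_analyte(cells3)
  pf <- dplyr::filter(rep3$per_tumor, quantity == "positive_fraction")
  expect_equal(pf$median, 0.5)
  expect_equal(pf$q25, pf$q75)
  # image with zero EC: missing, not zero
  none <- tibble::tibble(image_id = 9, tumor_id = "t1",
                         cell_class = "non-EC", positive = FALSE)
  repn <- summarize_analyte(dplyr::bind_rows(cells, none))
  expect_true(is.na(
    repn$per_image$positive_fraction[repn$per_image$image_id == 9]))
})

test_that("rendered positivity fractions are recovered across images", {
  reports <- purrr::map_dfr(1:10, function(i) {
    img <- make_image(image_spec(n_nuclei = 20, ec_fraction = 0.25,
                                 analyte_positive_fraction = 0.3, seed = 40 + i))
    lm <- img$truth$label_map
    corr <- background_subtract(img$channels$analyte, lm)$corrected
    vals <- measure_expression(corr, lm, analyte_config())
    tibble::tibble(
      image_id = i, tumor_id = "t1",
      cell_class = img$truth$cell_types$type,
      positive = classify_positive(vals$value, 50))
  })
  rep <- summarize_analyte(reports)
  pf <- dplyr::filter(rep$per_tumor, quantity == "positive_fraction")
  expect_lte(abs(pf$median - 0.3), 0.1 + 1e-9)
  expect_lte(pf$q25, pf$median)
  expect_lte(pf$median, pf$q75)
})
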