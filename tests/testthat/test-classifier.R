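test_that("quartile thresholds use linear interpolation and keep ordering", {
  th <- learn_thresholds(data.frame(FAP = c(1, 2, 3, 4)), markers = "FAP")
  expect_equal(th$q1, 1.75)
  expect_equal(th$median, 2.5)
  expect_equal(th$q3, 3.25)

  expect_warning(
    thc <- learn_thresholds(data.frame(FAP = rep(7, 10)), markers = "FAP"),
    "constant"
  )
  expect_equal(unlist(thc[, c("q1", "median", "q3")], use.names = FALSE),
               c(7, 7, 7))

  expect_error(learn_thresholds(data.frame(FAP = numeric(0))), "empty")
  expect_error(learn_thresholds(data.frame(FAP = 1:3), markers = "FAP"),
               "at least 4")

  # quartiles of a large log-normal sample converge to distribution quantiles
  set.seed(5)
  x <- 2^rnorm(2e5, 5, 1)
  th2 <- learn_thresholds(data.frame(FAP = x), markers = "FAP")
  expect_equal(th2$median, 2^5, tolerance = 0.01)
  expect_equal(th2$q1, 2^qnorm(0.25, 5, 1), tolerance = 0.01)
  expect_equal(th2$q3, 2^qnorm(0.75, 5, 1), tolerance = 0.01)
})

test_that("discretization bands are left-closed", {
  th <- structure(data.frame(marker = "FAP", q1 = 2, median = 5, q3 = 8),
                  class = c("caf_thresholds", "data.frame"))
  expect_equal(discretize_level(c(0, 1.99, 2, 4.9, 5, 6, 7.9, 8, 100),
                                "FAP", th),
               c(0, 0, 1, 1, 2, 2, 2, 3, 3))
  expect_error(discretize_level(1, "CD29", th), "no thresholds")
})

test_that("printed subset profiles classify to their subset", {
  pr <- caf_profiles("FACS")
  # canonical level vectors straight from the subset definitions
  expect_equal(classify_record(c(FAP = 3, CD29 = 3, SMA = 3, PDPN = 3,
                                 PDGFRB = 3), profiles = pr,
                               discretized = TRUE)$label, "CAF-S1")
  expect_equal(classify_record(c(FAP = 0, CD29 = 1, SMA = 0, PDPN = 1,
                                 PDGFRB = 1), profiles = pr,
                               discretized = TRUE)$label, "CAF-S2")
  expect_equal(classify_record(c(FAP = 0, CD29 = 2, SMA = 0, PDPN = 1,
                                 PDGFRB = 2), profiles = pr,
                               discretized = TRUE)$label, "CAF-S3")
  expect_equal(classify_record(c(FAP = 2, CD29 = 3, SMA = 3, PDPN = 1,
                                 PDGFRB = 2), profiles = pr,
                               discretized = TRUE)$label, "CAF-S4")
  # every admissible level combination of each subset maps back to it
  for (s in names(pr)) {
    combos <- do.call(expand.grid, pr[[s]])
    labs <- apply(combos, 1, function(v)
      classify_record(v, profiles = pr, discretized = TRUE)$label)
    expect_true(all(labs == s), info = s)
  }
})

test_that("classify_record agrees with the exhaustive oracle on all 4^5 vectors", {
  pr <- caf_profiles("FACS")
  grid <- all_level_vectors(names(pr[[1]]))
  mine <- apply(grid, 1, function(v)
    classify_record(v, profiles = pr, discretized = TRUE)$label)
  orac <- apply(grid, 1, function(v) oracle_classify(as.list(v), pr))
  expect_identical(mine, orac)
  # vectorized path agrees too (via fake thresholds mapping value = level)
  th <- structure(data.frame(marker = colnames(grid), q1 = 1, median = 2, q3 = 3),
                  class = c("caf_thresholds", "data.frame"))
  bulk <- classify_cells(as.data.frame(grid), th, pr)
  expect_identical(bulk$label, unname(mine))
})

test_that("panel mismatch and errors are caught", {
  pr <- caf_profiles("FACS")
  expect_error(classify_record(c(FAP = 3, CD29 = 3), profiles = pr,
                               discretized = TRUE), "panel mismatch")
  expect_error(classify_record(c(FAP = 1), profiles = pr), "panel mismatch")
})

test_that("threshold transposition is idempotent and quantile-equivariant", {
  cells <- simulate_reference_cells(500, seed = 7)
  th <- learn_thresholds(cells, markers = caf_panel("FACS"))
  th2 <- transpose_thresholds(cells, markers = caf_panel("FACS"),
                              marker_map = c())
  expect_equal(th$q1, th2$q1)
  expect_equal(th$median, th2$median)
  expect_equal(th$q3, th2$q3)
  expect_identical(attr(th2, "provenance"), "transposed")

  # affine image of the data gives the affine image of the thresholds
  scaled <- cells
  for (m in caf_panel("FACS")) scaled[[m]] <- 3 * scaled[[m]] + 10
  th3 <- transpose_thresholds(scaled, markers = caf_panel("FACS"),
                              marker_map = c())
  expect_equal(th3$median, 3 * th$median + 10)
  expect_equal(th3$q1, 3 * th$q1 + 10)
  expect_equal(th3$q3, 3 * th$q3 + 10)

  # PDPN maps onto FSP1 on the IHC modality
  href <- simulate_reference_hscores(200, seed = 8)
  thi <- transpose_thresholds(href, markers = caf_panel("FACS"))
  expect_true("FSP1" %in% thi$marker)
  expect_false("PDPN" %in% thi$marker)
  expect_true(all(thi$q1 <= thi$median & thi$median <= thi$q3))
})

test_that("H-score is the weighted intensity sum with range [0, 400]", {
  expect_equal(compute_hscore(c("4" = 1)), 400)
  expect_equal(compute_hscore(c("0" = 1)), 0)
  expect_equal(compute_hscore(c("1" = 0.5, "3" = 0.5)), 200)
  expect_equal(compute_hscore(c("0" = 0.2, "1" = 0.3, "2" = 0.1, "3" = 0.2,
                                "4" = 0.2)), 0.3 * 100 + 0.1 * 200 + 0.2 * 300 +
                 0.2 * 400)
  expect_error(compute_hscore(c("1" = 0.7)), "sum to 1")
  expect_error(compute_hscore(c("1" = 1.2, "2" = -0.2)), "\\[0, 1\\]")
})

test_that("stroma percentage is area ratio times 100", {
  expect_equal(stroma_percent(25, 100), 25)
  expect_equal(stroma_percent(0, 50), 0)
  expect_equal(stroma_percent(7, 7), 100)
  expect_error(stroma_percent(1, 0), "positive")
  expect_error(stroma_percent(5, 4), "fibroblastic_area")
})

test_that("enrichment calling applies the tree to extreme H-score patterns", {
  th <- structure(data.frame(marker = caf_panel("IHC"), q1 = 100, median = 200,
                             q3 = 300),
                  class = c("caf_thresholds", "data.frame"))
  hi <- as.data.frame(as.list(setNames(rep(350, 5), caf_panel("IHC"))))
  expect_equal(call_sample_enrichment(hi, th)$label, "CAF-S1")
  lo <- as.data.frame(as.list(setNames(c(50, 150, 50, 150, 150),
                                       caf_panel("IHC"))))
  expect_equal(call_sample_enrichment(lo, th)$label, "CAF-S2")
})

test_that("classification is invariant under monotone per-marker transforms", {
  # thresholds learned on the classified table itself: band membership is
  # then purely rank-based and exactly invariant under monotone maps
  cells <- simulate_facs_cohort(400, seed = 9)
  th <- learn_thresholds(cells, markers = caf_panel("FACS"))
  base <- classify_cells(cells, th, caf_profiles("FACS"))
  transforms <- list(FAP = function(x) x^3, CD29 = function(x) log1p(x),
                     SMA = function(x) 5 * x + 1, PDPN = sqrt,
                     PDGFRB = function(x) exp(x / 50))
  cells2 <- cells
  for (m in names(transforms)) cells2[[m]] <- transforms[[m]](cells2[[m]])
  th2 <- learn_thresholds(cells2, markers = caf_panel("FACS"))
  again <- classify_cells(cells2, th2, caf_profiles("FACS"))
  expect_identical(again$label, base$label)
  expect_identical(again$level_FAP, base$level_FAP)
})

test_that("every record gets exactly one of the four labels", {
  cells <- simulate_facs_cohort(300, seed = 15)
  ref <- simulate_reference_cells(500, seed = 16)
  th <- learn_thresholds(ref, markers = caf_panel("FACS"))
  calls <- classify_cells(cells, th, caf_profiles("FACS"))
  expect_equal(nrow(calls), 300)
  expect_true(all(calls$label %in% paste0("CAF-S", 1:4)))
  expect_true(all(calls$match_score >= 0 & calls$match_score <= 5))
})
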