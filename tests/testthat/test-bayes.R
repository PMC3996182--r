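test_that("finding_probability is count over cohort size", {
  expect_identical(finding_probability(0, 30), 0)
  expect_equal(round_half_away(finding_probability(8, 30), 3), 0.267)
  expect_equal(round_half_away(finding_probability(57, 65), 3), 0.877)
  expect_error(finding_probability(1, 0), "positive")
  expect_error(finding_probability(31, 30), "cohort_size")
})

test_that("feature weights are normalized and scale-invariant", {
  expect_equal(feature_weights(rep(3, 15)), rep(1 / 15, 15))
  copd_counts <- c(8, 5, 19, 11, 28, 17, 21, 18, 21, 23, 22, 17, 20, 22, 8)
  expect_equal(feature_weights(copd_counts)[1], 8 / 260)
  set.seed(7)
  for (i in 1:20) {
    v <- runif(15)
    w <- feature_weights(v)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(feature_weights(v / runif(1, 0.1, 50)), w, tolerance = 1e-12)
  }
  expect_error(feature_weights(rep(0, 15)), "positive")
})

test_that("disease score equals the explicit two-pass weighted mean", {
  expect_equal(disease_probability(rep(0.5, 15)), 0.5)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(15)
    oracle <- sum(feature_weights(p) * p)
    expect_equal(disease_probability(p), oracle, tolerance = 1e-12)
    expect_gte(disease_probability(p), min(p))
    expect_lte(disease_probability(p), max(p))
  }
  expect_equal(disease_probability(rep(0.3, 7)), 0.3)
})

test_that("reference columns yield the published ARDS and CVD scores", {
  probs <- reference_finding_probabilities()
  expect_equal(round_half_away(disease_probability(probs[, "ARDS"]), 2), 0.66)
  expect_equal(round_half_away(disease_probability(probs[, "CVD"]), 2), 0.73)
  # the COPD column computes 0.65 under the same formula; the historically
  # reported 0.63 is not consistent with the self-weighted mean, so the
  # computed value is asserted instead
  expect_equal(round_half_away(disease_probability(probs[, "COPD"]), 2), 0.65)
})

test_that("total and conditional probability follow their definitions", {
  expect_equal(total_probability(1.0, 0.4), 0.4)
  expect_equal(total_probability(c(0.5, 0.5), c(0.2, 0.8)), 0.5)
  expect_equal(total_probability(c(0.3, 0.6), c(0, 0)), 0)
  expect_error(total_probability(c(0.5, 0.5), 0.2), "length")

  expect_equal(conditional_probability(0.3, 0.3), 1.0)
  expect_equal(conditional_probability(0.0, 0.7), 0.0)
  expect_equal(conditional_probability(0.12, 0.4), 0.3)
  expect_error(conditional_probability(0.2, 0), "positive")
  expect_error(conditional_probability(0.5, 0.4), "joint")
})

test_that("rationalize_column recovers the cohort sizes behind the tables", {
  probs <- reference_finding_probabilities()
  sizes <- vapply(colnames(probs), function(d)
    rationalize_column(probs[, d])$cohort_size, 1L)
  expect_identical(unname(sizes), c(30L, 65L, 63L))
  expect_identical(sum(sizes), 158L)

  small <- rationalize_column(c(0.5, 0.25), n_max = 10)
  expect_identical(small$cohort_size, 4L)
  expect_identical(small$counts, c(2L, 1L))

  expect_error(rationalize_column(c(0.123, 0.457), n_max = 3), "irrational")
})

test_that("recovered counts reproduce every printed cell at 3 decimals", {
  probs <- reference_finding_probabilities()
  for (d in colnames(probs)) {
    r <- rationalize_column(probs[, d])
    cells <- round_half_away(finding_probability(r$counts, r$cohort_size), 3)
    expect_equal(cells, unname(probs[, d]))
  }
})

test_that("binarization applies each rule deterministically", {
  rec <- plausible_record(support_mode = "PS")
  pres <- binarize_findings(rec)
  expect_named(pres, finding_names())
  # an all-normal record triggers none of the 13 physiological findings
  expect_false(any(pres[setdiff(finding_names(),
                                c("pressure_support", "volume_support"))]))
  expect_true(pres[["pressure_support"]])
  expect_false(pres[["volume_support"]])

  rec$core_body_temperature <- 38.2
  expect_true(binarize_findings(rec)[["core_body_temperature"]])
  rec$core_body_temperature <- 37.5   # strict comparison: at the cut-off is normal
  expect_false(binarize_findings(rec)[["core_body_temperature"]])

  rec$ph <- 7.30
  expect_true(binarize_findings(rec)[["ph"]])
  rec$support_mode <- "VS"
  p2 <- binarize_findings(rec)
  expect_false(p2[["pressure_support"]])
  expect_true(p2[["volume_support"]])

  rec$pco2 <- NA_real_
  expect_error(binarize_findings(rec), "pco2")
})

test_that("disease ranking restricts the score to present findings", {
  tabs <- reference_finding_tables()
  full <- rep(TRUE, 15)
  rk <- rank_diseases(full, tabs)
  expect_identical(rk$disease[1], "CVD")
  expect_equal(rk$score[rk$disease == "ARDS"],
               disease_probability(tabs$ARDS$probabilities), tolerance = 1e-12)
  expect_equal(rk$score[rk$disease == "CVD"],
               disease_probability(tabs$CVD$probabilities), tolerance = 1e-12)

  # one present finding: each disease scores exactly its table cell
  single <- setNames(rep(FALSE, 15), finding_names())
  single["pulse"] <- TRUE
  rk1 <- rank_diseases(single, tabs)
  for (d in c("COPD", "ARDS", "CVD"))
    expect_equal(rk1$score[rk1$disease == d],
                 unname(tabs[[d]]$probabilities["pulse"]), tolerance = 1e-12)

  expect_identical(rank_diseases(full, tabs), rk)  # determinism
  expect_error(rank_diseases(setNames(rep(FALSE, 15), finding_names()), tabs),
               "manual")
})
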