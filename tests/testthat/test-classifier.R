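record <- function(ptau = 50, ab_ratio = 0.10, md_z = 0.5, infarct = FALSE,
                   ...) {
  tibble::tibble(ptau = ptau, ab_ratio = ab_ratio, md_z = md_z,
                 infarct = infarct, ...)
}

test_that("the Alzheimer axis combines the two CSF analytes as configured", {
  th <- default_thresholds()
  # group-mean Ptau of mixed dementia is far above any sensible cut
  expect_true(ad_axis_positive(record(ptau = 118.86, ab_ratio = 0.10), th))
  expect_false(ad_axis_positive(record(ptau = 50, ab_ratio = 0.10), th))
  expect_true(ad_axis_positive(record(ptau = 50, ab_ratio = 0.05), th))

  both <- thresholds(ad_axis_rule = "both")
  expect_false(ad_axis_positive(record(ptau = 120, ab_ratio = 0.10), both))
  expect_true(ad_axis_positive(record(ptau = 120, ab_ratio = 0.05), both))
  expect_false(ad_axis_positive(record(ptau = 120, ab_ratio = 0.10),
                                thresholds(ad_axis_rule = "amyloid_only")))
  expect_true(ad_axis_positive(record(ptau = 120, ab_ratio = 0.10),
                               thresholds(ad_axis_rule = "ptau_only")))

  # positivity at the exact cut
  expect_true(ad_axis_positive(record(ptau = th$ptau_high, ab_ratio = 0.10), th))
  expect_true(ad_axis_positive(record(ptau = 40, ab_ratio = th$ab_ratio_low), th))

  err <- expect_error(
    ad_axis_positive(record(ptau = NA_real_)),
    class = "mixstrat_missing_data"
  )
  expect_match(conditionMessage(err), "ptau")
})

test_that("the vascular axis thresholds the diffusivity z-score", {
  th <- default_thresholds()
  # published group means: SIVD 2.94 is vascular-positive, AD 0.74 is not
  expect_true(vascular_axis_positive(record(md_z = 2.94), th))
  expect_false(vascular_axis_positive(record(md_z = 0.74), th))
  expect_true(vascular_axis_positive(record(md_z = th$md_z_high), th))
  expect_error(vascular_axis_positive(tibble::tibble(ptau = 1), th),
               class = "mixstrat_missing_data")
})

test_that("the double dichotomy maps the four quadrants and the MI override", {
  th <- default_thresholds()
  hi_ad <- 120; lo_ad <- 45   # ptau on either side of the cut
  hi_v <- 3; lo_v <- 0.5      # md_z on either side of the cut
  expect_equal(classify_dichotomy(record(ptau = hi_ad, md_z = hi_v), th), "MX")
  expect_equal(classify_dichotomy(record(ptau = hi_ad, md_z = lo_v), th), "AD")
  expect_equal(classify_dichotomy(record(ptau = lo_ad, md_z = hi_v), th), "SIVD")
  expect_equal(classify_dichotomy(record(ptau = lo_ad, md_z = lo_v), th), "LA")
  # infarct overrides every quadrant
  for (p in c(hi_ad, lo_ad)) {
    for (m in c(hi_v, lo_v)) {
      expect_equal(
        classify_dichotomy(record(ptau = p, md_z = m, infarct = TRUE), th),
        "MI"
      )
    }
  }
})

test_that("the dichotomy is a total partition with MX iff both axes positive", {
  th <- default_thresholds()
  grid <- tidyr::expand_grid(
    ptau = c(120, 45), md_z = c(3, 0.5), infarct = c(TRUE, FALSE)
  )
  grid$ab_ratio <- 0.10
  labels <- classify_dichotomy(grid, th)
  expect_true(all(labels %in% c("MI", "MX", "AD", "SIVD", "LA")))
  expect_equal(length(labels), nrow(grid))
  non_mi <- !grid$infarct
  both_pos <- ad_axis_positive(grid, th) & vascular_axis_positive(grid, th)
  expect_equal(labels[non_mi] == "MX", both_pos[non_mi])
})

test_that("axis positivity is monotone in its biomarker", {
  th <- default_thresholds()
  withr::with_seed(61, {
    for (i in 1:50) {
      r <- record(ptau = runif(1, 10, 150), ab_ratio = runif(1, 0.02, 0.2),
                  md_z = runif(1, -1, 5))
      if (ad_axis_positive(r, th)) {
        r2 <- r; r2$ptau <- r$ptau + runif(1, 0, 100)
        expect_true(ad_axis_positive(r2, th))
      }
      if (vascular_axis_positive(r, th)) {
        r2 <- r; r2$md_z <- r$md_z + runif(1, 0, 5)
        expect_true(vascular_axis_positive(r2, th))
      }
    }
  })
})

test_that("feature vectors binarize records deterministically", {
  th <- default_thresholds()
  # AD-like profile: very low memory, normal diffusivity, elevated Ptau
  ad_like <- tibble::tibble(
    hyperreflexia = FALSE, imbalance = FALSE, t_executive = 48,
    t_memory = 25, wmh_present = FALSE, md_z = 0.5, ab_ratio = 0.05,
    ptau = 150, albumin_index = 5, infarct = FALSE
  )
  fv <- feature_vector(ad_like, th)
  expect_true(fv$memory_deficit)
  expect_false(fv$md_dti_high)
  expect_true(fv$ptau_positive)
  expect_false(fv$executive_deficit)

  normal <- tibble::tibble(
    hyperreflexia = FALSE, imbalance = FALSE, t_executive = 52,
    t_memory = 55, wmh_present = FALSE, md_z = 0, ab_ratio = 0.10,
    ptau = 45, albumin_index = 5, infarct = FALSE
  )
  expect_false(any(unlist(feature_vector(normal, th))))

  boundary <- tibble::tibble(
    hyperreflexia = TRUE, imbalance = TRUE,
    t_executive = th$t_executive_low, t_memory = th$t_memory_low,
    wmh_present = TRUE, md_z = th$md_z_high, ab_ratio = th$ab_ratio_low,
    ptau = th$ptau_high, albumin_index = th$albumin_index_high
  )
  expect_true(all(unlist(feature_vector(boundary, th))))
})

test_that("feature matcher recovers each archetype with a perfect score", {
  fm <- default_feature_matrix()
  for (lab in colnames(fm)) {
    fv <- tibble::as_tibble(t(fm[, lab]))
    res <- classify_feature_matrix(fv, fm)
    expect_equal(res$label, lab)
    expect_equal(res[[paste0("score_", lab)]], 9)
    # and both classifiers agree on a record built at the archetype
    rec <- archetype_record(lab)
    expect_equal(classify_dichotomy(rec), lab)
    expect_equal(
      classify_feature_matrix(feature_vector(rec), fm)$label, lab
    )
  }
})

test_that("feature-matrix ties resolve by the documented precedence", {
  fm <- default_feature_matrix()
  # SIVD and MX archetypes differ only in executive/memory/amyloid/ptau;
  # flipping executive_deficit off the SIVD archetype and memory_deficit on
  # lands equidistant between the two columns
  fv <- tibble::as_tibble(t(fm[, "SIVD"]))
  fv$executive_deficit <- FALSE
  fv$memory_deficit <- TRUE
  res <- classify_feature_matrix(fv, fm)
  expect_equal(res$score_SIVD, res$score_MX)
  expect_equal(res$label, "MX")
})

test_that("feature matcher equals a brute-force Hamming minimizer", {
  fm <- default_feature_matrix()
  # all 512 possible feature vectors, exhaustively
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 9))
  names(grid) <- rownames(fm)
  res <- classify_feature_matrix(tibble::as_tibble(grid), fm)
  oracle <- apply(as.matrix(grid), 1, hamming_oracle, fm = fm)
  expect_equal(res$label, unname(oracle))
  # scores complement distances: score = 9 - Hamming distance
  d_mx <- apply(as.matrix(grid), 1, function(r) sum(fm[, "MX"] != r))
  expect_equal(res$score_MX, 9 - unname(d_mx))
})

test_that("cohort classification handles missing data row-wise", {
  well <- well_separated_params()
  cfg <- cohort_config(sizes = c(SIVD = 10, AD = 10, MX = 10, LA = 10,
                                 CONTROL = 10, MI = 10), seed = 17)
  cohort <- generate_cohort(cfg, well)

  out <- classify_cohort(cohort)
  expect_equal(attr(out, "n_unclassified"), 0)

  # drop a required column: everything is UNCLASSIFIED, nothing errors
  no_md <- cohort[, names(cohort) != "md_z"]
  out2 <- classify_cohort(no_md)
  expect_true(all(out2$biological_label_predicted == unclassified_label()))
  expect_equal(attr(out2, "n_unclassified"), nrow(cohort))
  expect_match(attr(out2, "unclassified_reasons")$reason[1], "md_z")

  # puncture single cells
  holed <- cohort
  holed$ptau[3] <- NA
  holed$infarct[5] <- NA
  out3 <- classify_cohort(holed)
  expect_equal(attr(out3, "n_unclassified"), 2)
  expect_equal(sort(attr(out3, "unclassified_reasons")$row), c(3L, 5L))
  expect_equal(out3$biological_label_predicted[3], unclassified_label())
  expect_false(out3$biological_label_predicted[4] == unclassified_label())

  # empty table in, empty labeled table out
  empty <- cohort[0, ]
  out4 <- classify_cohort(empty)
  expect_equal(nrow(out4), 0)
  expect_true("biological_label_predicted" %in% names(out4))
})

test_that("well-separated cohorts are recovered at default thresholds", {
  well <- well_separated_params()
  cfg <- cohort_config(sizes = c(SIVD = 50, AD = 50, MX = 50, LA = 50,
                                 MI = 50, CONTROL = 50), seed = 23)
  cohort <- generate_cohort(cfg, well)
  out <- classify_cohort(cohort)

  patients <- out$biological_label != "CONTROL"
  acc <- mean(out$biological_label_predicted[patients] ==
                out$biological_label[patients])
  expect_gte(acc, 0.9)

  # controls and LA never drift into the degenerative or mixed quadrants
  calm <- out$biological_label %in% c("CONTROL", "LA")
  expect_false(any(out$biological_label_predicted[calm] %in% c("MX", "AD")))

  # the feature matcher agrees with the dichotomy on the archetypal groups
  fmx <- classify_cohort(cohort, method = "feature_matrix")
  agree <- mean(fmx$biological_label_predicted[patients &
                                                 cohort$biological_label != "MI"] ==
                  out$biological_label_predicted[patients &
                                                   cohort$biological_label != "MI"])
  expect_gte(agree, 0.9)
})
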