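rule <- classification_rule()

test_that("length and ellipticity thresholds classify marks (inclusive)", {
  marks <- data.frame(
    length_nm = c(1250, 400, 700, 1600, 700, 1500),
    width_nm  = c(590, 400, 538, 600, 539, 1153))
  lab <- classify_marks(marks, rule)
  # 700/538 = 1.301 passes; 700/539 = 1.2987 fails; 1500/1153 = 1.3010
  expect_equal(as.character(lab),
               c("virion", "other", "virion", "other", "other", "virion"))
  # exact boundary values are inclusive
  expect_equal(as.character(classify_marks(
    data.frame(length_nm = c(700, 1500), width_nm = c(700, 1500) / 1.3),
    rule)), c("virion", "virion"))
})

test_that("classification ignores angle and length/width order on ingest", {
  a <- data.frame(length_nm = 1250, width_nm = 590, angle_deg = 10)
  b <- data.frame(length_nm = 590, width_nm = 1250, angle_deg = 100)
  c <- data.frame(length_nm = 1250, width_nm = 590, angle_deg = 170)
  expect_equal(classify_marks(a, rule), classify_marks(b, rule))
  expect_equal(classify_marks(a, rule), classify_marks(c, rule))
  swapped <- as_object_marks(b)
  expect_equal(swapped$length_nm, 1250)
  expect_equal(swapped$width_nm, 590)
})

test_that("invalid marks are rejected with a diagnostic", {
  expect_error(as_object_marks(data.frame(length_nm = 500, width_nm = 0)),
               "non-positive")
})

test_that("false-positive rate pools control cells", {
  mk <- function(n_fp, n_other) {
    rbind(if (n_fp > 0) data.frame(length_nm = rep(1000, n_fp),
                                   width_nm = rep(500, n_fp)),
          data.frame(length_nm = rep(400, n_other),
                     width_nm = rep(380, n_other)))
  }
  clean <- list(cell_annotation("c1", 0, mk(0, 120)),
                cell_annotation("c2", 0, mk(0, 80)))
  expect_equal(false_positive_rate(clean, rule), 0)
  dirty <- list(cell_annotation("c1", 0, mk(2, 118)),
                cell_annotation("c2", 0, mk(0, 80)))
  expect_equal(false_positive_rate(dirty, rule), 0.01)
  empty <- list(cell_annotation("c1", 0,
                                data.frame(length_nm = numeric(0),
                                           width_nm = numeric(0))))
  expect_error(false_positive_rate(empty, rule), "empty controls")
  expect_error(false_positive_rate(list(), rule), "control")
})

test_that("false-positive rate matches the generator's confusion rate", {
  controls <- simulate_annotation_cohort(hpi = 0, cells_per_time = 40,
                                         mean_virions = 0,
                                         n_distractors = 30,
                                         elongated_fraction = 0.05,
                                         seed = 21)
  rate <- false_positive_rate(controls, rule)
  truth <- do.call(rbind, lapply(controls, `[[`, "marks"))
  true_rate <- mean(classify_marks(truth, rule) == "virion")
  expect_equal(rate, true_rate, tolerance = 1e-12)
  # elongated debris is built to fool the rule, so the rate is near the
  # programmed elongated fraction
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("orientation miss probability matches the projection geometry", {
  expect_equal(orientation_miss_probability(1000, 700),
               1 - sqrt(1 - 0.49), tolerance = 1e-12)
  expect_equal(orientation_miss_probability(1000, 1e-9), 0,
               tolerance = 1e-12)
  expect_warning(p <- orientation_miss_probability(500, 700), "missed")
  expect_equal(p, 1)
  # Monte-Carlo oracle agreement
  th <- sample_orientation(1e6, seed = 13)
  expect_lt(abs(mean(1000 * sin(th) < 700) -
                  orientation_miss_probability(1000, 700)), 0.0015)
})

test_that("counting adds the false-positive and orientation components", {
  marks <- rbind(data.frame(length_nm = rep(1250, 300),
                            width_nm = rep(590, 300)),
                 data.frame(length_nm = rep(400, 200),
                            width_nm = rep(380, 200)))
  ann <- cell_annotation("c1", 24, marks)
  vc <- count_with_uncertainty(ann, rule, fp_rate = 0.01,
                               miss_prob = 0.2859)
  expect_equal(vc$n_virions, 300)
  expect_equal(vc$n_marks_total, 500)
  expect_equal(vc$components[["false_positive_estimate"]], 5.0)
  expect_equal(vc$components[["orientation_miss_estimate"]],
               300 * 0.2859 / (1 - 0.2859), tolerance = 1e-9)
  expect_equal(vc$uncertainty, 125.1, tolerance = 1e-3)
  # the cruder direct mode scales by p instead of p/(1-p)
  vc2 <- count_with_uncertainty(ann, rule, fp_rate = 0.01,
                                miss_prob = 0.2859, miss_mode = "direct")
  expect_equal(vc2$components[["orientation_miss_estimate"]], 300 * 0.2859)
  expect_error(count_with_uncertainty(ann, rule, miss_prob = 1), "< 1")
})

test_that("empty annotations count zero with zero uncertainty", {
  ann <- cell_annotation("c0", 6, data.frame(length_nm = numeric(0),
                                             width_nm = numeric(0)))
  vc <- count_with_uncertainty(ann, rule, fp_rate = 0.01, miss_prob = 0.3)
  expect_equal(vc$n_virions, 0)
  expect_equal(vc$uncertainty, 0)
})

test_that("uncertainty grows with mark count and miss probability", {
  marks <- data.frame(length_nm = rep(1250, 50), width_nm = rep(590, 50))
  base <- count_with_uncertainty(cell_annotation("a", 1, marks), rule,
                                 fp_rate = 0.02, miss_prob = 0.2)
  more_marks <- rbind(marks, data.frame(length_nm = rep(300, 50),
                                        width_nm = rep(290, 50)))
  u2 <- count_with_uncertainty(cell_annotation("a", 1, more_marks), rule,
                               fp_rate = 0.02, miss_prob = 0.2)
  expect_gte(u2$uncertainty, base$uncertainty)
  u3 <- count_with_uncertainty(cell_annotation("a", 1, marks), rule,
                               fp_rate = 0.02, miss_prob = 0.35)
  expect_gte(u3$uncertainty, base$uncertainty)
})

test_that("cohort summary averages per timepoint in hpi order", {
  ann <- simulate_annotation_cohort(hpi = c(54, 18, 30), cells_per_time = 4,
                                    mean_virions = c(150, 10, 60),
                                    seed = 17)
  counts <- lapply(ann, count_with_uncertainty, rule = rule,
                   fp_rate = 0.01, miss_prob = 0.21)
  sm <- cohort_summary(counts)
  expect_equal(sm$hpi, c(18, 30, 54))
  expect_equal(sm$n_cells, rep(4, 3))
  # programmed growth recovered up to sampling noise and orientation loss
  expect_true(all(diff(sm$mean_virions) > 0))
  one <- cohort_summary(counts[1])
  expect_equal(one$mean_virions, counts[[1]]$n_virions)
})

test_that("phantom virions above the effective cutoff are always classified", {
  pr <- small_cell_projection(n_virions = 120, seed = 31)
  marks <- pr$ground_truth$marks
  lab <- classify_marks(marks, rule)
  cutoff <- effective_min_projected_length(rule, marks$width_nm)
  visible <- marks$length_nm >= cutoff & marks$length_nm <= rule$max_length
  expect_true(all(lab[visible] == "virion"))
  expect_true(all(lab[!visible] == "other"))
})

test_that("measured orientation miss matches the closed form at the cutoff", {
  # many virions of fixed size, random orientations
  n <- 4000
  th <- sample_orientation(n, seed = 37)
  L <- 1250; W <- 590
  marks <- data.frame(length_nm = pmax(sqrt(L^2 * sin(th)^2 +
                                              W^2 * cos(th)^2), W),
                      width_nm = W)
  lab <- classify_marks(marks, rule)
  cutoff <- effective_min_projected_length(rule, W)  # 767 nm
  p_true <- spheroid_miss_probability(L, W, cutoff)
  # same number via the rod formula on the reduced axes
  expect_equal(p_true, orientation_miss_probability(
    sqrt(L^2 - W^2), sqrt(cutoff^2 - W^2)), tolerance = 1e-12)
  miss <- mean(lab == "other")
  expect_lt(abs(miss - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  # degenerate cutoffs
  expect_equal(spheroid_miss_probability(L, W, W), 0)
  expect_equal(spheroid_miss_probability(L, W, L), 1)
})
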