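test_that("subgroup pooling partitions the studies exactly", {
  recs <- demo_records(k = 9, seed = 61)
  est <- estimate_effects(recs, "allele")
  for (axis in c("ethnicity", "study_size", "intervention")) {
    sg <- subgroup_analysis(est, axis)
    expect_equal(sum(vapply(sg, function(p) p$k, numeric(1))), nrow(est))
  }
  # missing axis values collect in an "unknown" subgroup
  est2 <- est
  est2$ethnicity[c(1, 4)] <- NA
  sg2 <- subgroup_analysis(est2, "ethnicity")
  expect_true("unknown" %in% names(sg2))
  expect_equal(sg2$unknown$k, 2)

  # all studies in one subgroup reproduce the overall pool
  est3 <- est
  est3$ethnicity <- "Asian"
  sg3 <- subgroup_analysis(est3, "ethnicity")
  expect_equal(names(sg3), "Asian")
  expect_equal(sg3$Asian$pooled_log_or, pool_random_dl(est)$pooled_log_or)

  # boundary: total N equal to the threshold is classed "large"
  est4 <- est
  est4$size <- c(500, rep(100, nrow(est) - 1))
  sg4 <- subgroup_analysis(est4, "study_size", size_threshold = 500)
  expect_equal(sg4$large$k, 1)
})

test_that("cumulative meta-analysis steps by year and ends at the overall pool", {
  est <- rand_estimates(6)
  est$year <- c(1995, 1995, 1999, 1999, 1999, 2004)
  cm <- cumulative_meta(est)
  expect_equal(cm$year, c(1995, 1999, 2004))
  expect_equal(cm$k_so_far, c(2, 5, 6))
  overall <- pool_random_dl(est)
  expect_equal(cm$pooled_or[3], overall$pooled_or, tolerance = 1e-12)
  expect_equal(cm$tau2[3], overall$tau2, tolerance = 1e-12)

  # a missing year is excluded with a diagnostic, a single year is one step
  est$year[2] <- NA
  cm2 <- cumulative_meta(est)
  expect_equal(attr(cm2, "excluded")$study_id, "s02")
  expect_equal(max(cm2$k_so_far), 5)
  one <- rand_estimates(3)
  one$year <- 2001
  cm3 <- cumulative_meta(one)
  expect_equal(nrow(cm3), 1)
  expect_equal(cm3$pooled_or, pool_random_dl(one)$pooled_or)
})

test_that("cumulative final step equals the overall pool for all five models", {
  recs <- demo_records(k = 8, seed = 62)
  for (m in genetic_models()) {
    est <- estimate_effects(recs, m)
    cm <- cumulative_meta(est)
    overall <- pool_random_dl(est)
    expect_equal(cm$pooled_or[nrow(cm)], overall$pooled_or, tolerance = 1e-12)
    expect_equal(cm$k_so_far[nrow(cm)], nrow(est))
  }
})

test_that("leave-one-out produces k pools of k-1 studies", {
  est <- rand_estimates(5)
  loo <- leave_one_out(est)
  expect_equal(nrow(loo), 5)
  expect_true(all(loo$k == 4))
  expect_equal(loo$omitted_study_id, est$study_id)
  expect_error(leave_one_out(rand_estimates(1)), "at least 2")

  # omitting a study with essentially no weight leaves the pool unchanged
  est2 <- data.frame(study_id = sprintf("s%02d", 1:6),
                     log_or = c(0.30, 0.31, 0.29, 0.305, 0.295, 0.3),
                     se = rep(0.3, 6))
  est2 <- rbind(est2, data.frame(study_id = "tiny", log_or = 3, se = 1e4))
  loo2 <- leave_one_out(est2)
  full_minus_tiny <- pool_random_dl(est2[est2$study_id != "tiny", ])
  with_tiny <- pool_random_dl(est2)
  expect_equal(with_tiny$pooled_log_or, full_minus_tiny$pooled_log_or,
               tolerance = 1e-6)
  expect_equal(loo2$pooled_or[loo2$omitted_study_id == "tiny"],
               full_minus_tiny$pooled_or, tolerance = 1e-12)
})

test_that("the full analysis report covers strata, models and diagnostics", {
  stent <- demo_records(k = 7, seed = 63)
  balloon <- simulate_studies(sim_config(k_studies = 4, seed = 64,
                                         intervention = "balloon",
                                         n_case_range = c(60, 150),
                                         n_ctrl_range = c(100, 300)))
  recs <- genassocmeta:::as_study_records(rbind(as.data.frame(stent),
                                                as.data.frame(balloon)))
  rep <- run_full_analysis(recs)
  expect_s3_class(rep, "meta_report")
  expect_setequal(names(rep$strata), c("stent", "balloon"))
  expect_setequal(names(rep$strata$stent), genetic_models())
  entry <- rep$strata$stent$allele
  expect_equal(entry$pooled$k, 7)
  expect_s3_class(entry$heterogeneity, "heterogeneity_verdict")
  expect_equal(nrow(entry$funnel), 7)
  expect_equal(nrow(entry$leave_one_out), 7)
  tab <- tabulate_stratum(rep, "stent")
  expect_true(all(genetic_models() %in% tab$model))
  # published-table cell format: "OR (low-high); p"
  expect_match(tab$or_ci_p[1], "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}-\\d+\\.\\d{2}\\); ")
  expect_match(format_or_ci(1.3096, c(1.0833, 1.5831), 0.00624),
               "1.31 (1.08-1.58); 0.00624", fixed = TRUE)
  expect_equal(format_p(3e-5), "<10^-4")
})

test_that("a one-study cohort reports that study's five contrasts", {
  recs <- demo_records(k = 1, seed = 65)
  rep <- run_full_analysis(recs)
  for (m in genetic_models()) {
    entry <- rep$strata$stent[[m]]
    expect_equal(entry$pooled$k, 1)
    est <- estimate_effects(recs, m)
    expect_equal(entry$pooled$pooled_log_or, est$log_or)
  }
})

test_that("identical input and config give byte-identical reports", {
  recs <- demo_records(k = 6, seed = 66)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(run_full_analysis(recs), d1)
  write_report(run_full_analysis(recs), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("ACE-inhibitor strata pool through the subgroup machinery", {
  recs <- demo_records(k = 6, seed = 67)
  recs$ace_inhibitor_stratum <- rep(c("treated", "untreated"), 3)
  est <- estimate_effects(recs, "recessive")
  sg <- subgroup_analysis(est, "ace_inhibitor")
  expect_setequal(names(sg), c("treated", "untreated"))
  expect_equal(sg$treated$k + sg$untreated$k, 6)
})
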