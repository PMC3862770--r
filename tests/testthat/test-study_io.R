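fixture_path <- system.file("extdata", "ptca_restenosis_studies.csv",
                            package = "genassocmeta")

test_that("the bundled restenosis cohort loads with its published totals", {
  studies <- load_studies(fixture_path)
  expect_s3_class(studies, "study_records")
  expect_equal(nrow(studies), 33)

  lv <- studies[studies$study_id == "Lv", ]
  expect_equal(lv$year, 2012)
  expect_equal(lv$cases_total, 81)
  expect_equal(lv$controls_total, 315)

  cs <- summarize_cohort(studies)
  expect_equal(cs$counts_by_intervention$stent,
               c(cases = 1952, controls = 6598))
  expect_equal(cs$counts_by_intervention$balloon,
               c(cases = 1076, controls = 1567))
  expect_equal(cs$total_patients, 11193)
  expect_equal(unname(cs$counts_by_quality["High"]), 21L)
  expect_equal(unname(cs$counts_by_quality["Median"]), 12L)
})

test_that("loading validates rows and reports schema problems", {
  header <- paste(c("study_id", "year", "ethnicity", "intervention",
                    "n_case_II", "n_case_ID", "n_case_DD",
                    "n_ctrl_II", "n_ctrl_ID", "n_ctrl_DD"), collapse = ",")
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(header, tmp)
  expect_equal(nrow(load_studies(tmp)), 0)

  writeLines(c(header, "s1,2001,Asian,stent,-1,10,10,5,5,5"), tmp)
  expect_error(load_studies(tmp), "row 1.*s1.*n_case_II")
  lenient <- load_studies(tmp, strict = FALSE)
  expect_equal(nrow(lenient), 0)
  expect_match(attr(lenient, "rejected")$reason, "n_case_II")

  writeLines(c(header, "s1,2001,Asian,stent,NA,10,10,5,5,5"), tmp)
  expect_error(load_studies(tmp), "partial genotype counts")

  writeLines("study_id,year,ethnicity\ns1,2001,Asian", tmp)
  expect_error(load_studies(tmp), "intervention")
})

test_that("declared totals and allele counts must agree with genotypes", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,year,ethnicity,intervention,n_case_II,n_case_ID,n_case_DD,n_ctrl_II,n_ctrl_ID,n_ctrl_DD,a_case_I,a_case_D,cases_total",
               "s1,2001,Asian,stent,10,20,10,5,5,5,40,41,40"), tmp)
  expect_error(load_studies(tmp), "D allele count disagrees")
  writeLines(c("study_id,year,ethnicity,intervention,n_case_II,n_case_ID,n_case_DD,n_ctrl_II,n_ctrl_ID,n_ctrl_DD,cases_total",
               "s1,2001,Asian,stent,10,20,10,5,5,5,99"), tmp)
  expect_error(load_studies(tmp), "total disagrees")
})

test_that("write/load round trip is the identity on all schema fields", {
  studies <- demo_records(k = 8, seed = 31)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_studies(studies, tmp)
  back <- load_studies(tmp)
  shared <- setdiff(names(studies), "ethnicity_label")
  expect_equal(as.data.frame(back)[shared], as.data.frame(studies)[shared])
})

test_that("inclusion filters drop by follow-up window, missing counts and HWE", {
  studies <- load_studies(fixture_path)
  f <- apply_inclusion_filters(studies)
  expect_true("Yoshida" %in% f$dropped$study_id)
  expect_equal(f$dropped$reason[f$dropped$study_id == "Yoshida"],
               "followup_window")
  # all Table 1 rows lack genotype counts, so nothing survives
  expect_true(all(f$dropped$reason %in% c("followup_window", "no_counts")))
  expect_equal(nrow(f$kept) + nrow(f$dropped), nrow(studies))

  # widened window keeps the 5.2-year cohort (counts permitting)
  sim <- demo_records(k = 4, seed = 9)
  sim$followup_months[1] <- 62.4
  f2 <- apply_inclusion_filters(sim)
  expect_equal(f2$dropped$reason, "followup_window")
  f3 <- apply_inclusion_filters(sim, meta_config(followup_window = c(3, 120)))
  expect_equal(nrow(f3$dropped), 0)

  # HWE violations flag by default, exclude behind the config switch
  sim2 <- demo_records(k = 5, seed = 10)
  sim2$n_ctrl_II[1] <- 200; sim2$n_ctrl_ID[1] <- 0; sim2$n_ctrl_DD[1] <- 200
  sim2 <- add_hwe_flags(sim2)
  expect_true(sim2$hwe_violation[1])
  expect_equal(nrow(apply_inclusion_filters(sim2)$dropped), 0)
  f4 <- apply_inclusion_filters(sim2, meta_config(exclude_hwe_violations = TRUE))
  # the distorted study is excluded; simulated controls may add the
  # occasional alpha-level flag of their own
  expect_true("hwe_violation" %in% f4$dropped$reason &&
                sim2$study_id[1] %in% f4$dropped$study_id)
  expect_true(all(f4$dropped$reason == "hwe_violation"))
})

test_that("cohort summary is invariant under row permutation", {
  studies <- load_studies(fixture_path)
  set.seed(4)
  shuffled <- studies[sample(nrow(studies)), ]
  expect_equal(summarize_cohort(shuffled), summarize_cohort(studies))
  empty <- summarize_cohort(studies[0, ])
  expect_equal(empty$total_patients, 0)
  expect_equal(empty$n_datasets, 0)
})

test_that("the HWE chi-square matches hand values and chisq.test", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)
  expect_equal(perfect$allele_freq_D, 0.5)

  h <- hwe_test(30, 40, 30)
  expect_equal(h$chi2, 4.0)
  expect_equal(h$p_value, 0.04550026, tolerance = 1e-6)

  expect_error(hwe_test(0, 0, 0), "zero")
  expect_error(hwe_test(-1, 5, 5), "non-negative")

  # allele relabeling I <-> D swaps II and DD but cannot change the fit
  set.seed(11)
  for (i in 1:25) {
    g <- as.vector(stats::rmultinom(1, 200, c(0.3, 0.45, 0.25)))
    a <- hwe_test(g[1], g[2], g[3])
    b <- hwe_test(g[3], g[2], g[1])
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    expect_equal(a$allele_freq_D, 1 - b$allele_freq_D, tolerance = 1e-12)
    # chisq.test as an independent oracle for the statistic at the
    # estimated allele frequency
    p <- (2 * g[3] + g[2]) / (2 * sum(g))
    or_chi <- suppressWarnings(
      stats::chisq.test(g, p = c((1 - p)^2, 2 * p * (1 - p), p^2)))
    expect_equal(a$chi2, unname(or_chi$statistic), tolerance = 1e-10)
  }
})
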