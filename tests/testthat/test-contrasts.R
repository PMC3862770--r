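geno_rec <- list(study_id = "g1",
                 n_case_II = 10, n_case_ID = 20, n_case_DD = 10,
                 n_ctrl_II = 30, n_ctrl_ID = 20, n_ctrl_DD = 10)
allele_rec <- list(study_id = "a1",
                   n_case_II = NA, n_case_ID = NA, n_case_DD = NA,
                   n_ctrl_II = NA, n_ctrl_ID = NA, n_ctrl_DD = NA,
                   a_case_I = 40, a_case_D = 40, a_ctrl_I = 80, a_ctrl_D = 40)

test_that("each genetic model produces its defining 2x2 cells", {
  cells <- function(m) {
    t <- build_contrast(geno_rec, m)
    c(t$a, t$b, t$c, t$d)
  }
  expect_equal(cells("allele"), c(40, 40, 40, 80))
  expect_equal(cells("dominant"), c(30, 10, 30, 30))
  expect_equal(cells("recessive"), c(10, 30, 10, 50))
  expect_equal(cells("heterozygous"), c(20, 10, 20, 30))
  expect_equal(cells("homozygous"), c(10, 10, 10, 30))
})

test_that("allele-only studies are eligible for the allele contrast only", {
  t <- build_contrast(allele_rec, "allele")
  expect_equal(c(t$a, t$b, t$c, t$d), c(40, 40, 40, 80))
  for (m in setdiff(genetic_models(), "allele"))
    expect_error(build_contrast(allele_rec, m), "allele contrast")
})

test_that("continuity correction touches only tables with zero cells", {
  mk <- function(a, b, c, d)
    structure(list(study_id = "t", model = "allele", a = a, b = b, c = c,
                   d = d, corrected = FALSE), class = "contrast_table")
  z <- continuity_correct(mk(0, 10, 5, 5))
  expect_equal(c(z$a, z$b, z$c, z$d), c(0.5, 10.5, 5.5, 5.5))
  expect_true(z$corrected)
  u <- continuity_correct(mk(3, 4, 5, 6))
  expect_equal(c(u$a, u$b, u$c, u$d), c(3, 4, 5, 6))
  expect_false(u$corrected)
  expect_error(continuity_correct(mk(0, 0, 0, 0)),
               class = "noninformative_study")
  k <- continuity_correct(mk(0, 10, 5, 5), constant = 1)
  expect_equal(k$a, 1)
})

test_that("the Woolf log odds ratio and its variance are exact", {
  mk <- function(a, b, c, d)
    structure(list(study_id = "t", model = "allele", a = a, b = b, c = c,
                   d = d, corrected = FALSE), class = "contrast_table")
  null_t <- estimate_effect(mk(10, 10, 10, 10))
  expect_equal(null_t$log_or, 0)
  expect_equal(null_t$se, sqrt(0.4))

  e <- estimate_effect(mk(20, 10, 10, 20))
  expect_equal(e$log_or, log(4))
  expect_equal(e$se, sqrt(0.3))

  # swapping the case and control rows negates the log OR, keeps the se
  sw <- estimate_effect(mk(10, 20, 20, 10))
  expect_equal(sw$log_or, -e$log_or)
  expect_equal(sw$se, e$se)

  expect_error(estimate_effect(mk(0, 10, 5, 5)), "zero cell")
})

test_that("relabeling I <-> D reciprocates the allele odds ratio", {
  set.seed(21)
  for (i in 1:20) {
    g <- as.list(c(stats::rmultinom(1, 150, c(0.3, 0.4, 0.3)),
                   stats::rmultinom(1, 250, c(0.35, 0.45, 0.2))))
    names(g) <- c("n_case_II", "n_case_ID", "n_case_DD",
                  "n_ctrl_II", "n_ctrl_ID", "n_ctrl_DD")
    g$study_id <- "r"
    flipped <- g
    flipped[c("n_case_II", "n_case_DD")] <- g[c("n_case_DD", "n_case_II")]
    flipped[c("n_ctrl_II", "n_ctrl_DD")] <- g[c("n_ctrl_DD", "n_ctrl_II")]
    e1 <- estimate_effect(continuity_correct(build_contrast(g, "allele")))
    e2 <- estimate_effect(continuity_correct(build_contrast(flipped, "allele")))
    expect_equal(e1$log_or, -e2$log_or, tolerance = 1e-12)
    expect_equal(e1$se, e2$se, tolerance = 1e-12)
  }
})

test_that("dominant and heterozygous cells jointly recover the arm totals", {
  dom <- build_contrast(geno_rec, "dominant")
  het <- build_contrast(geno_rec, "heterozygous")
  n_case <- geno_rec$n_case_II + geno_rec$n_case_ID + geno_rec$n_case_DD
  n_ctrl <- geno_rec$n_ctrl_II + geno_rec$n_ctrl_ID + geno_rec$n_ctrl_DD
  expect_equal(dom$a + het$b, n_case)
  expect_equal(dom$c + het$d, n_ctrl)
})

test_that("increasing the exposed-case cell strictly increases the log OR", {
  mk <- function(a) structure(list(study_id = "t", model = "allele", a = a,
                                   b = 12, c = 9, d = 14, corrected = FALSE),
                              class = "contrast_table")
  lo <- vapply(1:30, function(a) estimate_effect(mk(a))$log_or, numeric(1))
  expect_true(all(diff(lo) > 0))
})

test_that("estimate_effects carries covariates and skips ineligible rows", {
  recs <- demo_records(k = 5, seed = 17)
  est <- estimate_effects(recs, "recessive")
  expect_s3_class(est, "effect_estimates")
  expect_equal(nrow(est), 5)
  expect_true(all(c("year", "ethnicity", "size", "followup_months",
                    "mean_age", "pct_male") %in% names(est)))
  expect_equal(est$size, recs$cases_total + recs$controls_total)

  # blank out one study's genotypes, leaving allele counts only
  recs2 <- recs
  recs2[2, c("n_case_II", "n_case_ID", "n_case_DD",
             "n_ctrl_II", "n_ctrl_ID", "n_ctrl_DD")] <- NA
  recs2 <- genassocmeta:::as_study_records(as.data.frame(recs2))
  est2 <- estimate_effects(recs2, "dominant")
  expect_equal(nrow(est2), 4)
  expect_equal(attr(est2, "skipped")$reason, "ineligible")
  est3 <- estimate_effects(recs2, "allele")
  expect_equal(nrow(est3), 5)
})
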