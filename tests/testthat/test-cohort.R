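test_that("cohort has the configured group sizes and schema", {
  coh <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(coh), 117)
  expect_equal(sum(coh$isr == 1), 52)
  expect_equal(sum(coh$isr == 0), 65)
  expect_true(all(c("id", "isr", "peri_stent_fai_hu", "degree_of_isr",
                    "vessel", "hdl_c", "apoa1", "hs_crp") %in% names(coh)))
  # degree present iff ISR
  expect_true(all(is.na(coh$degree_of_isr[coh$isr == 0])))
  expect_true(all(!is.na(coh$degree_of_isr[coh$isr == 1])))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 6))
  expect_false(identical(a$peri_stent_fai_hu, c2$peri_stent_fai_hu))
})

test_that("empirical moments converge to configured moments at large n", {
  coh <- generate_cohort(cohort_config(n_isr = 5000, n_nonisr = 5000,
                                       seed = 7))
  fai1 <- coh$peri_stent_fai_hu[coh$isr == 1]
  fai0 <- coh$peri_stent_fai_hu[coh$isr == 0]
  expect_lt(abs(mean(fai1) - (-78.1)), 3 * 6.2 / sqrt(5000))
  expect_lt(abs(mean(fai0) - (-87.2)), 3 * 7.3 / sqrt(5000))
  # binary covariate proportion (hypertension, ISR group: 28/52)
  p <- 28 / 52
  expect_lt(abs(mean(coh$hypertension[coh$isr == 1]) - p),
            3 * sqrt(p * (1 - p) / 5000))
  # degree-FAI correlation near target despite clipping
  r <- cor(coh$degree_of_isr[coh$isr == 1], fai1)
  expect_lt(abs(r - 0.579), 0.05)
})

test_that("non-ISR group FAI mean is recovered over replicates at n = 65", {
  means <- vapply(1:60, function(s) {
    coh <- generate_cohort(cohort_config(seed = 100 + s))
    mean(coh$peri_stent_fai_hu[coh$isr == 0])
  }, numeric(1))
  se <- 7.3 / sqrt(65 * 60)
  expect_lt(abs(mean(means) - (-87.2)), 3 * se)
})

test_that("zero configured correlation yields independent degree and FAI", {
  coh <- generate_cohort(cohort_config(n_isr = 5000, n_nonisr = 0,
                                       degree_fai_cor = 0, seed = 9))
  p <- pearson_with_ci(coh$degree_of_isr, coh$peri_stent_fai_hu)
  expect_gt(p$p_value, 0.01)
  expect_lt(abs(p$r), 0.05)
})

test_that("degrees are clipped to [0, 100] and config is validated", {
  coh <- generate_cohort(cohort_config(n_isr = 5000, n_nonisr = 0,
                                       degree = c(mean = 50.3, sd = 80),
                                       seed = 10))
  expect_true(all(coh$degree_of_isr >= 0 & coh$degree_of_isr <= 100))
  expect_true(any(coh$degree_of_isr == 0) && any(coh$degree_of_isr == 100))
  expect_error(cohort_config(n_isr = -1))
  expect_error(cohort_config(degree_fai_cor = 1.2))
})

test_that("per-vessel FAI overrides apply", {
  vf <- list(RCA = list(isr = c(-75.2, 5.4), nonisr = c(-90.9, 9.9)))
  coh <- generate_cohort(cohort_config(n_isr = 4000, n_nonisr = 4000,
                                       vessel_fai = vf, seed = 11))
  rca1 <- coh$peri_stent_fai_hu[coh$vessel == "RCA" & coh$isr == 1]
  expect_lt(abs(mean(rca1) - (-75.2)), 3 * 5.4 / sqrt(length(rca1)))
})
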