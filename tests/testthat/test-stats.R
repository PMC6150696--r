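make_emg_features <- function(rf_week1 = 1, seed = 1, n_subjects = 6,
                              strides = 30) {
  gains <- flat_gains(c("base", "week1"))
  gains <- gains[gains$muscle %in% c("RF", "VM"), ]
  gains$gain[gains$muscle == "RF" & gains$week == "week1"] <- rf_week1
  simulate_emg_features(gains, n_subjects = n_subjects,
                        strides_per_cell = strides, seed = seed)
}

test_that("Bonferroni adjustment multiplies and caps at one", {
  f <- make_emg_features(seed = 3)
  fit <- fit_emg_lmem(f)
  fe <- names(stridelab:::fixed_effects(fit$fit))
  L <- setNames(rep(0, length(fe)), fe)
  L["weekweek1"] <- 1
  ct <- posthoc_contrasts(fit, list(a = L, b = L, c = L), family_size = 3)
  expect_equal(ct$adj_p, pmin(1, 3 * ct$raw_p))
  big <- posthoc_contrasts(fit, list(a = L), family_size = 1e6)
  expect_equal(big$adj_p, 1)
  # monotone in family size
  small <- posthoc_contrasts(fit, list(a = L), family_size = 2)
  expect_gte(big$adj_p[1], small$adj_p[1])
})

test_that("a null contrast has estimate zero and p one", {
  f <- make_emg_features(seed = 3)
  fit <- fit_emg_lmem(f)
  fe <- names(stridelab:::fixed_effects(fit$fit))
  zero <- setNames(rep(0, length(fe)), fe)
  ct <- posthoc_contrasts(fit, list(self_minus_self = zero), family_size = 1)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$raw_p, 1)
})

test_that("contrasts naming absent coefficients raise a useful error", {
  f <- make_emg_features(seed = 3)
  fit <- fit_emg_lmem(f)
  expect_error(
    posthoc_contrasts(fit, list(bad = "weekweek9"), family_size = 1),
    "weekweek9"
  )
})

test_that("the EMG model recovers an injected log-ratio", {
  f <- make_emg_features(rf_week1 = 2, seed = 11, strides = 50)
  fit <- fit_emg_lmem(f)
  ct <- emg_contrasts(fit)
  est <- ct$estimate[ct$label == "RF_vs_VM_week1"]
  expect_equal(est, log(2), tolerance = 0.12)
  expect_lt(ct$adj_p[ct$label == "RF_vs_VM_week1"], 0.05)
  expect_equal(unique(ct$family_size), 3) # 2 muscles x 1 week + 1 difference
})

test_that("degenerate designs are rejected or collapsed sensibly", {
  f <- make_emg_features(seed = 5)
  single <- f[f$subject == "S01", ]
  expect_error(fit_emg_lmem(single), "two subjects")
  expect_error(fit_kinematic_lmem(f, "nonexistent"), "no rows")
  # all-ones response: log transform makes everything exactly zero
  ones <- f
  ones$value <- 1
  fit <- fit_emg_lmem(ones)
  expect_lt(max(abs(stridelab:::fixed_effects(fit$fit))), 1e-12)
})

test_that("kinematic mixed model recovers a week shift", {
  set.seed(8)
  rows <- tidyr::expand_grid(subject = sprintf("S%02d", 1:6),
                             week = c("base", "week1"), stride_id = 1:40)
  subj_int <- rnorm(6, 0, 2)
  rows$value <- 100 + subj_int[as.integer(factor(rows$subject))] +
    ifelse(rows$week == "week1", 10, 0) + rnorm(nrow(rows), 0, 3)
  rows$session <- paste0(rows$subject, "_", rows$week)
  rows$feature <- "hip_at_end_stance"
  fit <- fit_kinematic_lmem(rows, "hip_at_end_stance")
  ct <- week_contrasts(fit)
  expect_equal(ct$estimate[ct$label == "week1_vs_base"], 10, tolerance = 0.1)
  expect_lt(ct$adj_p[1], 0.001)
})

test_that("paired mass tests match the closed-form paired t statistic", {
  diffs <- c(0.1, 0.2, 0.3, 0.2, 0.2, 0.2)
  contra <- c(1.5, 1.6, 1.4, 1.5, 1.55, 1.5)
  masses <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:6), 2),
    muscle = "RF",
    side = rep(c("ipsi", "contra"), each = 6),
    mass_g = c(contra + diffs, contra)
  )
  ct <- paired_mass_tests(masses)
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(6))
  p_hand <- 2 * pt(-abs(t_hand), df = 5)
  expect_equal(ct$statistic, t_hand, tolerance = 1e-9)
  expect_equal(ct$raw_p, p_hand, tolerance = 1e-9)
  expect_equal(ct$estimate, 0.2)
  expect_equal(ct$adj_p, min(1, p_hand)) # family of one muscle
})

test_that("paired tests handle symmetric jitter and degenerate variance", {
  jit <- c(-1, 1, -1, 1) * 1e-9
  masses <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:4), 2), muscle = "VM",
    side = rep(c("ipsi", "contra"), each = 4),
    mass_g = c(1.3 + jit, rep(1.3, 4))
  )
  ct <- paired_mass_tests(masses)
  expect_equal(ct$estimate, 0, tolerance = 1e-12)
  flat <- masses
  flat$mass_g <- 1.3
  expect_error(paired_mass_tests(flat), "t undefined")
})

test_that("Bonferroni across muscles caps each adjusted mass p-value", {
  m <- simulate_mass_table(n_subjects = 6, seed = 10)
  ct <- paired_mass_tests(m)
  expect_equal(unique(ct$family_size), 4)
  expect_equal(ct$adj_p, pmin(1, 4 * ct$raw_p))
  expect_lt(ct$adj_p[ct$label == "VL_ipsi_vs_contra"], 0.001)
  expect_equal(ct$adj_p[ct$label == "VI_ipsi_vs_contra"], 1)
})

test_that("diagnostics expose residuals and random effects for inspection", {
  f <- make_emg_features(seed = 13, n_subjects = 6, strides = 45)
  fit <- fit_emg_lmem(f)
  d <- export_diagnostics(fit)
  expect_equal(nrow(d$residuals), stats::nobs(fit$fit))
  expect_true(all(c("group", "level", "term", "estimate") %in% names(d$ranef)))
  # Gaussian generative model: qq correlation close to 1 at n > 1000
  expect_gt(cor(sort(d$residuals$residual), sort(d$residuals$theoretical)), 0.99)
  expect_error(export_diagnostics(list()), "gait_lmem")
})
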