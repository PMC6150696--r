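#' Fit a linear mixed-effects model for a kinematic feature
#'
#' Models one stride-level feature against the adaptation time point with
#' `week` as a categorical fixed effect (baseline reference) and subject as
#' a random effect on both intercept and slope (the slope over numeric
#' weeks since baseline). Fitting is by REML via \pkg{lme4}, with
#' Satterthwaite degrees of freedom from \pkg{lmerTest} for the Wald
#' contrasts. Unbalanced cells and subjects missing whole weeks are
#' tolerated. A singular fit triggers a recorded fallback to a random
#' intercept only; failure after the fallback is an error.
#'
#' @param features Long feature tibble (`subject`, `week`, `session`,
#'   `stride_id`, `feature`, `value`).
#' @param feature Feature name to model (e.g. `"stance_pct"`).
#' @param transform `"none"` or `"log"` (natural log).
#' @param baseline_week Reference level for `week`.
#' @return An object of class `gait_lmem`: a list with the \pkg{lmerTest}
#'   fit, the model data, the random-effects structure used and whether it
#'   was downgraded.
#' @export
fit_kinematic_lmem <- function(features, feature, transform = c("none", "log"),
                               baseline_week = "base") {
  transform <- match.arg(transform)
  dat <- features |>
    filter(.data$feature == !!feature, !is.na(.data$value))
  if (nrow(dat) == 0) abort(sprintf("no rows for feature '%s'", feature))
  if (length(unique(dat$subject)) < 2) {
    abort("at least two subjects are required to identify subject random effects")
  }
  if (length(unique(dat$week)) < 2) {
    abort("at least two weeks are required to estimate week effects")
  }
  dat <- prepare_model_data(dat, transform, baseline_week)
  fit <- fit_with_fallback(
    dat,
    formulas = c(
      "y ~ week + (1 + week_numeric | subject)",
      "y ~ week + (1 | subject)"
    )
  )
  structure(
    list(fit = fit$model, data = dat, feature = feature,
         transform = transform, formula = fit$formula,
         downgraded = fit$downgraded, baseline_week = baseline_week),
    class = "gait_lmem"
  )
}

#' Fit the two-muscle EMG adaptation model
#'
#' Models log normalized integrated extension-burst activity of two muscles
#' jointly: fixed effects are week, muscle and their interaction; random
#' effects are a by-subject intercept and slope (numeric weeks) plus a
#' session-within-subject intercept that captures the nesting of strides
#' within each subject and recording session. The log transform symmetrizes
#' the skewed multiplicative EMG features. Singular fits fall back first to
#' dropping the subject slope, then the session level, each downgrade
#' recorded.
#'
#' @param features Long feature tibble containing `int_emg_<muscle>` rows.
#' @param muscles Two muscle names; the first is the reference level (the
#'   comparison muscle).
#' @param baseline_week Reference level for `week`.
#' @return An object of class `gait_emg_lmem` (inherits `gait_lmem`).
#' @export
fit_emg_lmem <- function(features, muscles = c("VM", "RF"),
                         baseline_week = "base") {
  if (length(muscles) != 2) abort("'muscles' must name exactly two muscles")
  dat <- features |>
    filter(.data$feature %in% paste0("int_emg_", muscles), !is.na(.data$value)) |>
    mutate(muscle = sub("^int_emg_", "", .data$feature))
  if (nrow(dat) == 0) abort("no normalized integrated-EMG rows for the requested muscles")
  missing_m <- setdiff(muscles, unique(dat$muscle))
  if (length(missing_m) > 0) {
    abort(sprintf("no rows for muscle(s): %s", paste(missing_m, collapse = ", ")))
  }
  if (length(unique(dat$subject)) < 2) {
    abort("at least two subjects are required to identify subject random effects")
  }
  if (any(dat$value <= 0)) abort("normalized integrated EMG must be positive to log-transform")
  dat <- prepare_model_data(dat, "log", baseline_week)
  dat$muscle <- factor(dat$muscle, levels = muscles)
  dat$session_id <- interaction(dat$subject, dat$session, drop = TRUE)
  fit <- fit_with_fallback(
    dat,
    formulas = c(
      "y ~ week * muscle + (1 + week_numeric | subject) + (1 | session_id)",
      "y ~ week * muscle + (1 | subject) + (1 | session_id)",
      "y ~ week * muscle + (1 | subject)"
    )
  )
  structure(
    list(fit = fit$model, data = dat, feature = paste0("int_emg_", muscles),
         muscles = muscles, transform = "log", formula = fit$formula,
         downgraded = fit$downgraded, baseline_week = baseline_week),
    class = c("gait_emg_lmem", "gait_lmem")
  )
}

prepare_model_data <- function(dat, transform, baseline_week) {
  if (!baseline_week %in% dat$week) {
    abort(sprintf("baseline week '%s' not present in the data", baseline_week))
  }
  wk_levels <- c(baseline_week, setdiff(unique(dat$week), baseline_week))
  ## keep chronological order of non-baseline weeks
  extra <- setdiff(wk_levels, baseline_week)
  extra <- extra[order(week_num(extra))]
  dat$week <- factor(dat$week, levels = c(baseline_week, extra))
  dat$week_numeric <- week_num(as.character(dat$week))
  dat$y <- if (transform == "log") log(dat$value) else dat$value
  dat
}

fixed_effects <- function(fit) {
  if (inherits(fit, "lm")) coef(fit) else lme4::fixef(fit)
}

fit_with_fallback <- function(dat, formulas) {
  ## degenerate case: a constant response carries no information for the
  ## variance components; fit the fixed part by least squares (all
  ## estimates 0 for an all-equal response after centering transforms)
  if (sd(dat$y) < 1e-12) {
    fixed_formula <- sub("\\s*\\+\\s*\\(.*$", "", formulas[length(formulas)])
    model <- stats::lm(as.formula(fixed_formula), data = dat)
    return(list(model = model, formula = fixed_formula, downgraded = TRUE))
  }
  last_err <- NULL
  for (k in seq_along(formulas)) {
    model <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(as.formula(formulas[k]), data = dat, REML = TRUE)
      )),
      error = function(e) e
    )
    if (inherits(model, "error")) {
      last_err <- model
      next
    }
    ## a singular or non-converged fit triggers the next, simpler structure
    conv_msgs <- model@optinfo$conv$lme4$messages
    healthy <- !lme4::isSingular(model, tol = 1e-4) &&
      (is.null(conv_msgs) || !any(grepl("failed to converge", conv_msgs)))
    if (healthy) {
      return(list(model = model, formula = formulas[k], downgraded = k > 1))
    }
    if (k == length(formulas)) {
      if (!is.null(conv_msgs) && any(grepl("failed to converge", conv_msgs))) {
        abort(paste0("mixed model did not converge even with the simplest ",
                     "random-effects structure: ",
                     paste(conv_msgs, collapse = "; ")))
      }
      ## simplest structure merely singular: keep it but flag the downgrade
      return(list(model = model, formula = formulas[k], downgraded = TRUE))
    }
  }
  abort(paste0("mixed-model fitting failed: ",
               conditionMessage(last_err %||% simpleError("no structure converged"))))
}

#' Wald post-hoc contrasts with Bonferroni correction
#'
#' Tests linear combinations of the fixed effects of a fitted model with
#' Wald t statistics on Satterthwaite degrees of freedom, multiplying each
#' raw p-value by the family size and capping at 1 (Bonferroni; corrected
#' p-values of exactly 1 are therefore common).
#'
#' @param fit A `gait_lmem` or `gait_emg_lmem` object.
#' @param contrasts Named list of numeric contrast vectors over the fixed
#'   effects (in `lme4::fixef()` order; shorter vectors are zero-padded).
#' @param family_size Bonferroni family size; defaults to the number of
#'   contrasts.
#' @return A `gait_contrasts` tibble: `label`, `estimate`, `se`, `df`,
#'   `statistic`, `raw_p`, `adj_p`, `family_size`.
#' @export
posthoc_contrasts <- function(fit, contrasts, family_size = length(contrasts)) {
  stopifnot(inherits(fit, "gait_lmem"))
  fe <- fixed_effects(fit$fit)
  rows <- purrr::imap(contrasts, function(L, label) {
    if (is.character(L)) {
      if (!all(L %in% names(fe))) {
        abort(sprintf("contrast '%s' names coefficient(s) absent from the fit: %s",
                      label, paste(setdiff(L, names(fe)), collapse = ", ")))
      }
      v <- setNames(rep(0, length(fe)), names(fe))
      v[L] <- 1
      L <- v
    }
    if (length(L) < length(fe)) L <- c(L, rep(0, length(fe) - length(L)))
    if (length(L) != length(fe)) {
      abort(sprintf("contrast '%s' has length %d but the model has %d coefficients",
                    label, length(L), length(fe)))
    }
    if (all(L == 0)) {
      return(tibble(label = label, estimate = 0, se = NA_real_, df = NA_real_,
                    statistic = 0, raw_p = 1))
    }
    if (inherits(fit$fit, "lm")) {
      est <- sum(L * fe)
      se <- sqrt(drop(t(L) %*% stats::vcov(fit$fit) %*% L))
      df <- stats::df.residual(fit$fit)
      stat <- if (se > 0) est / se else NA_real_
      p <- if (is.finite(stat)) 2 * pt(-abs(stat), df) else NA_real_
      return(tibble(label = label, estimate = est, se = se, df = df,
                    statistic = stat, raw_p = p))
    }
    ct <- lmerTest::contest1D(fit$fit, unname(L), ddf = "Satterthwaite")
    tibble(label = label, estimate = ct[["Estimate"]], se = ct[["Std. Error"]],
           df = ct[["df"]], statistic = ct[["t value"]],
           raw_p = ct[["Pr(>|t|)"]])
  })
  out <- bind_rows(rows) |>
    mutate(adj_p = pmin(1, .data$raw_p * family_size),
           family_size = family_size)
  class(out) <- c("gait_contrasts", class(out))
  out
}

#' Week-versus-baseline contrasts for a kinematic model
#'
#' Builds the per-feature family of contrasts comparing each post-baseline
#' week to baseline and corrects within that family.
#'
#' @param fit A `gait_lmem` from [fit_kinematic_lmem()].
#' @return A `gait_contrasts` tibble (family size = number of post-baseline
#'   weeks).
#' @export
week_contrasts <- function(fit) {
  fe <- names(fixed_effects(fit$fit))
  weeks <- levels(fit$data$week)[-1]
  contrasts <- lapply(weeks, function(w) paste0("week", w))
  names(contrasts) <- paste0(weeks, "_vs_", fit$baseline_week)
  bad <- !vapply(contrasts, function(nm) nm %in% fe, logical(1))
  if (any(bad)) {
    abort(sprintf("missing coefficient(s) for week(s): %s",
                  paste(weeks[bad], collapse = ", ")))
  }
  posthoc_contrasts(fit, contrasts, family_size = length(contrasts))
}

#' Post-hoc contrast family for the two-muscle EMG model
#'
#' The family tested on the EMG adaptation model: each muscle at each
#' post-baseline week versus its own baseline, plus the second muscle
#' versus the first at each post-baseline week, all Bonferroni-corrected
#' within the single pooled family. Estimates are on the log scale
#' (log-ratios of normalized activity).
#'
#' @param fit A `gait_emg_lmem` from [fit_emg_lmem()].
#' @return A `gait_contrasts` tibble with labels
#'   `<muscle>_<week>_vs_<baseline>` and `<m2>_vs_<m1>_<week>`.
#' @export
emg_contrasts <- function(fit) {
  fe <- names(fixed_effects(fit$fit))
  weeks <- levels(fit$data$week)[-1]
  m1 <- fit$muscles[1]; m2 <- fit$muscles[2]
  zero <- setNames(rep(0, length(fe)), fe)
  contrasts <- list()
  for (w in weeks) {
    wc <- paste0("week", w)
    wi <- paste0("week", w, ":muscle", m2)
    ## reference muscle at week w vs baseline
    L <- zero; L[wc] <- 1
    contrasts[[paste0(m1, "_", w, "_vs_", fit$baseline_week)]] <- L
    ## second muscle at week w vs baseline
    L <- zero; L[wc] <- 1
    if (wi %in% fe) L[wi] <- 1
    contrasts[[paste0(m2, "_", w, "_vs_", fit$baseline_week)]] <- L
    ## muscle difference at week w
    L <- zero; L[paste0("muscle", m2)] <- 1
    if (wi %in% fe) L[wi] <- 1
    contrasts[[paste0(m2, "_vs_", m1, "_", w)]] <- L
  }
  posthoc_contrasts(fit, contrasts, family_size = length(contrasts))
}

#' Paired t-tests for muscle masses
#'
#' Two-sided paired t-tests of ipsilateral versus contralateral mass for
#' each muscle, Bonferroni-corrected across the muscles tested. Estimates
#' are mean ipsi - contra differences in grams.
#'
#' @param masses Mass tibble (`subject`, `muscle`, `side` in
#'   `{ipsi, contra}`, `mass_g`).
#' @return A `gait_contrasts` tibble, one row per muscle.
#' @export
paired_mass_tests <- function(masses) {
  wide <- masses |>
    tidyr::pivot_wider(id_cols = c("subject", "muscle"),
                       names_from = "side", values_from = "mass_g") |>
    filter(!is.na(.data$ipsi), !is.na(.data$contra))
  muscles <- unique(wide$muscle)
  fam <- length(muscles)
  rows <- lapply(muscles, function(m) {
    d <- wide |> filter(.data$muscle == m)
    if (nrow(d) < 2) {
      abort(sprintf("muscle '%s' has fewer than 2 complete ipsi/contra pairs", m))
    }
    diffs <- d$ipsi - d$contra
    if (sd(diffs) == 0) {
      abort(sprintf("zero variance of ipsi-contra differences for '%s': t undefined", m))
    }
    tt <- t.test(d$ipsi, d$contra, paired = TRUE)
    tibble(label = paste0(m, "_ipsi_vs_contra"),
           estimate = unname(tt$estimate), se = unname(tt$stderr),
           df = unname(tt$parameter), statistic = unname(tt$statistic),
           raw_p = tt$p.value)
  })
  out <- bind_rows(rows) |>
    mutate(adj_p = pmin(1, .data$raw_p * fam), family_size = fam)
  class(out) <- c("gait_contrasts", class(out))
  out
}

#' Export residual and random-effect diagnostics
#'
#' Collects what is needed to inspect the model assumptions (Gaussian
#' residuals and random effects): per-observation residuals paired with
#' theoretical normal quantiles for qq-plots, and the estimated random
#' effects per grouping level.
#'
#' @param fit A `gait_lmem` or `gait_emg_lmem`.
#' @return An object of class `gait_diagnostics`: list of tibbles
#'   `residuals` (`fitted`, `residual`, `theoretical`) and `ranef`
#'   (`group`, `level`, `term`, `estimate`).
#' @export
export_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gait_lmem"))
  r <- unname(resid(fit$fit))
  if (length(r) == 0) abort("model has no observations")
  ord <- order(r)
  theo <- numeric(length(r))
  theo[ord] <- qnorm(ppoints(length(r))) * sd(r) + mean(r)
  res <- tibble(fitted = unname(fitted(fit$fit)), residual = r, theoretical = theo)
  re <- if (inherits(fit$fit, "lm")) list() else lme4::ranef(fit$fit)
  ranef_tbl <- purrr::imap(re, function(df, gname) {
    df2 <- as_tibble(df, rownames = "level")
    tidyr::pivot_longer(df2, -"level", names_to = "term", values_to = "estimate") |>
      mutate(group = gname, .before = 1)
  }) |>
    bind_rows()
  if (nrow(ranef_tbl) == 0) {
    ranef_tbl <- tibble(group = character(0), level = character(0),
                        term = character(0), estimate = numeric(0))
  }
  structure(list(residuals = res, ranef = ranef_tbl),
            class = "gait_diagnostics")
}

#' @export
print.gait_diagnostics <- function(x, ...) {
  cat(sprintf("<gait_diagnostics> %d residuals, %d random-effect estimates\n",
              nrow(x$residuals), nrow(x$ranef)))
  invisible(x)
}

#' @export
print.gait_lmem <- function(x, ...) {
  cat(sprintf("<%s> %s | %s\n", class(x)[1],
              paste(x$feature, collapse = "+"), x$formula))
  if (x$downgraded) cat("  (random-effects structure downgraded after singular fit)\n")
  print(summary(x$fit)$coefficients)
  invisible(x)
}
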