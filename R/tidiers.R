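#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted gait mixed model
#'
#' Returns the fixed effects of a `gait_lmem` / `gait_emg_lmem` fit as one
#' row per term with Satterthwaite-based Wald statistics, in the broom
#' column convention.
#'
#' @param x A `gait_lmem` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`.
#' @export
tidy.gait_lmem <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  if (inherits(x$fit, "lm")) {
    return(tibble(
      term = rownames(co), estimate = co[, "Estimate"],
      std.error = co[, "Std. Error"], df = stats::df.residual(x$fit),
      statistic = co[, "t value"], p.value = co[, "Pr(>|t|)"]
    ))
  }
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    df = co[, "df"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' Glance at a fitted gait mixed model
#'
#' One-row model summary: observation and group counts, residual SD,
#' log-likelihood, and whether the random-effects structure was downgraded
#' after a singular fit.
#'
#' @param x A `gait_lmem` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.gait_lmem <- function(x, ...) {
  if (inherits(x$fit, "lm")) {
    return(tibble(
      nobs = stats::nobs(x$fit),
      n_subjects = length(unique(x$data$subject)),
      sigma = summary(x$fit)$sigma,
      logLik = as.numeric(stats::logLik(x$fit)),
      REML = NA_real_, singular = NA, downgraded = x$downgraded,
      formula = x$formula
    ))
  }
  s <- summary(x$fit)
  tibble(
    nobs = stats::nobs(x$fit),
    n_subjects = length(unique(x$data$subject)),
    sigma = s$sigma,
    logLik = as.numeric(stats::logLik(x$fit)),
    REML = as.numeric(s$AICtab["REML"]),
    singular = lme4::isSingular(x$fit, tol = 1e-4),
    downgraded = x$downgraded,
    formula = x$formula
  )
}

#' Tidy a contrast table
#'
#' Renames a `gait_contrasts` table into broom columns (`term`,
#' `estimate`, `std.error`, `statistic`, `p.value`, `adj.p.value`).
#'
#' @param x A `gait_contrasts` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gait_contrasts <- function(x, ...) {
  tibble(
    term = x$label,
    estimate = x$estimate,
    std.error = x$se,
    df = x$df,
    statistic = x$statistic,
    p.value = x$raw_p,
    adj.p.value = x$adj_p
  )
}
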