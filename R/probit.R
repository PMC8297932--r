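#' Probit dose-response fit with LC50 and Fieller fiducial limits
#'
#' Fits mortality ~ probit(log10 dose) by maximum likelihood (Fisher-scoring
#' IRLS via [stats::glm()], convergence 1e-8, up to 100 iterations) after
#' Abbott's correction for control mortality. The LC50 is `10^(-a/b)` for
#' intercept `a` and slope `b`; its 95% limits come from Fieller's theorem on
#' `-a/b`. When the Pearson heterogeneity factor (chi-square / df over the
#' positive doses) exceeds 1, the variance is inflated by it and Student-t
#' quantiles on the residual df replace normal quantiles.
#'
#' @param records Data frame with columns `dose` (same units throughout,
#'   e.g. ug/cm2; a `dose == 0` row, if present, is the control), `n`
#'   (treated) and `dead`. At least 3 distinct positive doses are required.
#' @return Object of class `probit_fit`: `slope`, `slope_se`, `intercept`,
#'   `lc50`, `fl95` (length-2), `heterogeneity` (chi-square/df), `chisq`,
#'   `df`, `n_doses`, `control_mortality`.
#' @export
probit_fit <- function(records) {
  stopifnot(all(c("dose", "n", "dead") %in% names(records)))
  stopifnot(all(records$n > 0), all(records$dead >= 0), all(records$dead <= records$n))
  ctl <- records[records$dose == 0, , drop = FALSE]
  trt <- records[records$dose > 0, , drop = FALSE]
  if (length(unique(trt$dose)) < 3) stop("need >= 3 distinct positive doses")
  c0 <- if (nrow(ctl) > 0) sum(ctl$dead) / sum(ctl$n) else 0
  if (c0 >= 1) stop("complete control mortality; no response information")
  p_obs <- trt$dead / trt$n
  p_corr <- pmin(pmax((p_obs - c0) / (1 - c0), 0), 1)
  if (all(p_corr %in% c(0, 1))) {
    stop("all corrected mortalities are 0 or 1; probit MLE does not exist")
  }
  x <- log10(trt$dose)
  fit <- suppressWarnings(stats::glm(
    p_corr ~ x, family = stats::binomial(link = "probit"), weights = trt$n,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0) stop("non-positive or non-finite slope; fit failed")
  vc <- stats::vcov(fit)
  p_hat <- stats::pnorm(a + b * x)
  k <- length(x)
  df <- k - 2L
  chisq <- sum(trt$n * (p_corr - p_hat)^2 / (p_hat * (1 - p_hat)))
  h <- if (df > 0) chisq / df else NA_real_
  inflate <- !is.na(h) && h > 1
  if (inflate) vc <- vc * h
  tq <- if (inflate) stats::qt(0.975, df) else stats::qnorm(0.975)

  m <- -a / b
  v11 <- vc[1, 1]; v12 <- vc[1, 2]; v22 <- vc[2, 2]
  g <- tq^2 * v22 / b^2
  fl <- c(NA_real_, NA_real_)
  if (g < 1) {
    disc <- v11 + 2 * m * v12 + m^2 * v22 - g * (v11 - v12^2 / v22)
    half <- (tq / b) * sqrt(disc)
    centre <- m + g * v12 / v22
    fl <- sort(10^((centre + c(-1, 1) * half) / (1 - g)))
  } else {
    warning("g >= 1 in Fieller's theorem; fiducial limits are unbounded")
  }
  structure(list(
    slope = b, slope_se = sqrt(vc[2, 2]), intercept = a,
    lc50 = 10^m, fl95 = fl, heterogeneity = h, chisq = chisq, df = df,
    n_doses = k, control_mortality = c0
  ), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit on %d doses\n", x$n_doses))
  cat(sprintf("  slope     %.2f +/- %.2f\n", x$slope, x$slope_se))
  cat(sprintf("  LC50      %.4g  (95%% FL %.4g - %.4g)\n", x$lc50, x$fl95[1], x$fl95[2]))
  cat(sprintf("  chi-square/df %.2f on %d df\n", x$heterogeneity, x$df))
  invisible(x)
}

#' Simulate a dose-mortality experiment from probit parameters
#'
#' @param slope Probit slope on log10 dose.
#' @param lc50 True LC50 (dose units).
#' @param doses Positive dose series (default: 6 doses in a geometric series
#'   centred on the LC50, the usual bioassay layout).
#' @param n_per_dose Larvae per dose (default 24).
#' @param control_mortality Background mortality applied to all wells.
#' @param include_control Add a dose-0 control row of `n_per_dose` larvae.
#' @return Data frame of `dose`, `n`, `dead`.
#' @export
simulate_dose_response <- function(slope, lc50, doses = NULL, n_per_dose = 24,
                                   control_mortality = 0, include_control = TRUE) {
  if (is.null(doses)) doses <- lc50 * 10^seq(-1, 1, length.out = 6)
  p <- stats::pnorm(slope * (log10(doses) - log10(lc50)))
  p <- control_mortality + (1 - control_mortality) * p
  out <- data.frame(dose = doses, n = n_per_dose,
                    dead = stats::rbinom(length(doses), n_per_dose, p))
  if (include_control) {
    out <- rbind(data.frame(dose = 0, n = n_per_dose,
                            dead = stats::rbinom(1, n_per_dose, control_mortality)),
                 out)
  }
  out
}

#' Resistance ratio at the published printing convention
#'
#' RR = LC50(test) / LC50(reference). Values of 10 and above are printed to
#' the nearest integer, smaller values to one decimal.
#'
#' @param lc50_test,lc50_ref Positive LC50s in the same units.
#' @param rounded Apply the printing convention (default `TRUE`); `FALSE`
#'   returns the exact quotient.
#' @return The resistance ratio.
#' @export
resistance_ratio <- function(lc50_test, lc50_ref, rounded = TRUE) {
  if (any(lc50_test <= 0) || any(lc50_ref <= 0)) stop("LC50s must be positive")
  q <- lc50_test / lc50_ref
  if (!rounded) return(q)
  ifelse(q >= 10, round(q), round(q, 1))
}

#' Significance by non-overlap of 95% fiducial limits
#'
#' Two LC50s are considered significantly different when their 95% fiducial
#' intervals do not overlap.
#'
#' @param a,b `probit_fit` objects or numeric length-2 intervals
#'   `(lower, upper)`.
#' @return `TRUE` iff the intervals are disjoint.
#' @export
fiducial_overlap_significant <- function(a, b) {
  iv <- function(x) if (inherits(x, "probit_fit")) x$fl95 else sort(as.numeric(x))
  ia <- iv(a); ib <- iv(b)
  stopifnot(length(ia) == 2, length(ib) == 2, !anyNA(ia), !anyNA(ib))
  ia[2] < ib[1] || ib[2] < ia[1]
}
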