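#' Kaplan-Meier curves and log-rank test
#'
#' Estimates per-group Kaplan-Meier survival curves and tests their equality
#' with the log-rank test (two-sided chi-square p-value).
#'
#' @param data Tibble of one row per patient.
#' @param time,event,group Column names of the follow-up time (months), the
#'   event indicator (logical or 0/1) and the grouping variable.
#' @return Object of class `km_logrank` carrying the `survival::survfit` and
#'   `survival::survdiff` fits; see [tidy.km_logrank()], [glance.km_logrank()]
#'   and [autoplot.km_logrank()].
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' km <- km_logrank(coh$patients, group = "group_true")
#' glance(km)
#' @export
km_logrank <- function(data, time = "rfs_months", event = "event",
                       group = "group") {
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups.")
  if (any(table(g) == 0)) abort("every group must contain at least one subject.")
  srv <- survival::Surv(data[[time]], as.integer(data[[event]]))
  df <- data.frame(srv = srv, g = g)
  fit <- survival::survfit(srv ~ g, data = df)
  if (sum(as.integer(data[[event]])) == 0L) {
    # no events anywhere: curve comparison is undefined
    diff <- NULL; chisq <- NA_real_; p <- NA_real_
  } else {
    diff <- survival::survdiff(srv ~ g, data = df)
    chisq <- unname(diff$chisq)
    p <- stats::pchisq(chisq, df = nlevels(g) - 1L, lower.tail = FALSE)
  }
  structure(list(fit = fit, diff = diff, chisq = chisq,
                 df = nlevels(g) - 1L, p.value = p, group = group),
            class = "km_logrank")
}

#' @describeIn km_logrank Step-function coordinates of the KM curves.
#' @param x A `km_logrank` object.
#' @param ... Unused.
#' @export
tidy.km_logrank <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep("all", length(s$time))
    else sub("^g=", "", as.character(s$strata))
  tibble(group = strata, time = s$time, n.risk = s$n.risk,
         n.event = s$n.event, n.censor = s$n.censor, estimate = s$surv,
         std.error = s$std.err)
}

#' @describeIn km_logrank Log-rank statistic and p-value.
#' @export
glance.km_logrank <- function(x, ...) {
  tibble(statistic = x$chisq, df = x$df, p.value = x$p.value)
}

#' @describeIn km_logrank Kaplan-Meier plot with censoring marks.
#' @param object A `km_logrank` object.
#' @export
autoplot.km_logrank <- function(object, ...) {
  d <- tidy(object)
  start <- d |> distinct(.data$group) |>
    mutate(time = 0, estimate = 1, n.censor = 0)
  d2 <- bind_rows(start, d) |> arrange(.data$group, .data$time)
  ggplot2::ggplot(d2, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(d, .data$n.censor > 0), shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "relapse-free survival",
                  subtitle = sprintf("log-rank p = %.3g", object$p.value))
}

#' Cox proportional-hazards fit on dichotomized covariates
#'
#' Fits a Cox model (Efron tie handling) of the survival outcome on a set of
#' binary covariates and reports hazard ratios with Wald 95% confidence
#' intervals on the log-hazard scale and two-sided p-values. Mirrors the
#' multivariable model used for dichotomized clinical factors plus the two
#' microenvironment biomarkers (Immunoscore class and MMP14+ CAF/CAF ratio
#' class).
#'
#' @param data One row per patient.
#' @param terms Character vector of covariate column names (logical, 0/1 or
#'   two-level factors).
#' @param time,event Column names of follow-up time and event indicator.
#' @param ties Tie handling in the partial likelihood: `"efron"` (default,
#'   less biased with many ties) or `"breslow"`.
#' @return Object of class `cox_fit` wrapping the `survival::coxph` fit; use
#'   [tidy.cox_fit()] / [glance.cox_fit()].
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' fit <- cox_fit(coh$patients, c("true_ratio_high", "true_is_high"))
#' tidy(fit)
#' @export
cox_fit <- function(data, terms, time = "rfs_months", event = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  missing <- setdiff(terms, names(data))
  if (length(missing) > 0) {
    abort(paste0("term(s) not in data: ", paste(missing, collapse = ", ")))
  }
  novar <- terms[map_dbl(terms, function(t) dplyr::n_distinct(data[[t]], na.rm = TRUE)) < 2]
  if (length(novar) > 0) {
    abort(paste0("zero-variance term(s): ", paste(novar, collapse = ", ")))
  }
  nev <- sum(as.integer(data[[event]]))
  if (nev < length(terms)) {
    warn(sprintf("only %d events for %d terms; estimates may be unstable.",
                 nev, length(terms)))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", as.integer(", event, ")) ~ ",
    paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    abort("Cox fit failed to converge or produced undefined coefficients.")
  }
  structure(list(fit = fit, terms = terms), class = "cox_fit")
}

#' @describeIn cox_fit Hazard ratios, Wald 95% CIs and p-values per term.
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(term = rownames(co),
         estimate = unname(co[, "exp(coef)"]),
         conf.low = unname(exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"])),
         conf.high = unname(exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"])),
         p.value = unname(co[, "Pr(>|z|)"]))
}

#' @describeIn cox_fit Model-level summary (n, events, concordance).
#' @export
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = s$n, n.event = s$nevent,
         concordance = unname(s$concordance["C"]),
         logLik = as.numeric(stats::logLik(x$fit)))
}

#' Contrast of risk group C against the other three groups
#'
#' Fits a univariable Cox model of an indicator for group C (low Immunoscore,
#' high MMP14+ CAF/CAF ratio) against groups A, B and D combined, and also
#' computes the four-group Kaplan-Meier curves with the log-rank test.
#'
#' @param data One row per patient with a group column of `"A"`-`"D"`.
#' @param group,time,event Column names.
#' @return List of class `group_c_contrast` with `cox` (a [cox_fit()] result
#'   for the C indicator) and `km` (a [km_logrank()] over the four groups);
#'   `tidy()` returns the contrast's HR row.
#' @export
group_c_contrast <- function(data, group = "group", time = "rfs_months",
                             event = "event") {
  g <- data[[group]]
  if (!any(g == "C", na.rm = TRUE)) abort("group C is empty.")
  data$.is_group_c <- g == "C"
  cox <- cox_fit(data, ".is_group_c", time = time, event = event)
  km <- km_logrank(data, time = time, event = event, group = group)
  structure(list(cox = cox, km = km), class = "group_c_contrast")
}

#' @describeIn group_c_contrast Hazard ratio of group C vs the rest.
#' @param x A `group_c_contrast` object.
#' @param ... Unused.
#' @export
tidy.group_c_contrast <- function(x, ...) {
  tidy(x$cox) |> mutate(term = "group C vs A+B+D")
}
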