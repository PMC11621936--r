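#' Median split of a marker
#'
#' Dichotomises a continuous marker at its median: positive iff strictly
#' above the median, so values equal to the median fall in the negative
#' group.
#'
#' @param values finite numeric vector, length >= 2.
#' @return logical vector (`TRUE` = positive/high).
#' @export
median_split <- function(values) {
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("need >= 2 finite values", call. = FALSE)
  }
  if (all(values == values[1])) {
    warning("all values equal; everyone labelled negative", call. = FALSE)
  }
  values > median(values)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood standard errors, wrapping
#' [survival::survfit()].
#'
#' @param time follow-up times (e.g. months).
#' @param event 1 = event (death/relapse), 0 = censored.
#' @return a `km_curve`: data frame (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err`, `lower`, `upper`).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log")
  structure(data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv, std_err = fit$std.err,
    lower = fit$lower, upper = fit$upper
  ), class = c("km_curve", "data.frame"))
}

#' Read the survival probability at a time point
#'
#' Evaluates the Kaplan-Meier step function at `t` (right-continuous):
#' e.g. `survival_at(km, 60)` is the 5-year survival rate for times in
#' months.
#'
#' @param km a `km_curve` from [km_estimate()].
#' @param t time at which to read the curve.
#' @return survival probability in \[0, 1\].
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"), t >= 0)
  idx <- which(km$time <= t)
  if (length(idx) == 0L) return(1)
  km$surv[max(idx)]
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic with 1 degree of freedom,
#' wrapping [survival::survdiff()].
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level group vector.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (length(unique(group)) != 2L) {
    stop("log-rank test needs exactly two groups", call. = FALSE)
  }
  if (sum(event) == 0) stop("no events observed", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = data.frame(time, event, group))
  list(chi2 = fit$chisq, p = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratio
#'
#' Univariable Cox partial-likelihood fit with Efron handling of tied
#' event times (tabulated months make ties common), returning the hazard
#' ratio with Wald 95% confidence interval and p value. For a binary or
#' two-level covariate the HR indexes the second level (or `TRUE`)
#' against the first. Monotone likelihood (complete separation) is
#' flagged and the interval reported as unbounded.
#'
#' @param time,event follow-up times and event indicators.
#' @param covariate binary (logical/two-level) or continuous covariate.
#' @return a `hazard_estimate`: list with `hr`, `ci95`, `p`, `n`,
#'   `n_events`, `flagged`.
#' @export
cox_hr <- function(time, event, covariate) {
  stopifnot(length(time) == length(event),
            length(time) == length(covariate))
  x <- covariate
  if (is.character(x) || is.factor(x)) {
    x <- factor(x)
    if (nlevels(x) != 2L) stop("factor covariate must have 2 levels",
                               call. = FALSE)
  }
  df <- data.frame(time = time, event = event, x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         ties = "efron")
  s <- summary(fit)
  coef <- s$coefficients[1, "coef"]
  se <- s$coefficients[1, "se(coef)"]
  flagged <- !is.finite(coef) || !is.finite(se) || abs(coef) > 15 || se > 100
  ci <- if (flagged) c(0, Inf) else exp(coef + c(-1, 1) * 1.959964 * se)
  structure(list(
    hr = exp(coef), ci95 = ci,
    p = s$coefficients[1, "Pr(>|z|)"],
    n = nrow(df), n_events = sum(event), flagged = flagged
  ), class = "hazard_estimate")
}

#' Per-stratum hazard ratio of a treatment arm
#'
#' Fits an unadjusted Cox model of the treatment arm within each level
#' of a stratifying marker (e.g. TLC or PD-L1 status), producing a
#' forest-style table. Empty strata, or strata without both arms or any
#' event, are omitted with a warning.
#'
#' @param records data frame of cohort records.
#' @param stratifier column name of the stratifying marker.
#' @param arm column name of the treatment arm; `arm_levels` optionally
#'   fixes the order (control first).
#' @param time_col,event_col column names of follow-up time and event.
#' @param arm_levels optional length-2 vector ordering the arm levels.
#' @return data frame (stratum, n, n_events, hr, lo, hi, p).
#' @export
subgroup_analysis <- function(records, stratifier, arm,
                              time_col = "time_months",
                              event_col = "event", arm_levels = NULL) {
  stopifnot(all(c(stratifier, arm, time_col, event_col) %in%
                  names(records)))
  if (is.null(arm_levels)) arm_levels <- unique(records[[arm]])
  out <- lapply(unique(records[[stratifier]]), function(st) {
    d <- records[records[[stratifier]] == st, , drop = FALSE]
    if (nrow(d) == 0L || length(unique(d[[arm]])) < 2L ||
        sum(d[[event_col]]) == 0) {
      warning("stratum `", st, "` omitted (empty, single-arm or ",
              "event-free)", call. = FALSE)
      return(NULL)
    }
    est <- cox_hr(d[[time_col]], d[[event_col]],
                  factor(d[[arm]], levels = arm_levels))
    data.frame(stratum = st, n = est$n, n_events = est$n_events,
               hr = est$hr, lo = est$ci95[1], hi = est$ci95[2],
               p = est$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no stratum could be analysed", call. = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-gene hazard screen by median split
#'
#' For every gene (column) of an expression matrix: dichotomise patients
#' at the median expression and estimate the Cox hazard ratio of
#' high-versus-low expression. Constant genes are skipped with a
#' warning. Output is sorted by HR ascending, so protective genes (HR <
#' 1 for high expression) rank first.
#'
#' @param expr numeric matrix, rows = patients, columns = genes.
#' @param time,event follow-up times and event indicators aligned to the
#'   rows.
#' @return data frame (gene, hr, lo, hi, p, n_high).
#' @export
hazard_screen <- function(expr, time, event) {
  stopifnot(is.matrix(expr), nrow(expr) == length(time))
  out <- lapply(colnames(expr), function(g) {
    v <- expr[, g]
    if (all(v == v[1])) {
      warning("gene `", g, "` is constant; skipped", call. = FALSE)
      return(NULL)
    }
    high <- median_split(v)
    est <- cox_hr(time, event, high)
    data.frame(gene = g, hr = est$hr, lo = est$ci95[1], hi = est$ci95[2],
               p = est$p, n_high = sum(high), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no usable gene", call. = FALSE)
  res <- res[order(res$hr), ]
  rownames(res) <- NULL
  res
}
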