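#' Estimate GI50 from a viability profile
#'
#' Finds the 50% growth-inhibitory concentration as the first downward
#' crossing of 50% viability, by linear interpolation in log10 dose
#' between the bracketing doses. A dose whose measured viability is
#' exactly 50 is returned as-is. Profiles that never reach 50% are
#' right-censored at the maximum dose; profiles already below 50% at the
#' lowest dose are left-censored at the minimum dose.
#'
#' @param doses strictly increasing positive concentrations (>= 3).
#' @param viability_pct viability in percent of untreated control.
#' @return list with `gi50` and `censored` (`"none"`, `"right"` or
#'   `"left"`).
#' @examples
#' compute_gi50(c(0.1, 1), c(100, 40))$gi50  # ~0.681
#' @export
compute_gi50 <- function(doses, viability_pct) {
  if (length(doses) < 2L || length(doses) != length(viability_pct)) {
    stop("need >= 2 paired doses and viabilities", call. = FALSE)
  }
  if (any(doses <= 0) || any(diff(doses) <= 0)) {
    stop("`doses` must be positive and strictly increasing", call. = FALSE)
  }
  v <- as.double(viability_pct)
  for (i in seq_along(doses)) {
    if (v[i] == 50) return(list(gi50 = doses[i], censored = "none"))
    if (i > 1L && v[i - 1L] > 50 && v[i] < 50) {
      lx <- log10(doses[i - 1L]) +
        (v[i - 1L] - 50) / (v[i - 1L] - v[i]) *
          (log10(doses[i]) - log10(doses[i - 1L]))
      return(list(gi50 = 10^lx, censored = "none"))
    }
  }
  if (v[1L] < 50) return(list(gi50 = min(doses), censored = "left"))
  list(gi50 = max(doses), censored = "right")
}

#' Normalised area under the dose-response curve
#'
#' Trapezoidal integral of the viability fraction over log10 dose,
#' divided by the log-dose span, so the result lies in \[0, 1\] for
#' viabilities in \[0, 100\]; lower AUC means greater sensitivity.
#'
#' @inheritParams compute_gi50
#' @return scalar AUC.
#' @export
compute_auc <- function(doses, viability_pct) {
  if (length(doses) < 2L) stop("AUC needs >= 2 doses", call. = FALSE)
  if (length(doses) != length(viability_pct)) {
    stop("doses and viabilities must be paired", call. = FALSE)
  }
  if (any(doses <= 0) || any(diff(doses) <= 0)) {
    stop("`doses` must be positive and strictly increasing", call. = FALSE)
  }
  x <- log10(doses)
  y <- viability_pct / 100
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  auc / (max(x) - min(x))
}

#' Segregate cell lines into sensitive and resistant by GI50
#'
#' Sorts log10 GI50 ascending and splits at the largest adjacent gap;
#' lines below the gap are labelled sensitive. Right-censored GI50s are
#' resistant by definition and left-censored ones sensitive; the gap is
#' searched among the finite values only. A fixed `threshold` (on the
#' GI50 scale) overrides the gap rule: sensitive iff GI50 < threshold.
#'
#' @param calls data frame with columns `cell_line`, `gi50`, `censored`.
#' @param threshold optional fixed GI50 cut.
#' @return `calls` with an added `label` column
#'   (`"sensitive"`/`"resistant"`).
#' @export
segregate_by_gi50 <- function(calls, threshold = NULL) {
  stopifnot(all(c("cell_line", "gi50", "censored") %in% names(calls)))
  if (nrow(calls) < 2L) stop("need >= 2 cell lines", call. = FALSE)
  label <- rep(NA_character_, nrow(calls))
  label[calls$censored == "right"] <- "resistant"
  label[calls$censored == "left"] <- "sensitive"
  fin <- which(calls$censored == "none")
  if (!is.null(threshold)) {
    label[fin] <- ifelse(calls$gi50[fin] < threshold,
                         "sensitive", "resistant")
  } else if (length(fin) == 1L) {
    label[fin] <- "sensitive"
  } else if (length(fin) > 1L) {
    lg <- log10(calls$gi50[fin])
    ord <- order(lg)
    gaps <- diff(lg[ord])
    if (max(gaps) == 0) {
      warning("all finite GI50s equal; labelling all sensitive",
              call. = FALSE)
      label[fin] <- "sensitive"
    } else {
      cut_after <- which.max(gaps)
      lab <- rep("resistant", length(fin))
      lab[ord[seq_len(cut_after)]] <- "sensitive"
      label[fin] <- lab
    }
  }
  calls$label <- label
  calls
}

#' Correlate AUC profiles of two drugs
#'
#' Pearson correlation between per-line AUC vectors of two drugs, with a
#' two-sided p value from the t distribution on n - 2 degrees of freedom.
#'
#' @param auc1,auc2 paired AUC vectors (same cell lines, n >= 3).
#' @return list with `r`, `p`, `n` (see [pearson_cor()]).
#' @export
auc_correlation <- function(auc1, auc2) pearson_cor(auc1, auc2)
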