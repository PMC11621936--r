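#' Pearson correlation with a t-based p value
#'
#' Sample Pearson correlation of two paired vectors and the two-sided p
#' value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. Constant input is an error (r is undefined).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

rank_correlations <- function(mat, target, exclude = character()) {
  res <- lapply(setdiff(colnames(mat), exclude), function(ab) {
    v <- mat[, ab]
    if (sd(v[is.finite(v) & is.finite(target)]) == 0) return(NULL)
    pc <- tryCatch(pearson_cor(v, target), error = function(e) NULL)
    if (is.null(pc)) return(NULL)
    data.frame(antibody = ab, r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no non-constant antibody to correlate", call. = FALSE)
  }
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  out
}

#' Rank antibodies by correlation with drug sensitivity
#'
#' Correlates each antibody's level across cell lines (at one time
#' point, e.g. baseline or 24 h post treatment) with log10 GI50 of a
#' drug, and ranks by r descending: proteins at the top are candidate
#' resistance markers. Censored GI50s are excluded with a warning.
#' Constant antibody columns are skipped. A Benjamini-Hochberg `q`
#' column is attached as auxiliary information.
#'
#' @param mat numeric matrix, rows = cell lines, columns = antibodies
#'   (log2 intensities recommended).
#' @param gi50_calls data frame with `cell_line`, `gi50`, `censored`,
#'   aligned by cell line to `mat` rownames.
#' @return data frame (antibody, r, p, n, q), sorted by r descending.
#' @export
rank_vs_gi50 <- function(mat, gi50_calls) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            all(c("cell_line", "gi50", "censored") %in% names(gi50_calls)))
  calls <- gi50_calls[match(rownames(mat), gi50_calls$cell_line), ]
  if (anyNA(calls$gi50)) stop("GI50 calls missing for some cell lines",
                              call. = FALSE)
  keep <- calls$censored == "none"
  if (!all(keep)) {
    warning(sum(!keep), " cell lines with censored GI50 excluded",
            call. = FALSE)
  }
  if (sum(keep) < 3L) stop("need >= 3 cell lines with finite GI50",
                           call. = FALSE)
  rank_correlations(mat[keep, , drop = FALSE],
                    log10(calls$gi50[keep]))
}

#' Rank antibodies by co-expression with an anchor protein
#'
#' Pearson correlation of the anchor antibody against every other
#' antibody across all samples, ranked by r descending; the anchor
#' itself is excluded. Used to find proteins co-regulated with an anchor
#' phosphoprotein (e.g. STAT1-pY701) across drug-perturbation samples.
#'
#' @param mat numeric matrix, rows = samples, columns = antibodies.
#' @param anchor column name of the anchor antibody.
#' @return data frame (antibody, r, p, n, q), sorted by r descending.
#' @export
coexpression_ranking <- function(mat, anchor) {
  stopifnot(is.matrix(mat))
  if (!anchor %in% colnames(mat)) {
    stop("anchor `", anchor, "` not present in the matrix", call. = FALSE)
  }
  rank_correlations(mat, mat[, anchor], exclude = anchor)
}
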