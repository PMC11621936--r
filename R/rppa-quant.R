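#' Describe a printed RPPA slide layout
#'
#' @param n_conditions number of treatment conditions.
#' @param n_timepoints number of sampling times.
#' @param n_cell_lines number of cell lines.
#' @param n_replicates replicate spots per sample.
#' @param n_control_spots control spots per slide.
#' @return a `slide_layout` with `total_spots` computed as
#'   `n_conditions * n_timepoints * n_cell_lines * n_replicates +
#'   n_control_spots`.
#' @examples
#' build_layout(12, 5, 8, 4, 80)$total_spots  # 2000
#' @export
build_layout <- function(n_conditions, n_timepoints, n_cell_lines,
                         n_replicates, n_control_spots) {
  n_conditions <- assert_count(n_conditions, "n_conditions")
  n_timepoints <- assert_count(n_timepoints, "n_timepoints")
  n_cell_lines <- assert_count(n_cell_lines, "n_cell_lines")
  n_replicates <- assert_count(n_replicates, "n_replicates")
  n_control_spots <- assert_count(n_control_spots, "n_control_spots")
  structure(list(
    n_conditions = n_conditions, n_timepoints = n_timepoints,
    n_cell_lines = n_cell_lines, n_replicates = n_replicates,
    n_control_spots = n_control_spots,
    total_spots = n_conditions * n_timepoints * n_cell_lines *
      n_replicates + n_control_spots
  ), class = "slide_layout")
}

#' Aggregate replicate spot intensities
#'
#' Collapses the replicate spots of one sample to a single level: values
#' further than `k * 1.4826 * MAD` from the replicate median are excluded
#' as outliers (the rule is skipped when the MAD is zero and all values
#' are equal), and the median of the survivors is returned.
#'
#' @param values nonnegative replicate intensities (length >= 1).
#' @param k outlier cut in robust SD units (default 3.5).
#' @return list with `level`, `n_used`, `n_excluded`.
#' @examples
#' aggregate_replicates(c(10, 12, 11, 100))  # level 11, one excluded
#' @export
aggregate_replicates <- function(values, k = 3.5) {
  if (length(values) == 0L) stop("no replicate values", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("replicate intensities must be finite and nonnegative",
         call. = FALSE)
  }
  med <- median(values)
  madv <- mad(values)  # includes the 1.4826 consistency constant
  if (madv == 0 && all(values == values[1])) {
    keep <- rep(TRUE, length(values))
  } else {
    keep <- abs(values - med) <= k * madv
  }
  list(level = median(values[keep]),
       n_used = sum(keep), n_excluded = sum(!keep))
}

new_intensity_matrix <- function(values, sample_info) {
  stopifnot(is.matrix(values), nrow(values) == nrow(sample_info))
  structure(values, sample_info = sample_info,
            class = c("intensity_matrix", class(values)))
}

#' Sample annotation of an intensity matrix
#'
#' @param x an `intensity_matrix`.
#' @return data frame with one row per sample (cell_line, drug,
#'   dose_level, time_h), aligned to the matrix rows.
#' @export
sample_info <- function(x) attr(x, "sample_info")

#' Quantify a spot table into a raw intensity matrix
#'
#' Aggregates each sample's replicate spots per antibody with
#' [aggregate_replicates()] and collects the control MIX spot levels per
#' antibody. Rows are samples (cell line x drug x dose x time), columns
#' are antibodies.
#'
#' @param spots spot table as produced by [gen_spot_table()] (columns
#'   condition, drug, dose_level, time_h, cell_line, replicate, antibody,
#'   intensity, is_control).
#' @param k outlier cut passed to [aggregate_replicates()].
#' @return list with `matrix` (raw `intensity_matrix`), `controls`
#'   (named list of control replicate levels per antibody) and `qc`
#'   (replicates used/excluded per cell).
#' @export
quantify_spots <- function(spots, k = 3.5) {
  need <- c("condition", "drug", "dose_level", "time_h", "cell_line",
            "antibody", "intensity", "is_control")
  if (!all(need %in% names(spots))) {
    stop("spot table lacks columns: ",
         paste(setdiff(need, names(spots)), collapse = ", "), call. = FALSE)
  }
  dt <- data.table::as.data.table(spots)
  smp <- dt[is_control == FALSE,
            {
              agg <- aggregate_replicates(intensity, k = k)
              list(level = agg$level, n_used = agg$n_used,
                   n_excluded = agg$n_excluded)
            },
            by = .(cell_line, drug, dose_level, time_h, condition, antibody)]
  data.table::setorder(smp, cell_line, drug, dose_level, time_h, antibody)
  smp[, sample := paste(cell_line, drug, dose_level, time_h, sep = "|")]
  wide <- data.table::dcast(smp, sample ~ antibody, value.var = "level")
  info <- unique(smp[, .(sample, cell_line, drug, dose_level, time_h)])
  info <- info[match(wide$sample, sample)]
  values <- as.matrix(wide[, -1])
  rownames(values) <- wide$sample
  ctrl <- dt[is_control == TRUE, .(levels = list(intensity)), by = antibody]
  controls <- setNames(ctrl$levels, ctrl$antibody)
  list(matrix = new_intensity_matrix(values, as.data.frame(info)),
       controls = controls,
       qc = as.data.frame(smp[, .(sample, antibody, n_used, n_excluded)]))
}

#' Normalise an intensity matrix against control MIX levels
#'
#' Each cell is divided by the median control level of its antibody, then
#' every sample (row) is median-centred in log2 space. Antibodies with a
#' missing or nonpositive control level are dropped with a warning. The
#' output is strictly positive and invariant to rescaling any antibody
#' and its controls by a common factor.
#'
#' @param mat raw `intensity_matrix` from [quantify_spots()].
#' @param controls named list or vector of control levels per antibody.
#' @return normalised `intensity_matrix`.
#' @export
normalize_intensities <- function(mat, controls) {
  stopifnot(inherits(mat, "intensity_matrix"))
  ctrl <- vapply(colnames(mat), function(ab) {
    v <- controls[[ab]]
    if (is.null(v) || length(v) == 0L) NA_real_ else median(as.double(v))
  }, numeric(1))
  bad <- is.na(ctrl) | ctrl <= 0
  if (any(bad)) {
    warning("dropping antibodies without a positive control level: ",
            paste(colnames(mat)[bad], collapse = ", "), call. = FALSE)
  }
  if (all(bad)) stop("no antibody has a usable control level", call. = FALSE)
  values <- unclass(mat)[, !bad, drop = FALSE]
  values <- sweep(values, 2L, ctrl[!bad], "/")
  lv <- log2(values)
  lv <- lv - apply(lv, 1L, median)
  new_intensity_matrix(2^lv, sample_info(mat))
}

#' Assemble per-antibody time courses from an intensity matrix
#'
#' One time course is produced per (series, antibody), a series being a
#' cell line under one drug-dose condition; `log2fc` is computed against
#' the same series' t = 0 sample. Series lacking a t = 0 sample are
#' skipped with a warning, so the number of courses equals
#' `n_series * n_antibodies - n_skipped`.
#'
#' @param mat an `intensity_matrix` whose sample annotation covers a
#'   common time grid including 0.
#' @return a `timecourse_set` (long data frame with `course_id`,
#'   `cell_line`, `drug`, `dose_level`, `antibody`, `time_h`,
#'   `intensity`, `log2fc`; attribute `skipped` lists dropped series).
#' @export
assemble_timecourses <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  info <- sample_info(mat)
  grid <- sort(unique(info$time_h))
  dt <- data.table::data.table(
    info, unclass(mat)[, , drop = FALSE], check.names = FALSE)
  long <- data.table::melt(dt,
    id.vars = c("cell_line", "drug", "dose_level", "time_h"),
    measure.vars = colnames(mat),
    variable.name = "antibody", value.name = "intensity",
    variable.factor = FALSE)
  long[, series := paste(cell_line, drug, dose_level, sep = "|")]
  has_t0 <- long[, .(ok = any(time_h == 0)), by = series]
  skipped <- has_t0[ok == FALSE, series]
  if (length(skipped) > 0L) {
    warning(length(skipped), " series without a t=0 sample skipped",
            call. = FALSE)
    long <- long[!series %in% skipped]
  }
  data.table::setorder(long, series, antibody, time_h)
  long[, log2fc := log2(intensity / intensity[time_h == 0][1]),
       by = .(series, antibody)]
  long[, course_id := paste(series, antibody, sep = "|")]
  out <- as.data.frame(long[, .(course_id, cell_line, drug, dose_level,
                                antibody, time_h, intensity, log2fc)])
  res <- new_timecourse_set(out, grid)
  attr(res, "skipped") <- skipped
  res
}
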