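#' Assign a kinetic class to a log2 fold-change profile
#'
#' A profile without a peak of at least `flat_threshold` log2 units is
#' `none` (no response); peak prominence is measured as the largest
#' absolute log2 fold change minus the smallest one after baseline, so
#' that a uniform offset (such as the folded-noise bias in a centroid of
#' absolute fold changes) does not register as a response. Otherwise the
#' class is set by the time of the absolute peak (earliest time on
#' ties): peaked by 6 h is `early`, by 12 h `intermediate`, later
#' `late`.
#'
#' @param log2fc numeric profile on the time grid.
#' @param time_grid_h matching time grid in hours.
#' @param flat_threshold flat cut in log2 units (default 0.25).
#' @return one of [kinetic_classes()].
#' @export
assign_kinetic_class <- function(log2fc, time_grid_h,
                                 flat_threshold = 0.25) {
  stopifnot(length(log2fc) == length(time_grid_h))
  a <- abs(log2fc)
  prominence <- max(a) - min(a[time_grid_h > 0])
  if (prominence < flat_threshold) return("none")
  t_star <- time_grid_h[which.max(a)]  # which.max takes the earliest tie
  if (t_star <= 6) "early" else if (t_star <= 12) "intermediate" else "late"
}

## Wide matrix of |log2fc| features, one row per complete course.
course_feature_matrix <- function(courses) {
  stopifnot(inherits(courses, "timecourse_set"))
  grid <- attr(courses, "time_grid")
  dt <- data.table::as.data.table(courses)
  wide <- data.table::dcast(dt, course_id ~ time_h, value.var = "log2fc")
  m <- abs(as.matrix(wide[, -1]))
  rownames(m) <- wide$course_id
  keep <- rowSums(is.na(m)) == 0L
  if (!all(keep)) {
    warning(sum(!keep), " courses with missing time points dropped",
            call. = FALSE)
  }
  list(features = m[keep, , drop = FALSE],
       grid = as.double(colnames(wide)[-1]))
}

#' Cluster time courses by their kinetics
#'
#' K-means on absolute log2 fold-change vectors (peak timing, not
#' direction, defines the kinetic classes), with `restarts` random
#' initialisations keeping the best within-cluster sum of squares. Each
#' centroid is then mapped to a kinetic class with
#' [assign_kinetic_class()] and the class propagated to cluster members.
#'
#' @param courses a `timecourse_set`.
#' @param k number of clusters (default 7).
#' @param seed seed making the clustering deterministic.
#' @param restarts random restarts (`nstart`).
#' @param flat_threshold flat cut for centroid classification.
#' @return a `cluster_model`: list with `k`, `centroids`, `assignment`
#'   (course -> cluster), `class_of_cluster`, and `course_class` (data
#'   frame course_id, cluster, class).
#' @export
cluster_timecourses <- function(courses, k = 7L, seed = 1L,
                                restarts = 10L, flat_threshold = 0.25) {
  fm <- course_feature_matrix(courses)
  m <- fm$features
  if (nrow(m) < 1L) stop("no complete courses to cluster", call. = FALSE)
  k <- assert_count(k, "k", 1L)
  if (k > nrow(m)) stop("k exceeds the number of courses", call. = FALSE)
  n_unique <- nrow(unique(m))
  if (k > n_unique) {
    warning("only ", n_unique, " distinct profiles; reducing k",
            call. = FALSE)
    k <- n_unique
  }
  fit <- withr::with_seed(substream_seed(seed, "kmeans"), {
    kmeans(m, centers = k, nstart = restarts, iter.max = 100L)
  })
  class_of_cluster <- vapply(seq_len(k), function(j) {
    assign_kinetic_class(fit$centers[j, ], fm$grid, flat_threshold)
  }, character(1))
  structure(list(
    k = k, centroids = fit$centers,
    assignment = setNames(fit$cluster, rownames(m)),
    class_of_cluster = class_of_cluster,
    course_class = data.frame(course_id = rownames(m),
                              cluster = unname(fit$cluster),
                              class = class_of_cluster[fit$cluster],
                              stringsAsFactors = FALSE),
    time_grid = fm$grid, flat_threshold = flat_threshold
  ), class = "cluster_model")
}

#' Classify every time course into a kinetic class
#'
#' Either via the two-step route (K-means clusters, centroid classes
#' propagated to members; the default) or directly per course.
#'
#' @param courses a `timecourse_set`.
#' @param method `"cluster"` or `"direct"`.
#' @param k,seed,restarts passed to [cluster_timecourses()].
#' @param flat_threshold flat cut in log2 units.
#' @return data frame with one row per course: `course_id`, `cell_line`,
#'   `drug`, `dose_level`, `antibody`, `class`.
#' @export
classify_courses <- function(courses, method = c("cluster", "direct"),
                             k = 7L, seed = 1L, restarts = 10L,
                             flat_threshold = 0.25) {
  method <- match.arg(method)
  meta <- unique(as.data.frame(courses)[
    , c("course_id", "cell_line", "drug", "dose_level", "antibody")])
  if (method == "cluster") {
    model <- cluster_timecourses(courses, k = k, seed = seed,
                                 restarts = restarts,
                                 flat_threshold = flat_threshold)
    cls <- model$course_class[, c("course_id", "class")]
  } else {
    fm <- course_feature_matrix(courses)
    cls <- data.frame(
      course_id = rownames(fm$features),
      class = apply(fm$features, 1L, assign_kinetic_class,
                    time_grid_h = fm$grid,
                    flat_threshold = flat_threshold),
      stringsAsFactors = FALSE)
  }
  merge(meta, cls, by = "course_id", sort = FALSE)
}

#' Tabulate kinetic-class proportions by group
#'
#' Counts classified courses per group over the four kinetic classes and
#' converts to fractions (summing to 1 within each group).
#'
#' @param classified output of [classify_courses()], optionally with
#'   extra grouping columns merged in.
#' @param by character vector of grouping columns.
#' @return data frame: grouping columns, `class`, `n`, `fraction`.
#' @export
proportion_table <- function(classified, by = c("drug", "dose_level")) {
  stopifnot(all(by %in% names(classified)), "class" %in% names(classified))
  dt <- data.table::as.data.table(classified)
  dt[, class := factor(class, levels = kinetic_classes())]
  tab <- dt[, .(n = .N), by = c(by, "class")]
  grp <- unique(tab[, ..by])
  full <- grp[, data.table::data.table(class = factor(kinetic_classes(),
                                       levels = kinetic_classes())),
              by = by]
  tab <- merge(full, tab, by = c(by, "class"), all.x = TRUE)
  tab[is.na(n), n := 0L]
  tab[, fraction := n / sum(n), by = by]
  data.table::setorderv(tab, c(by, "class"))
  as.data.frame(tab)
}

## Collapse class counts to (responsive, none).
collapse_responsive <- function(counts) {
  if (!is.null(names(counts)) && all(names(counts) %in% kinetic_classes())) {
    resp <- sum(counts[setdiff(names(counts), "none")])
    none <- sum(counts[names(counts) == "none"])
    c(responsive = unname(resp), none = unname(none))
  } else if (length(counts) == 2L) {
    c(responsive = counts[[1]], none = counts[[2]])
  } else {
    stop("counts must be named by kinetic class or length 2", call. = FALSE)
  }
}

#' Compare responsive proportions of two groups
#'
#' Collapses class counts to responsive (early + intermediate + late)
#' versus none and applies the two-sided Fisher exact test to the
#' resulting 2x2 table.
#'
#' @param counts_a,counts_b class counts per group, either named by
#'   kinetic class or as length-2 `(responsive, none)` vectors.
#' @return two-sided p value.
#' @export
compare_proportions <- function(counts_a, counts_b) {
  a <- collapse_responsive(counts_a)
  b <- collapse_responsive(counts_b)
  fisher_exact_2x2(rbind(a, b))
}

#' Protein dynamics by drug-sensitivity group
#'
#' Pools classified time courses of sensitive versus resistant cell
#' lines for one drug and compares their responsive fractions (overall
#' and, when a pathway map is supplied, per signalling pathway) with the
#' Fisher exact test. A depleted responsive fraction in the resistant
#' group indicates robust protein-level regulation under the drug.
#'
#' @param classified output of [classify_courses()].
#' @param sensitivity data frame with `cell_line` and `label`
#'   (`"sensitive"`/`"resistant"`), e.g. from [segregate_by_gi50()].
#' @param drug drug to analyse (matched against the `drug` column);
#'   `NULL` uses all courses.
#' @param pathway_map optional data frame (antibody, pathway).
#' @return list with `overall` (proportion table plus `p`) and
#'   `by_pathway` (data frame: pathway, responsive fractions per group,
#'   p), the latter `NULL` without a map.
#' @export
dynamics_by_sensitivity <- function(classified, sensitivity, drug = NULL,
                                    pathway_map = NULL) {
  stopifnot(all(c("cell_line", "label") %in% names(sensitivity)))
  df <- classified
  if (!is.null(drug)) df <- df[df$drug == drug, , drop = FALSE]
  df <- merge(df, sensitivity[, c("cell_line", "label")], by = "cell_line")
  if (nrow(df) == 0L) stop("no classified courses for this drug",
                           call. = FALSE)
  counts_of <- function(d) {
    table(factor(d$class, levels = kinetic_classes()))
  }
  groups <- split(df, df$label)
  tab <- proportion_table(df, by = "label")
  p_overall <- if (length(groups) == 2L) {
    compare_proportions(counts_of(groups[[1]]), counts_of(groups[[2]]))
  } else NA_real_
  by_pathway <- NULL
  if (!is.null(pathway_map)) {
    dfp <- merge(df, pathway_map, by = "antibody")
    by_pathway <- do.call(rbind, lapply(split(dfp, dfp$pathway), function(d) {
      g <- split(d, d$label)
      fr <- vapply(g, function(x) mean(x$class != "none"), numeric(1))
      p <- if (length(g) == 2L) {
        compare_proportions(counts_of(g[[1]]), counts_of(g[[2]]))
      } else NA_real_
      out <- data.frame(pathway = d$pathway[1], n = nrow(d), p = p,
                        stringsAsFactors = FALSE)
      for (nm in names(fr)) out[[paste0("responsive_", nm)]] <- fr[[nm]]
      out
    }))
    rownames(by_pathway) <- NULL
  }
  list(overall = list(table = tab, p = p_overall), by_pathway = by_pathway)
}
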