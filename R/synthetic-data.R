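#' Simulation configuration for the synthetic RPPA world
#'
#' Bundles every knob of the synthetic-data generators. The defaults encode
#' the printed-slide design of the platform being emulated: one slide per
#' antibody carries 12 treatment conditions (4 drugs at low/medium/high
#' concentration) x 5 time points x 8 cell lines x 4 replicate spots, plus
#' 80 control spots of a pooled MIX lysate, i.e. 2000 spots per slide.
#'
#' @param seed root seed; all generators derive named substreams from it.
#' @param n_cell_lines number of cell lines on the panel.
#' @param n_antibodies number of antibodies (one slide each).
#' @param time_grid_h sampling times in hours, strictly increasing from 0.
#'   6, 12 and 24 h must be expressible on the grid for the kinetic class
#'   windows to be meaningful.
#' @param drugs drug names; conditions are `drugs x dose levels`.
#' @param doses_per_drug number of dose levels per drug (3 = low/medium/high).
#' @param replicates spots printed per sample (tetraplicate by default).
#' @param n_control_spots control MIX spots per slide.
#' @param class_mix named fractions over the kinetic classes
#'   `early`, `intermediate`, `late`, `none`; must sum to 1.
#' @param amplitude_log2 peak |log2 fold change| of responsive archetypes.
#' @param noise_sd_log2 additive Gaussian noise SD on log2 scale.
#' @param outlier_rate probability that a replicate spot is a gross (x10)
#'   outlier.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cell_lines = 8L,
                       n_antibodies = 1L,
                       time_grid_h = c(0, 3, 6, 12, 24),
                       drugs = c("5FU", "CIS", "ETP", "DTX"),
                       doses_per_drug = 3L,
                       replicates = 4L,
                       n_control_spots = 80L,
                       class_mix = c(early = 0.15, intermediate = 0.15,
                                     late = 0.10, none = 0.60),
                       amplitude_log2 = 2,
                       noise_sd_log2 = 0.25,
                       outlier_rate = 0.01) {
  seed <- assert_count(seed, "seed")
  n_cell_lines <- assert_count(n_cell_lines, "n_cell_lines", 1L)
  n_antibodies <- assert_count(n_antibodies, "n_antibodies", 1L)
  doses_per_drug <- assert_count(doses_per_drug, "doses_per_drug", 1L)
  replicates <- assert_count(replicates, "replicates", 1L)
  n_control_spots <- assert_count(n_control_spots, "n_control_spots", 0L)
  amplitude_log2 <- assert_number(amplitude_log2, "amplitude_log2", min = 0)
  noise_sd_log2 <- assert_number(noise_sd_log2, "noise_sd_log2", min = 0)
  outlier_rate <- assert_number(outlier_rate, "outlier_rate", 0, 1)

  if (length(time_grid_h) < 3L) {
    stop("`time_grid_h` must contain at least 3 time points", call. = FALSE)
  }
  if (time_grid_h[1] != 0 || any(diff(time_grid_h) <= 0)) {
    stop("`time_grid_h` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% kinetic_classes())) {
    stop("`class_mix` must be named with kinetic classes ",
         paste(kinetic_classes(), collapse = ", "), call. = FALSE)
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    stop("`class_mix` fractions must be nonnegative and sum to 1",
         call. = FALSE)
  }

  structure(list(
    seed = seed, n_cell_lines = n_cell_lines, n_antibodies = n_antibodies,
    time_grid_h = as.double(time_grid_h), drugs = drugs,
    doses_per_drug = doses_per_drug, replicates = replicates,
    n_control_spots = n_control_spots, class_mix = class_mix,
    amplitude_log2 = amplitude_log2, noise_sd_log2 = noise_sd_log2,
    outlier_rate = outlier_rate
  ), class = "sim_config")
}

#' Kinetic class labels
#'
#' The four response classes of a drug-perturbation protein time course:
#' `early` (peaked by 6 h), `intermediate` (peaked by 12 h), `late`
#' (peaked by 24 h) and `none` (flat).
#'
#' @return character vector of the four labels.
#' @export
kinetic_classes <- function() c("early", "intermediate", "late", "none")

dose_level_names <- function(k) {
  if (k == 3L) c("low", "medium", "high") else paste0("dose", seq_len(k))
}

#' Kinetic archetype curve
#'
#' Noise-free |log2 fold change| profile of one kinetic class on a time
#' grid: a unit-height Gaussian bump in log2-time centred on the class's
#' peak time (the latest grid time inside its window: by default 6 h for
#' `early`, 12 h for `intermediate`, the final time for `late`), zero at
#' t = 0; the `none` archetype is identically zero.
#'
#' @param class one of [kinetic_classes()].
#' @param time_grid_h time grid (hours), first element 0.
#' @param width bump width in log2-hours.
#' @return numeric vector on the grid with maximum 1 (or all 0 for `none`).
#' @export
archetype_curve <- function(class, time_grid_h, width = 0.75) {
  class <- match.arg(class, kinetic_classes())
  t <- as.double(time_grid_h)
  if (class == "none") return(numeric(length(t)))
  peak <- switch(class,
    early = max(t[t > 0 & t <= 6]),
    intermediate = max(t[t > 6 & t <= 12]),
    late = max(t[t > 12])
  )
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-(log2(t[pos] / peak))^2 / (2 * width^2))
  out
}

## Draw kinetic classes for n courses from the configured mix.
draw_classes <- function(n, class_mix) {
  labs <- names(class_mix)
  labs[sample.int(length(labs), n, replace = TRUE, prob = class_mix)]
}

#' Generate a synthetic RPPA spot table
#'
#' Emits one slide per antibody with one spot row per (condition, time
#' point, cell line, replicate) plus the configured control MIX spots.
#' Replicate intensities are the sample's true level times multiplicative
#' log-normal noise; with probability `outlier_rate` a replicate is
#' multiplied by a gross-error factor of 10. Every true level is recorded
#' in the ground-truth record, so noiseless runs can be checked exactly.
#'
#' @param config a [sim_config()].
#' @return list with `spots` (data frame: slide, block, row, col,
#'   condition, drug, dose_level, time_h, cell_line, replicate, antibody,
#'   intensity, is_control) and `truth` (class per course, true sample
#'   levels, control level per antibody).
#' @export
gen_spot_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(substream_seed(config$seed, "spots"), {
    grid <- config$time_grid_h
    lines <- sprintf("line%02d", seq_len(config$n_cell_lines))
    abs_ <- sprintf("ab%03d", seq_len(config$n_antibodies))
    levels_ <- dose_level_names(config$doses_per_drug)
    cond <- expand.grid(dose_level = levels_, drug = config$drugs,
                        stringsAsFactors = FALSE)[, c("drug", "dose_level")]
    cond$condition <- paste(cond$drug, cond$dose_level, sep = "_")

    ## one kinetic course per antibody x cell line x condition
    courses <- expand.grid(antibody = abs_, cell_line = lines,
                           condition = cond$condition,
                           stringsAsFactors = FALSE)
    courses$class <- draw_classes(nrow(courses), config$class_mix)
    courses$sign <- sample(c(-1, 1), nrow(courses), replace = TRUE)
    courses$course_id <- paste(courses$cell_line, courses$condition,
                               courses$antibody, sep = "|")

    ctrl_level <- setNames(rlnorm(length(abs_), log(1000), 0.5), abs_)
    base <- expand.grid(antibody = abs_, cell_line = lines,
                        stringsAsFactors = FALSE)
    base$baseline <- ctrl_level[base$antibody] * 2^rnorm(nrow(base), 0, 0.5)

    arch <- vapply(kinetic_classes(), archetype_curve,
                   numeric(length(grid)), time_grid_h = grid)

    dt <- data.table::as.data.table(courses)
    dt <- dt[, .(time_h = grid,
                 log2fc_true = sign * config$amplitude_log2 *
                   arch[, class]),
             by = .(course_id, antibody, cell_line, condition, class)]
    dt <- merge(dt, data.table::as.data.table(base),
                by = c("antibody", "cell_line"), sort = FALSE)
    dt <- merge(dt, data.table::as.data.table(cond), by = "condition",
                sort = FALSE)
    dt[, true_level := baseline * 2^log2fc_true]

    reps <- dt[rep(seq_len(nrow(dt)), each = config$replicates)]
    reps[, replicate := rep(seq_len(config$replicates), nrow(dt))]
    reps[, intensity := true_level *
           2^rnorm(.N, 0, config$noise_sd_log2) *
           ifelse(runif(.N) < config$outlier_rate, 10, 1)]
    reps[, is_control := FALSE]

    ## control MIX spots per slide
    ctrl <- data.table::data.table(
      antibody = rep(abs_, each = config$n_control_spots),
      condition = "MIX", drug = "none", dose_level = "none",
      time_h = NA_real_, cell_line = "MIX",
      replicate = rep(seq_len(config$n_control_spots), length(abs_))
    )
    ctrl[, intensity := ctrl_level[antibody] *
           2^rnorm(.N, 0, config$noise_sd_log2)]
    ctrl[, is_control := TRUE]

    cols <- c("condition", "drug", "dose_level", "time_h", "cell_line",
              "replicate", "antibody", "intensity", "is_control")
    spots <- rbind(reps[, ..cols], ctrl[, ..cols])
    data.table::setorder(spots, antibody, is_control, condition,
                         cell_line, time_h, replicate)
    ## slide geometry: one slide per antibody, spots filled row-major
    spots[, slide := match(antibody, abs_)]
    spots[, idx := seq_len(.N), by = slide]
    spots[, block := 1L]
    spots[, row := (idx - 1L) %/% 50L + 1L]
    spots[, col := (idx - 1L) %% 50L + 1L]
    spots[, idx := NULL]
    out_cols <- c("slide", "block", "row", "col", "condition", "drug",
                  "dose_level", "time_h", "cell_line", "replicate",
                  "antibody", "intensity", "is_control")
    spots <- as.data.frame(spots[, ..out_cols])

    truth <- list(
      class_by_course = courses[, c("course_id", "class", "sign")],
      true_levels = as.data.frame(
        dt[, .(antibody, cell_line, condition, drug, dose_level, time_h,
               log2fc_true, true_level)]),
      control_level = ctrl_level
    )
    list(spots = spots, truth = truth)
  })
}

#' Generate synthetic protein expression time courses
#'
#' Draws one time course per (series, antibody), where a series is a cell
#' line under one drug-dose condition. Each course is sampled from its
#' kinetic-class archetype with amplitude `amplitude_log2`, a random
#' direction (up- or down-regulation), and additive Gaussian noise of SD
#' `noise_sd_log2` at every time point after t = 0; `log2fc` at t = 0 is
#' exactly 0 by construction. The class of every course is recorded.
#'
#' @param config a [sim_config()].
#' @return list with `courses` (a `timecourse_set`: long data frame with
#'   course_id, cell_line, drug, dose_level, antibody, time_h, log2fc and
#'   a `time_grid` attribute) and `truth` (`class_by_course`).
#' @export
gen_timecourses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$time_grid_h
  withr::with_seed(substream_seed(config$seed, "courses"), {
    lines <- sprintf("line%02d", seq_len(config$n_cell_lines))
    abs_ <- sprintf("ab%03d", seq_len(config$n_antibodies))
    levels_ <- dose_level_names(config$doses_per_drug)
    series <- expand.grid(dose_level = levels_, drug = config$drugs,
                          cell_line = lines, stringsAsFactors = FALSE)
    courses <- merge(series, data.frame(antibody = abs_), by = NULL)
    courses$course_id <- paste(courses$cell_line, courses$drug,
                               courses$dose_level, courses$antibody,
                               sep = "|")
    courses$class <- draw_classes(nrow(courses), config$class_mix)
    courses$sign <- sample(c(-1, 1), nrow(courses), replace = TRUE)

    arch <- vapply(kinetic_classes(), archetype_curve,
                   numeric(length(grid)), time_grid_h = grid)
    n <- nrow(courses)
    fc <- t(arch[, courses$class]) * courses$sign * config$amplitude_log2
    if (config$noise_sd_log2 > 0) {
      noise <- matrix(rnorm(n * (length(grid) - 1L), 0,
                            config$noise_sd_log2), nrow = n)
      fc[, -1L] <- fc[, -1L] + noise
    }
    long <- data.frame(
      course_id = rep(courses$course_id, each = length(grid)),
      cell_line = rep(courses$cell_line, each = length(grid)),
      drug = rep(courses$drug, each = length(grid)),
      dose_level = rep(courses$dose_level, each = length(grid)),
      antibody = rep(courses$antibody, each = length(grid)),
      time_h = rep(grid, n),
      log2fc = as.vector(t(fc)),
      stringsAsFactors = FALSE
    )
    list(courses = new_timecourse_set(long, grid),
         truth = list(class_by_course =
                        courses[, c("course_id", "class", "sign")]))
  })
}

new_timecourse_set <- function(df, time_grid) {
  structure(df, time_grid = as.double(time_grid),
            class = c("timecourse_set", "data.frame"))
}

#' Generate a synthetic dose-response viability profile
#'
#' Viability follows a 4-parameter logistic in dose with top 100, bottom
#' 0, Hill slope `hill` and midpoint `true_gi50`, plus additive Gaussian
#' noise in percentage points. When `true_gi50` lies on the dose grid and
#' `noise_sd = 0`, viability at that dose is exactly 50.
#'
#' @param true_gi50 true midpoint concentration (same units as `doses`).
#' @param doses strictly increasing positive concentrations.
#' @param noise_sd noise SD in viability percentage points.
#' @param seed seed for the noise draw.
#' @param hill Hill slope of the logistic (default 1).
#' @return data frame (dose, viability_pct) with attribute `true_gi50`.
#' @export
gen_dose_response <- function(true_gi50, doses, noise_sd = 0, seed = 1L,
                              hill = 1) {
  true_gi50 <- assert_number(true_gi50, "true_gi50", min = 1e-12)
  if (any(doses <= 0) || any(diff(doses) <= 0)) {
    stop("`doses` must be positive and strictly increasing", call. = FALSE)
  }
  viab <- 100 / (1 + (doses / true_gi50)^hill)
  if (noise_sd > 0) {
    withr::with_seed(substream_seed(seed, "doses"), {
      viab <- viab + rnorm(length(doses), 0, noise_sd)
    })
  }
  structure(data.frame(dose = doses, viability_pct = viab),
            true_gi50 = true_gi50)
}

#' Generate synthetic copy-number profiles with a planted shared loss
#'
#' Every cell line starts diploid (copy number 2) at each of
#' `n_positions` unit positions on one chromosome. Lines belonging to the
#' designated group lose one copy across the planted region; elsewhere,
#' sporadic background gains (copy 3) and losses (copy 1) occur
#' independently at `background_rate` per position.
#'
#' @param n_lines number of cell lines.
#' @param n_positions genome length in unit positions (1-based inclusive).
#' @param planted_region list with `chrom`, `start`, `end`.
#' @param group_labels logical or 0/1 vector of length `n_lines`: which
#'   lines carry the planted loss.
#' @param background_rate per-position probability of a sporadic event.
#' @param seed seed.
#' @return list with `profiles` (list of per-line segment data frames:
#'   cell_line, chrom, start, end, copy_number) and `truth`.
#' @export
gen_cnv_profiles <- function(n_lines, n_positions, planted_region,
                             group_labels, background_rate = 0.01,
                             seed = 1L) {
  n_lines <- assert_count(n_lines, "n_lines", 1L)
  n_positions <- assert_count(n_positions, "n_positions", 1L)
  stopifnot(length(group_labels) == n_lines)
  group <- as.logical(group_labels)
  chrom <- planted_region$chrom %||% "chr1"
  withr::with_seed(substream_seed(seed, "cnv"), {
    lines <- sprintf("line%02d", seq_len(n_lines))
    profiles <- lapply(seq_len(n_lines), function(i) {
      cn <- rep(2L, n_positions)
      if (background_rate > 0) {
        hit <- runif(n_positions) < background_rate
        cn[hit] <- sample(c(1L, 3L), sum(hit), replace = TRUE)
      }
      if (group[i]) {
        idx <- planted_region$start:planted_region$end
        cn[idx] <- 1L
      }
      data.frame(cell_line = lines[i], chrom = chrom,
                 start = seq_len(n_positions), end = seq_len(n_positions),
                 copy_number = cn, stringsAsFactors = FALSE)
    })
    names(profiles) <- lines
    list(profiles = profiles,
         truth = list(planted_region = c(planted_region, list(chrom = chrom)),
                      group = setNames(group, lines)))
  })
}

#' Generate a synthetic survival cohort with planted hazard ratios
#'
#' Event times are exponential with a stratum- and arm-specific hazard:
#' the control arm has hazard `log(2) / median_surv_months` in every
#' stratum, and the treated arm's hazard is multiplied by the stratum's
#' entry in `hr_by_stratum`. Censoring is an independent exponential with
#' rate `censor_rate`, plus administrative censoring at
#' `admin_censor_months`. Binary markers are independent Bernoulli draws
#' at the given prevalences; TLC (total lymphocyte count) is log-normal.
#'
#' @param n cohort size.
#' @param arms two arm labels, control first (default surgery vs S-1
#'   adjuvant chemotherapy).
#' @param hr_by_stratum named positive reals: treated-vs-control hazard
#'   ratio per stratum; stratum membership is drawn uniformly.
#' @param censor_rate exponential censoring rate per month.
#' @param marker_prevalences named list of Bernoulli prevalences for
#'   binary markers.
#' @param seed seed.
#' @param median_surv_months control-arm median survival.
#' @param admin_censor_months administrative censoring horizon.
#' @return list with `cohort` (data frame: id, time_months, event,
#'   endpoint, arm, stratum, tlc, one column per marker) and `truth`.
#' @export
gen_cohort <- function(n, arms = c("surgery", "S-1"),
                       hr_by_stratum = c(`TLC-` = 1, `TLC+` = 0.46),
                       censor_rate = log(2) / 240,
                       marker_prevalences = list(PDL1 = 0.29, IkBa = 0.45),
                       seed = 1L, median_surv_months = 60,
                       admin_censor_months = 120) {
  n <- assert_count(n, "n", 2L)
  stopifnot(length(arms) == 2L, all(hr_by_stratum > 0))
  withr::with_seed(substream_seed(seed, "cohort"), {
    strata <- names(hr_by_stratum)
    stratum <- sample(strata, n, replace = TRUE)
    arm <- sample(arms, n, replace = TRUE)
    lambda0 <- log(2) / median_surv_months
    hr <- ifelse(arm == arms[2], hr_by_stratum[stratum], 1)
    t_event <- rexp(n, rate = lambda0 * hr)
    t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
    t_cens <- pmin(t_cens, admin_censor_months)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    cohort <- data.frame(
      id = sprintf("pt%04d", seq_len(n)),
      time_months = time, event = event, endpoint = "OS",
      arm = arm, stratum = stratum,
      tlc = rlnorm(n, log(1600), 0.3),
      stringsAsFactors = FALSE
    )
    for (m in names(marker_prevalences)) {
      cohort[[m]] <- rbinom(n, 1L, marker_prevalences[[m]])
    }
    list(cohort = cohort,
         truth = list(hr_by_stratum = hr_by_stratum,
                      control_arm = arms[1],
                      median_surv_months = median_surv_months))
  })
}

#' Generate an antibody-to-pathway map
#'
#' Assigns each antibody to one of the six signalling pathways commonly
#' profiled on drug-perturbation RPPA panels (DNA damage response, MAPK,
#' PI3K, STAT, NFKB, WNT) or to `other`, uniformly at random.
#'
#' @param antibodies antibody names.
#' @param seed seed.
#' @return data frame (antibody, pathway).
#' @export
gen_pathway_map <- function(antibodies, seed = 1L) {
  pw <- c("DDR", "MAPK", "PI3K", "STAT", "NFKB", "WNT", "other")
  withr::with_seed(substream_seed(seed, "pathways"), {
    data.frame(antibody = antibodies,
               pathway = sample(pw, length(antibodies), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
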