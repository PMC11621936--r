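#' Default demonstration configuration for [run_pipeline()]
#'
#' A small end-to-end configuration: an 8-line panel profiled with 20
#' antibodies on the standard slide design, a half-log dose grid per
#' drug with a bimodal planted GI50 (sensitive lines near 0.5, resistant
#' near 50 concentration units), a 500-position genome with a loss
#' region planted in the sensitive group, and a 400-patient cohort with
#' the treatment effect confined to the marker-positive stratum.
#'
#' @param seed root seed for the whole run.
#' @return nested configuration list.
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(n_cell_lines = 8L, n_antibodies = 20L,
                    amplitude_log2 = 2, noise_sd_log2 = 0.25,
                    outlier_rate = 0.01),
    gi50 = list(doses = 10^seq(-2, 2, by = 0.5),
                gi50_sensitive = 0.5, gi50_resistant = 50,
                n_resistant = 3L, noise_sd = 2),
    dynamics = list(k = 7L, restarts = 10L, flat_threshold = 0.25,
                    drug = "5FU"),
    cnv = list(n_positions = 500L, region_start = 101L,
               region_end = 150L, background_rate = 0.01,
               gene_size = 25L, drug = "CIS"),
    survive = list(n = 400L, hr_by_stratum = c(`TLC-` = 1, `TLC+` = 0.46))
  )
}

stage_deps <- function() {
  list(simulate = character(),
       quantify = "simulate",
       gi50 = "simulate",
       dynamics = c("quantify", "gi50"),
       correlate = c("quantify", "gi50"),
       cnv = c("simulate", "gi50"),
       survive = "simulate")
}

## Per-cell-line log2 matrix at one time point (t = 0 -> baseline),
## averaging over conditions.
matrix_at_time <- function(mat, time_h) {
  info <- sample_info(mat)
  sel <- info$time_h == time_h
  if (!any(sel)) stop("no samples at t = ", time_h, call. = FALSE)
  lv <- log2(unclass(mat)[sel, , drop = FALSE])
  lines <- info$cell_line[sel]
  out <- do.call(rbind, lapply(unique(lines), function(cl) {
    colMeans(lv[lines == cl, , drop = FALSE])
  }))
  rownames(out) <- unique(lines)
  out
}

#' Run the whole analysis pipeline on synthetic data
#'
#' Executes simulate, quantify, gi50, dynamics, correlate, cnv and
#' survive in dependency order from one configuration, writing every
#' intermediate as plain TSV under `out_dir` together with a ground
#' truth JSON sidecar. A failed stage halts its dependents (recorded as
#' skipped); rerunning with the same configuration and seed reproduces
#' all outputs byte-identically.
#'
#' @param config nested configuration list (see [demo_config()]) or a
#'   path to a JSON file with the same structure.
#' @param out_dir output directory (created if missing).
#' @return the run manifest: data frame (stage, status, seconds,
#'   outputs) with attributes `config_hash` and `seed`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  for (key in c("seed", "simulate", "gi50", "dynamics", "cnv", "survive")) {
    if (is.null(config[[key]])) {
      stop("configuration is missing required key `", key, "`",
           call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  seed <- config$seed
  state <- new.env(parent = emptyenv())
  manifest <- data.frame(stage = names(stage_deps()), status = "pending",
                         seconds = NA_real_, outputs = "",
                         stringsAsFactors = FALSE)

  runners <- list(
    simulate = function() {
      sim <- config$simulate
      cfg <- sim_config(seed = seed,
                        n_cell_lines = sim$n_cell_lines,
                        n_antibodies = sim$n_antibodies,
                        amplitude_log2 = sim$amplitude_log2,
                        noise_sd_log2 = sim$noise_sd_log2,
                        outlier_rate = sim$outlier_rate)
      spots <- gen_spot_table(cfg)
      state$spots <- spots
      state$cfg <- cfg
      lines <- sprintf("line%02d", seq_len(cfg$n_cell_lines))
      ## planted bimodal GI50s per drug
      g <- config$gi50
      truth_gi50 <- withr::with_seed(substream_seed(seed, "gi50truth"), {
        do.call(rbind, lapply(cfg$drugs, function(dr) {
          res <- sample(lines, g$n_resistant)
          data.frame(cell_line = lines, drug = dr,
                     true_gi50 = ifelse(lines %in% res,
                                        g$gi50_resistant,
                                        g$gi50_sensitive) *
                       2^rnorm(length(lines), 0, 0.25),
                     stringsAsFactors = FALSE)
        }))
      })
      viability <- do.call(rbind, lapply(seq_len(nrow(truth_gi50)),
        function(i) {
          pr <- gen_dose_response(truth_gi50$true_gi50[i], g$doses,
                                  noise_sd = g$noise_sd,
                                  seed = substream_seed(seed, paste0(
                                    "dr|", truth_gi50$cell_line[i], "|",
                                    truth_gi50$drug[i])))
          data.frame(cell_line = truth_gi50$cell_line[i],
                     drug = truth_gi50$drug[i], pr,
                     stringsAsFactors = FALSE)
        }))
      state$truth_gi50 <- truth_gi50
      ## CNV: loss region planted in the lines truly sensitive to cnv$drug
      cn <- config$cnv
      sens_lines <- truth_gi50$cell_line[
        truth_gi50$drug == cn$drug &
          truth_gi50$true_gi50 < sqrt(g$gi50_sensitive * g$gi50_resistant)]
      cnv <- gen_cnv_profiles(
        cfg$n_cell_lines, cn$n_positions,
        planted_region = list(chrom = "chr1", start = cn$region_start,
                              end = cn$region_end),
        group_labels = lines %in% sens_lines,
        background_rate = cn$background_rate, seed = seed)
      state$cnv <- cnv
      sv <- config$survive
      cohort <- gen_cohort(sv$n, hr_by_stratum = unlist(sv$hr_by_stratum),
                           seed = seed)
      state$cohort <- cohort
      pmap <- gen_pathway_map(sprintf("ab%03d", seq_len(cfg$n_antibodies)),
                              seed = seed)
      state$pathway_map <- pmap

      paths <- c(spots = file.path(out_dir, "spots.tsv"),
                 viability = file.path(out_dir, "viability.tsv"),
                 cnv = file.path(out_dir, "cnv_segments.tsv"),
                 cohort = file.path(out_dir, "cohort.tsv"),
                 pathways = file.path(out_dir, "pathway_map.tsv"),
                 truth = file.path(out_dir, "ground_truth.json"))
      write_tsv(spots$spots, paths["spots"])
      write_tsv(viability, paths["viability"])
      write_tsv(do.call(rbind, cnv$profiles), paths["cnv"])
      write_tsv(cohort$cohort, paths["cohort"])
      write_tsv(pmap, paths["pathways"])
      jsonlite::write_json(
        list(class_by_course = spots$truth$class_by_course,
             gi50_by_line_drug = truth_gi50,
             planted_loss_region = cnv$truth$planted_region,
             cnv_group = cnv$truth$group,
             hr_by_stratum = cohort$truth$hr_by_stratum),
        paths["truth"], auto_unbox = TRUE, digits = NA)
      paths
    },
    quantify = function() {
      q <- quantify_spots(state$spots$spots)
      norm <- normalize_intensities(q$matrix, q$controls)
      state$matrix <- norm
      path <- file.path(out_dir, "intensity_matrix.tsv")
      write_tsv(cbind(sample_info(norm), as.data.frame(unclass(norm))),
                path)
      c(matrix = path)
    },
    gi50 = function() {
      v <- read_tsv(file.path(out_dir, "viability.tsv"))
      calls <- do.call(rbind, lapply(split(v, list(v$cell_line, v$drug)),
        function(d) {
          d <- d[order(d$dose), ]
          gc <- compute_gi50(d$dose, d$viability_pct)
          data.frame(cell_line = d$cell_line[1], drug = d$drug[1],
                     gi50 = gc$gi50, censored = gc$censored,
                     auc = compute_auc(d$dose, d$viability_pct),
                     stringsAsFactors = FALSE)
        }))
      calls <- do.call(rbind, lapply(split(calls, calls$drug),
                                     segregate_by_gi50))
      rownames(calls) <- NULL
      state$calls <- calls
      path <- file.path(out_dir, "sensitivity_calls.tsv")
      write_tsv(calls, path)
      c(calls = path)
    },
    dynamics = function() {
      courses <- assemble_timecourses(state$matrix)
      dy <- config$dynamics
      classified <- classify_courses(courses, k = dy$k, seed = seed,
                                     restarts = dy$restarts,
                                     flat_threshold = dy$flat_threshold)
      props <- proportion_table(classified, by = c("drug", "dose_level"))
      sens <- state$calls[state$calls$drug == dy$drug, ]
      res <- dynamics_by_sensitivity(classified, sens, drug = dy$drug,
                                     pathway_map = state$pathway_map)
      paths <- c(classified = file.path(out_dir, "classified_courses.tsv"),
                 proportions = file.path(out_dir, "class_proportions.tsv"),
                 by_sens = file.path(out_dir, "dynamics_by_sensitivity.tsv"))
      write_tsv(classified, paths["classified"])
      write_tsv(props, paths["proportions"])
      sens_tab <- res$overall$table
      sens_tab$p_overall <- res$overall$p
      write_tsv(sens_tab, paths["by_sens"])
      if (!is.null(res$by_pathway)) {
        paths <- c(paths,
                   by_pathway = file.path(out_dir,
                                          "dynamics_by_pathway.tsv"))
        write_tsv(res$by_pathway, paths["by_pathway"])
      }
      paths
    },
    correlate = function() {
      base <- matrix_at_time(state$matrix, 0)
      dr <- config$dynamics$drug
      calls <- state$calls[state$calls$drug == dr, ]
      ranked <- rank_vs_gi50(base, calls)
      path <- file.path(out_dir, "gi50_correlations.tsv")
      write_tsv(ranked, path)
      c(correlations = path)
    },
    cnv = function() {
      profiles <- state$cnv$profiles
      counts <- do.call(rbind, lapply(names(profiles), function(cl) {
        ct <- count_cnv_loci(profiles[[cl]])
        data.frame(cell_line = cl, n_loss = ct$n_loss,
                   n_gain = ct$n_gain, stringsAsFactors = FALSE)
      }))
      dr <- config$cnv$drug
      calls <- state$calls[state$calls$drug == dr, ]
      counts <- merge(counts, calls[, c("cell_line", "label")],
                      by = "cell_line")
      grp <- split(counts$n_loss, counts$label)
      mw <- if (length(grp) == 2L) {
        compare_group_counts(grp$sensitive, grp$resistant)$p
      } else NA_real_
      counts$p_loss_mw <- mw
      cn <- config$cnv
      n_genes <- cn$n_positions %/% cn$gene_size
      genes <- data.frame(
        gene = sprintf("gene%03d", seq_len(n_genes)), chrom = "chr1",
        start = (seq_len(n_genes) - 1L) * cn$gene_size + 1L,
        end = seq_len(n_genes) * cn$gene_size)
      lm <- shared_loss_matrix(profiles, genes)
      slt <- shared_loss_test(
        lm, counts$label[match(colnames(lm), counts$cell_line)] ==
          "sensitive")
      paths <- c(counts = file.path(out_dir, "cnv_counts.tsv"),
                 shared = file.path(out_dir, "shared_loss.tsv"))
      write_tsv(counts, paths["counts"])
      write_tsv(slt, paths["shared"])
      paths
    },
    survive = function() {
      cohort <- state$cohort$cohort
      km_tab <- do.call(rbind, lapply(
        split(cohort, list(cohort$stratum, cohort$arm)), function(d) {
          km <- km_estimate(d$time_months, d$event)
          data.frame(stratum = d$stratum[1], arm = d$arm[1],
                     n = nrow(d), surv_60m = survival_at(km, 60),
                     stringsAsFactors = FALSE)
        }))
      rownames(km_tab) <- NULL
      forest <- subgroup_analysis(cohort, "stratum", "arm",
                                  arm_levels = c("surgery", "S-1"))
      lr <- do.call(rbind, lapply(split(cohort, cohort$stratum),
        function(d) {
          t <- logrank_test(d$time_months, d$event, d$arm)
          data.frame(stratum = d$stratum[1], chi2 = t$chi2, p = t$p,
                     stringsAsFactors = FALSE)
        }))
      forest <- merge(forest, lr, by = "stratum",
                      suffixes = c("_cox", "_logrank"))
      paths <- c(km = file.path(out_dir, "km_5year.tsv"),
                 forest = file.path(out_dir, "forest.tsv"))
      write_tsv(km_tab, paths["km"])
      write_tsv(forest, paths["forest"])
      paths
    }
  )

  deps <- stage_deps()
  for (i in seq_len(nrow(manifest))) {
    st <- manifest$stage[i]
    up <- manifest$status[match(deps[[st]], manifest$stage)]
    if (length(up) > 0L && !all(up == "ok")) {
      manifest$status[i] <- "skipped"
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, paths = runners[[st]]()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    manifest$seconds[i] <- round(proc.time()[["elapsed"]] - t0, 3)
    if (res$ok) {
      manifest$status[i] <- "ok"
      manifest$outputs[i] <- paste(res$paths, collapse = ";")
    } else {
      manifest$status[i] <- paste0("failed: ", res$msg)
    }
  }
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  attr(manifest, "config_hash") <- unname(tools::md5sum(cfg_path))
  attr(manifest, "seed") <- seed
  manifest
}
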