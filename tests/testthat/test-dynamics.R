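grid5 <- c(0, 3, 6, 12, 24)

test_that("kinetic class assignment follows the peak-time windows", {
  expect_equal(assign_kinetic_class(c(0, 1.2, 0.4, 0.1, 0), grid5), "early")
  expect_equal(assign_kinetic_class(c(0, 0.1, 0.1, 0, 0.1), grid5), "none")
  expect_equal(assign_kinetic_class(c(0, 0.1, 0.3, 0.2, 1.0), grid5),
               "late")
  expect_equal(assign_kinetic_class(c(0, 0.2, 0.2, 1.4, 0.3), grid5),
               "intermediate")
  # direction is irrelevant; ties go to the earliest time
  expect_equal(assign_kinetic_class(c(0, -1.2, -0.4, 0, 0), grid5), "early")
  expect_equal(assign_kinetic_class(c(0, 1, 1, 1, 1) - c(0, 0, 0, 0, 0.8),
                                    grid5), "early")
  # uniform folded-noise offset does not count as a response
  expect_equal(assign_kinetic_class(c(0, 0.4, 0.4, 0.4, 0.4), grid5),
               "none")
})

test_that("clustering is deterministic and collapses identical courses", {
  tcs <- make_tcs(list(a = c(0, 1, 2, 1, 0), b = c(0, 1, 2, 1, 0),
                       c = c(0, 1, 2, 1, 0)))
  expect_warning(model <- cluster_timecourses(tcs, k = 3, seed = 1),
                 "distinct")
  expect_equal(model$k, 1L)
  expect_equal(unname(model$centroids[1, ]), c(0, 1, 2, 1, 0))

  cfg <- sim_config(seed = 2, n_antibodies = 5)
  tc <- gen_timecourses(cfg)
  m1 <- cluster_timecourses(tc$courses, k = 4, seed = 3)
  m2 <- cluster_timecourses(tc$courses, k = 4, seed = 3)
  expect_identical(m1$assignment, m2$assignment)
  expect_error(cluster_timecourses(tcs, k = 10, seed = 1), "exceeds")
})

test_that("well-separated archetypes are partitioned exactly", {
  cfg <- sim_config(seed = 6, n_antibodies = 4, noise_sd_log2 = 0.05,
                    class_mix = c(early = 0.5, late = 0.5))
  tc <- gen_timecourses(cfg)
  model <- cluster_timecourses(tc$courses, k = 2, seed = 6)
  mg <- merge(model$course_class, tc$truth$class_by_course,
              by = "course_id")
  expect_equal(mg$class.x, mg$class.y)
})

test_that("direct classification recovers noiseless archetypes exactly", {
  cfg <- sim_config(seed = 13, n_antibodies = 6, noise_sd_log2 = 0,
                    class_mix = c(early = 0.25, intermediate = 0.25,
                                  late = 0.25, none = 0.25))
  tc <- gen_timecourses(cfg)
  cl <- classify_courses(tc$courses, method = "direct")
  mg <- merge(cl, tc$truth$class_by_course, by = "course_id")
  expect_equal(mg$class.x, mg$class.y)
})

test_that("proportion tables count classes and sum to one", {
  df <- data.frame(drug = "5FU", dose_level = "high",
                   class = c("early", "none", "none", "late"))
  tab <- proportion_table(df)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$n[tab$class == "none"], 2L)
  expect_equal(sum(tab$fraction[tab$class != "none"]), 0.5)
  expect_equal(nrow(tab), 4L)  # all four classes always present
})

test_that("proportion comparison collapses to responsive vs none", {
  expect_equal(compare_proportions(c(3, 1), c(1, 3)), 34 / 70)
  expect_equal(compare_proportions(c(5, 5), c(5, 5)), 1)
  expect_equal(
    compare_proportions(c(early = 2, intermediate = 1, late = 0, none = 1),
                        c(early = 0, intermediate = 1, late = 0, none = 3)),
    fisher_exact_2x2(rbind(c(3, 1), c(1, 3))))
})

test_that("planted dynamics depletion is detected per sensitivity group", {
  gen_arm <- function(mix, seed, lines) {
    cfg <- sim_config(seed = seed, n_cell_lines = 2, n_antibodies = 100,
                      drugs = "5FU", doses_per_drug = 1, class_mix = mix,
                      noise_sd_log2 = 0.1)
    tc <- gen_timecourses(cfg)$courses
    tc$cell_line <- paste0(lines, tc$cell_line)
    tc$course_id <- paste0(lines, tc$course_id)
    rppadyn:::new_timecourse_set(tc, attr(tc, "time_grid"))
  }
  sens <- gen_arm(c(early = 0.2, intermediate = 0.2, late = 0.1,
                    none = 0.5), 1, "S")
  res <- gen_arm(c(early = 0.04, intermediate = 0.03, late = 0.03,
                   none = 0.9), 2, "R")
  courses <- rppadyn:::new_timecourse_set(rbind(sens, res),
                                          attr(sens, "time_grid"))
  classified <- classify_courses(courses, method = "cluster", k = 7,
                                 seed = 5)
  labels <- data.frame(
    cell_line = unique(classified$cell_line),
    label = ifelse(startsWith(unique(classified$cell_line), "S"),
                   "sensitive", "resistant"))
  out <- dynamics_by_sensitivity(classified, labels, drug = "5FU")
  expect_lt(out$overall$p, 0.01)
  tab <- out$overall$table
  resp <- tapply(tab$fraction[tab$class != "none"],
                 tab$label[tab$class != "none"], sum)
  expect_lt(resp[["resistant"]], resp[["sensitive"]])
})

test_that("an all-'other' pathway map reproduces the overall contrast", {
  cfg <- sim_config(seed = 4, n_antibodies = 10)
  tc <- gen_timecourses(cfg)
  classified <- classify_courses(tc$courses, method = "direct")
  labels <- data.frame(cell_line = sprintf("line%02d", 1:8),
                       label = rep(c("sensitive", "resistant"), each = 4))
  pmap <- data.frame(antibody = sprintf("ab%03d", 1:10),
                     pathway = "other")
  out <- dynamics_by_sensitivity(classified, labels, drug = "5FU",
                                 pathway_map = pmap)
  expect_equal(nrow(out$by_pathway), 1L)
  expect_equal(out$by_pathway$p, out$overall$p)
})
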