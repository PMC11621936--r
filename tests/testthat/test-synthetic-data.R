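test_that("sim_config enforces its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(class_mix = c(early = 0.5, none = 0.6)),
               "sum to 1")
  expect_error(sim_config(time_grid_h = c(0, 24)), "at least 3")
  expect_error(sim_config(time_grid_h = c(3, 6, 12)), "start at 0")
  expect_error(sim_config(time_grid_h = c(0, 12, 6)), "increasing")
  expect_error(sim_config(replicates = 0), "replicates")
  expect_error(sim_config(outlier_rate = 1.5), "outlier_rate")
})

test_that("spot tables have the printed-slide geometry", {
  st <- gen_spot_table(sim_config(seed = 4))
  # 12 conditions x 5 time points x 8 lines x 4 replicates + 80 controls
  expect_equal(nrow(st$spots), 2000L)
  expect_equal(sum(st$spots$is_control), 80L)
  expect_true(all(st$spots$intensity > 0))

  # every generated course carries exactly one ground-truth class
  expect_equal(nrow(st$truth$class_by_course), 12 * 8)
  expect_setequal(unique(st$truth$class_by_course$class),
                  intersect(kinetic_classes(),
                            st$truth$class_by_course$class))
})

test_that("spot generation is seed-deterministic and exact when noiseless", {
  a <- gen_spot_table(sim_config(seed = 9))
  b <- gen_spot_table(sim_config(seed = 9))
  expect_identical(a, b)
  c <- gen_spot_table(sim_config(seed = 10))
  expect_false(identical(a$spots$intensity, c$spots$intensity))

  quiet <- gen_spot_table(sim_config(seed = 2, noise_sd_log2 = 0,
                                     outlier_rate = 0))
  by_sample <- split(quiet$spots$intensity[!quiet$spots$is_control],
                     with(quiet$spots[!quiet$spots$is_control, ],
                          paste(antibody, cell_line, condition, time_h)))
  expect_true(all(vapply(by_sample,
                         function(v) diff(range(v)) == 0, logical(1))))
})

test_that("time-course archetypes respect their peak windows", {
  grid <- c(0, 3, 6, 12, 24)
  expect_equal(archetype_curve("none", grid), rep(0, 5))
  expect_lte(grid[which.max(archetype_curve("early", grid))], 6)
  peak_int <- grid[which.max(archetype_curve("intermediate", grid))]
  expect_true(peak_int > 6 && peak_int <= 12)
  expect_gt(grid[which.max(archetype_curve("late", grid))], 12)

  tc <- gen_timecourses(sim_config(seed = 3, n_antibodies = 4,
                                   class_mix = c(early = 1),
                                   noise_sd_log2 = 0))
  peaks <- tapply(seq_len(nrow(tc$courses)), tc$courses$course_id,
                  function(i) {
    tc$courses$time_h[i][which.max(abs(tc$courses$log2fc[i]))]
  })
  expect_true(all(peaks <= 6))

  flat <- gen_timecourses(sim_config(seed = 3, n_antibodies = 2,
                                     class_mix = c(none = 1),
                                     noise_sd_log2 = 0))
  expect_true(all(flat$courses$log2fc == 0))
})

test_that("course count is series x antibodies and draws are reproducible", {
  cfg <- sim_config(seed = 8, n_antibodies = 7)
  tc <- gen_timecourses(cfg)
  expect_equal(length(unique(tc$courses$course_id)), 96 * 7)
  expect_true(all(tc$courses$log2fc[tc$courses$time_h == 0] == 0))
  expect_identical(tc, gen_timecourses(cfg))
})

test_that("class fractions converge to the configured mix", {
  mix <- c(early = 0.3, intermediate = 0.2, late = 0.1, none = 0.4)
  cfg <- sim_config(seed = 21, n_antibodies = 30, class_mix = mix)
  tc <- gen_timecourses(cfg)
  n <- nrow(tc$truth$class_by_course)
  obs <- table(tc$truth$class_by_course$class)[names(mix)] / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(obs - mix) <= 3 * se))
})

test_that("dose-response generator hits its midpoint and round-trips", {
  doses <- 10^seq(-2, 2, by = 1)
  pr <- gen_dose_response(1, doses, noise_sd = 0)
  expect_equal(pr$viability_pct[doses == 1], 50)
  expect_identical(gen_dose_response(2, doses, noise_sd = 3, seed = 5),
                   gen_dose_response(2, doses, noise_sd = 3, seed = 5))
  for (g in c(0.05, 0.7, 13)) {
    grid <- sort(c(doses, g))
    rec <- compute_gi50(grid, gen_dose_response(g, grid)$viability_pct)
    expect_equal(rec$censored, "none")
    expect_lt(abs(rec$gi50 - g) / g, 1e-6)
  }
  expect_error(gen_dose_response(1, c(1, 1, 2)), "increasing")
})

test_that("CNV generator confines planted losses to the designated group", {
  sim <- gen_cnv_profiles(8, 200,
                          planted_region = list(start = 51, end = 80),
                          group_labels = c(rep(TRUE, 5), rep(FALSE, 3)),
                          background_rate = 0, seed = 6)
  for (cl in names(sim$profiles)) {
    pr <- sim$profiles[[cl]]
    losses <- pr$start[pr$copy_number < 2]
    if (sim$truth$group[[cl]]) {
      expect_setequal(losses, 51:80)
    } else {
      expect_length(losses, 0)
    }
  }
  expect_identical(sim, gen_cnv_profiles(
    8, 200, planted_region = list(start = 51, end = 80),
    group_labels = c(rep(TRUE, 5), rep(FALSE, 3)),
    background_rate = 0, seed = 6))
})

test_that("cohort generator is deterministic with sane structure", {
  sim <- gen_cohort(300, seed = 12)
  expect_identical(sim, gen_cohort(300, seed = 12))
  co <- sim$cohort
  expect_true(all(co$time_months > 0))
  expect_true(all(co$event %in% 0:1))
  expect_setequal(unique(co$arm), c("surgery", "S-1"))
  expect_setequal(unique(co$stratum), c("TLC-", "TLC+"))
  expect_true(all(co$PDL1 %in% 0:1))
})
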