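test_that("reader accepts a minimal well-formed cohort and rejects malformed ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual_id,age,alive,stage,eggs_laid,kills_egg,kills_immature,kills_adult",
    "f1,0,1,egg,0,0,0,0",
    "f1,1,1,larva,0,1,0,0",
    "f1,2,0,larva,0,0,0,0"
  ), path)
  co <- read_cohort(path, "demo")
  expect_s3_class(co, "cohort_table")
  expect_identical(attr(co, "n_individuals"), 1L)
  expect_identical(attr(co, "treatment"), "demo")

  # record after a death row
  writeLines(c(
    "individual_id,age,alive,stage,eggs_laid,kills_egg,kills_immature,kills_adult",
    "f1,0,1,egg,0,0,0,0",
    "f1,1,0,egg,0,0,0,0",
    "f1,2,1,larva,0,1,0,0"
  ), path)
  expect_error(read_cohort(path, "demo"), "after the death row")

  # missing column
  writeLines(c(
    "individual_id,age,alive,stage,eggs_laid,kills_egg,kills_immature",
    "f1,0,1,egg,0,0,0"
  ), path)
  expect_error(read_cohort(path, "demo"), "kills_adult")

  # non-numeric cell names the line
  writeLines(c(
    "individual_id,age,alive,stage,eggs_laid,kills_egg,kills_immature,kills_adult",
    "f1,0,1,egg,0,0,0,0",
    "f1,one,1,egg,0,0,0,0"
  ), path)
  expect_error(read_cohort(path, "demo"), "line 3")
})

test_that("cohort validation enforces the observation-protocol invariants", {
  base <- data.frame(
    individual_id = "f1", age = 0:2, alive = c(TRUE, TRUE, FALSE),
    stage = c("egg", "larva", "larva"), eggs_laid = 0L,
    kills_egg = c(0L, 2L, 0L), kills_immature = 0L, kills_adult = 0L
  )
  expect_s3_class(cohort_table(base, "t"), "cohort_table")

  gap <- base; gap$age <- c(0L, 2L, 3L)
  expect_error(cohort_table(gap, "t"), "gaps")

  regress <- base; regress$stage <- c("larva", "egg", "egg")
  expect_error(cohort_table(regress, "t"), "regresses")

  dead_counts <- base; dead_counts$kills_egg[3] <- 1L
  expect_error(cohort_table(dead_counts, "t"), "death row")

  neg <- base; neg$kills_immature[1] <- -1L
  expect_error(cohort_table(neg, "t"), "negative counts")

  censored <- base[base$alive, ]
  expect_warning(cohort_table(censored, "t"), "censored")
})

test_that("write_cohort / read_cohort round-trips a simulated cohort exactly", {
  cfg <- preset_configs()$Ld
  co <- simulate_cohort(cfg, n_females = 15, seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, attr(co, "treatment"))
  expect_identical(as.data.frame(back), as.data.frame(co))
  expect_identical(attr(back, "n_individuals"), attr(co, "n_individuals"))
})

test_that("life schedule reproduces hand-computed survival and kill means", {
  # one dies after age 1 (alive 0-1), the other alive 0-2
  co <- toy_cohort(list(c(0L, 2L), c(0L, 2L, 4L)))
  sched <- build_life_schedule(co)
  expect_equal(sched$lx, c(1, 1, 0.5))
  # kx is the mean over individuals alive at each age
  expect_equal(sched$kx, c(0, 2, 4))

  solo <- toy_cohort(list(c(0L, 2L, 4L)))
  expect_equal(build_life_schedule(solo)$kx, c(0, 2, 4))
})

test_that("schedule invariants hold on simulated cohorts", {
  cfg <- preset_configs()$Gd
  for (seed in c(11, 12, 13)) {
    co <- simulate_cohort(cfg, n_females = 20, seed = seed)
    sched <- build_life_schedule(co)
    expect_equal(sched$lx[1], 1)
    expect_true(all(diff(sched$lx) <= 1e-12))
    expect_equal(sched$kx, sched$kx_egg + sched$kx_immature + sched$kx_adult)
    # conservation: sum lx*kx equals the K0 the demography module reports
    expect_equal(sum(sched$lx * sched$kx), net_rates(sched)$K0, tolerance = 1e-12)
  }
})

test_that("kx estimates recover a configured constant kill mean without mortality", {
  cfg <- simulation_config(
    period_kill_means = c(5, 5, 5), late_skew = 0.2, kill_start_age = 0,
    juvenile_survival = 1, adult_hazard = 0, residual_life_mean = 10,
    max_age = 60
  )
  co <- simulate_cohort(cfg, n_females = 300, seed = 5)
  sched <- build_life_schedule(co)
  adult_ages <- sched$x >= 10 & sched$x <= 29
  # law of large numbers: Poisson(5) daily, 300 females x 20 days
  expect_equal(mean(sched$kx[adult_ages]), 5, tolerance = 0.05)
})

test_that("period summaries match closed forms on toy cohorts", {
  part <- period_partition(9, 29)
  solo <- toy_cohort(list(rep(2L, 10)))
  ps <- period_summary(solo, part)
  row1 <- ps[ps$period == "0-9" & ps$variable == "kills", ]
  expect_equal(row1$daily_mean, 2)
  expect_equal(row1$daily_sd, 0)
  expect_equal(row1$total_mean, 20)

  # two individuals with period means a = 1 and b = 3:
  # mean (a+b)/2 = 2, SD = |a-b|/sqrt(2)
  duo <- toy_cohort(list(rep(1L, 10), rep(3L, 10)))
  row2 <- period_summary(duo, part)
  row2 <- row2[row2$period == "0-9" & row2$variable == "kills", ]
  expect_equal(row2$daily_mean, 2)
  expect_equal(row2$daily_sd, 2 / sqrt(2))
  expect_equal(row2$daily_se, 2 / sqrt(2) / sqrt(2))
})

test_that("periods with no survivors are flagged undefined, not zero", {
  co <- toy_cohort(list(rep(1L, 5), rep(1L, 6)))  # all dead before age 10
  ps <- period_summary(co, period_partition(9, 29))
  late <- ps[ps$period != "0-9", ]
  expect_true(all(!late$defined))
  expect_true(all(is.na(late$daily_mean)))
})

test_that("period summaries recover the configured treatment means", {
  # periods 2 and 3 have constant daily means; per-individual daily means
  # are unbiased for them regardless of when a female dies
  cfg <- preset_configs()$Ld
  co <- simulate_cohort(cfg, n_females = 15, seed = 2024)
  ps <- period_summary(co)
  kills <- ps[ps$variable == "kills", ]
  expect_equal(kills$daily_mean[2], 11.64, tolerance = 3 * 1.25 / sqrt(15) / 11.64)
  expect_equal(kills$daily_mean[3], 8.29, tolerance = 3 * 1.01 / sqrt(15) / 8.29)
  # period 1 has age-varying means, so early juvenile deaths bias the
  # daily mean low; under full juvenile survival the configured period
  # mean is recovered
  cfg1 <- simulation_config(period_kill_means = c(2.59, 11.64, 8.29),
                            juvenile_survival = 1)
  co1 <- simulate_cohort(cfg1, n_females = 200, seed = 2025)
  ps1 <- period_summary(co1)
  expect_equal(ps1[ps1$variable == "kills", "daily_mean"][1], 2.59,
               tolerance = 0.05)
})

test_that("life-table CSV export writes the documented columns", {
  co <- toy_cohort(list(c(0L, 2L), c(0L, 2L, 4L)))
  sched <- build_life_schedule(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_schedule(sched, path)
  out <- read.csv(path)
  expect_named(out, c("x", "lx", "mx", "kx", "kx_egg", "kx_immature", "kx_adult"))
  expect_equal(out$lx, sched$lx)
})
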