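# cheap conduction-mode configuration for schedule sweeps
sweep_config <- function(nr = 12, nz = 24, dt = 4) {
  solver_config(quiet_mesh(nr = nr, nz = nz), dt = dt, mode = "conduction")
}

test_that("a schedule with no hold above 100 degC cannot meet the target", {
  rep <- evaluate_schedule(parse_schedule("5-10-5/95"), sweep_config(),
                           lethality_config(target_F = 4.5))
  expect_false(rep$meets_target)
  expect_lt(rep$F_min, 4.5)
  expect_equal(rep$oz_fraction, 0)
})

test_that("lengthening a hold never decreases F_min or the overheated volume", {
  cfg <- sweep_config()
  reps <- lapply(c("10-20-5/121", "10-40-5/121", "10-60-5/121"),
                 function(s) evaluate_schedule(parse_schedule(s), cfg))
  fmin <- vapply(reps, `[[`, numeric(1), "F_min")
  fmax <- vapply(reps, `[[`, numeric(1), "F_max")
  oz <- vapply(reps, `[[`, numeric(1), "oz_fraction")
  expect_true(all(diff(fmin) >= 0))
  expect_true(all(diff(fmax) >= 0))
  expect_true(all(diff(oz) >= 0))
})

test_that("raising the hold temperature never decreases F_min or F_max", {
  cfg <- sweep_config()
  lo <- evaluate_schedule(parse_schedule("10-40-5/111"), cfg)
  hi <- evaluate_schedule(parse_schedule("10-40-5/121"), cfg)
  expect_gte(hi$F_min, lo$F_min)
  expect_gte(hi$F_max, lo$F_max)
})

test_that("F_max grows linearly with hold time at a fixed retort temperature", {
  cfg <- sweep_config()
  holds <- c(20, 40, 60, 80)
  fmax <- vapply(holds, function(h) {
    evaluate_schedule(parse_schedule(sprintf("10-%d-5/121", h)), cfg)$F_max
  }, numeric(1))
  r2 <- summary(lm(fmax ~ holds))$r.squared
  expect_gt(r2, 0.99)
})

test_that("low-temperature sterilization narrows the F spread at matched F_min", {
  cfg <- sweep_config()
  ref121 <- evaluate_schedule(parse_schedule("10-30-5/121"), cfg)
  cands <- lapply(c(120, 180, 240), function(h)
    evaluate_schedule(parse_schedule(sprintf("10-%d-5/110", h)), cfg))
  fmins <- vapply(cands, `[[`, numeric(1), "F_min")
  best <- cands[[which.min(abs(fmins - ref121$F_min))]]
  spread <- function(r) (r$F_max - r$F_min) / r$F_max
  expect_lt(spread(best), spread(ref121))
})

test_that("schedule comparison computes reductions and equivalence", {
  cfg <- sweep_config()
  a <- evaluate_schedule(parse_schedule("10-60-5/121"), cfg)
  b <- evaluate_schedule(parse_schedule("10-40-5/121"), cfg)
  cmp <- compare_schedules(a, b)
  expect_equal(cmp$oz_reduction_percent,
               100 * (1 - b$oz_fraction / a$oz_fraction))
  expect_equal(cmp$F_min_difference, b$F_min - a$F_min)
  expect_equal(cmp$time_penalty, b$total_process_time - a$total_process_time)
  # identity comparison
  same <- compare_schedules(a, a)
  expect_equal(same$oz_reduction_percent, 0)
  expect_equal(same$F_min_difference, 0)
  expect_true(same$equivalent_lethality)
  # candidate with zero overheated volume reduces by 100 %
  z <- b; z$oz_fraction <- 0
  expect_equal(compare_schedules(a, z)$oz_reduction_percent, 100)
  # mismatched geometry is rejected
  other <- evaluate_schedule(parse_schedule("10-40-5/121"),
                             sweep_config(nr = 16, nz = 24))
  expect_error(compare_schedules(a, other), "geometries|meshes")
})

test_that("grid search ranks feasible schedules by quality then time", {
  cfg <- sweep_config(nr = 8, nz = 16, dt = 5)
  rk <- grid_search_schedules(hold_temps = c(115, 121), hold_times = c(60, 120),
                              stages = 1, solver_config = cfg,
                              leth_config = lethality_config(target_F = 0.03),
                              come_up_min = 5, cool_min = 5)
  expect_s3_class(rk, "schedule_ranking")
  expect_true(nrow(rk$summary) >= 1)
  expect_true(all(rk$summary$F_min >= 0.03))
  expect_true(!is.unsorted(rk$summary$oz_percent))
  # all-infeasible set warns and returns an empty ranking
  expect_warning(
    rk0 <- grid_search_schedules(hold_temps = 101, hold_times = 5, stages = 1,
                                 solver_config = cfg,
                                 leth_config = lethality_config(target_F = 50),
                                 come_up_min = 5, cool_min = 5),
    "no candidate")
  expect_identical(nrow(rk0$summary), 0L)
  # two-stage candidates pair hotter-then-cooler holds
  expect_error(grid_search_schedules(hold_temps = seq(100, 130), hold_times = 1:20,
                                     stages = 1, solver_config = cfg),
               "budget")
})

test_that("the two-stage redesign beats the single-stage original on quality", {
  cfg <- sweep_config(nr = 12, nz = 24, dt = 4)
  leth <- lethality_config(target_F = 2.5)
  orig <- evaluate_schedule(parse_schedule("10-86-24/121"), cfg, leth)
  adj <- evaluate_schedule(parse_schedule("10-65-48-14/118-110"), cfg, leth)
  expect_true(orig$meets_target && adj$meets_target)
  expect_lt(adj$oz_fraction, orig$oz_fraction)
  cmp <- compare_schedules(orig, adj)
  expect_gt(cmp$oz_reduction_percent, 50)
})
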