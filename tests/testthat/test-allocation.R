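test_that("target-range membership uses inclusive bounds", {
  expect_true(is_restored(95, 105))
  expect_false(is_restored(95, 90))   # HR inside, SBP outside
  expect_false(is_restored(120, 105))
  expect_true(is_restored(100, 100))  # boundary included
  expect_equal(is_restored(c(95, 95, 101), c(105, 99, 105)),
               c(TRUE, FALSE, FALSE))
})

test_that("ground-truth needs equal a brute-force scan of stored endpoints", {
  coh <- mini_cohort()
  for (cs in coh$casualties) {
    nd <- oracle_needs(cs)
    restored <- vapply(1:4, function(o) {
      v <- vitals_at(cs, o, cs$times$t3)
      is_restored(v["hr"], v["sbp"])
    }, logical(1))
    units <- c(0, 1, 1, 2)
    if (!any(restored)) {
      expect_true(is.na(nd$units))
    } else {
      expect_equal(nd$units, min(units[restored]))
      expect_true(restored[nd$option])
      if (nd$units == 1 && restored[3]) expect_equal(nd$option, 3L)
    }
  }
  broken <- coh$casualties[[1]]
  broken$trajectories[[2]] <- NULL
  expect_error(oracle_needs(broken), "missing")
})

test_that("oracle allocation follows the greedy priority rule exactly", {
  stub <- make_needs_profile(c(0, 1, 1, 2))
  restored <- vapply(0:4, function(b) sum(oracle_allocate(stub, b)$restored),
                     numeric(1))
  expect_equal(restored, c(1, 2, 3, 3, 4))  # hand enumeration
  d3 <- oracle_allocate(stub, 3)
  expect_equal(d3$units_used, c(0L, 1L, 1L, 0L))  # stranded unit not given
  # unrestorable casualties never receive fluid
  none <- make_needs_profile(c(NA, NA, NA))
  for (b in 0:6) {
    expect_equal(sum(oracle_allocate(none, b)$units_used), 0)
  }
  # restored count is non-decreasing in budget on a mixed profile
  stub2 <- make_needs_profile(c(2, 0, 1, NA, 2, 1, 1, 0))
  r <- vapply(0:10, function(b) sum(oracle_allocate(stub2, b)$restored),
              numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("threshold-rule allocation traces the two-step protocol", {
  # everyone outside range at t2: stage 1 consumes min(budget, n) units
  stub <- make_needs_profile(c(1, 1, 1, 1))
  for (b in c(0, 2, 4, 6)) {
    dec <- vampire_allocate(stub, b)
    first_units <- sum(dec$option %in% c(3, 4))
    expect_equal(first_units, min(b, 4))
  }
  # a casualty healthy mid-course after 1 unit gets no second unit
  one <- make_needs_profile(1)
  expect_equal(vampire_allocate(one, 5)$units_used, 1L)
  # a casualty still outside mid-course gets the second unit (cap 2)
  two <- make_needs_profile(2)
  expect_equal(vampire_allocate(two, 5)$units_used, 2L)
  # saturation: beyond 2 units per casualty nothing changes
  stub2 <- make_needs_profile(c(2, 2, 1, NA))
  d_sat <- vampire_allocate(stub2, 2 * length(stub2))
  d_more <- vampire_allocate(stub2, 2 * length(stub2) + 5)
  expect_identical(d_sat, d_more)
})

test_that("a perfect predictor collapses the AI allocator onto the oracle", {
  stub <- make_needs_profile(c(0, 1, 2, NA, 1, 0, 2, 1))
  for (b in 0:10) {
    da <- ai_allocate(stub, b, predictor = perfect_predictor())
    do <- oracle_allocate(stub, b)
    expect_identical(da$option, do$option)
    expect_identical(da$units_used, do$units_used)
    expect_identical(da$restored, do$restored)
  }
  coh <- mini_cohort()
  for (b in c(0, 3, 7, 20)) {
    da <- ai_allocate(coh$casualties, b, predictor = perfect_predictor())
    do <- oracle_allocate(coh$casualties, b)
    expect_identical(da$units_used, do$units_used)
    expect_identical(da$restored, do$restored)
  }
})

test_that("zero budget makes all three policies identical", {
  coh <- mini_cohort()
  pd <- tiny_predictor()
  do <- oracle_allocate(coh$casualties, 0)
  dv <- vampire_allocate(coh$casualties, 0)
  da <- ai_allocate(coh$casualties, 0, predictor = pd)
  expect_identical(do$restored, dv$restored)
  expect_identical(do$restored, da$restored)
  expect_equal(sum(do$units_used) + sum(dv$units_used) + sum(da$units_used),
               0)
})

test_that("oracle dominates both policies at every budget", {
  coh <- mini_cohort()
  pd <- tiny_predictor()
  fc <- ai_forecast_table(coh$casualties, pd)
  for (b in 0:12) {
    n_o <- sum(oracle_allocate(coh$casualties, b)$restored)
    n_a <- sum(ai_allocate(coh$casualties, b, forecasts = fc)$restored)
    n_v <- sum(vampire_allocate(coh$casualties, b)$restored)
    expect_gte(n_o, n_a)
    expect_gte(n_o, n_v)
  }
  # budget feasibility and vampire monotonicity over the same sweep
  units_v <- vapply(0:12, function(b) {
    sum(vampire_allocate(coh$casualties, b)$units_used)
  }, numeric(1))
  expect_true(all(units_v <= 0:12))
  restored_v <- vapply(0:12, function(b) {
    sum(vampire_allocate(coh$casualties, b)$restored)
  }, numeric(1))
  expect_true(all(diff(restored_v) >= 0))
})

test_that("excess fluid is counted per casualty against ground-truth need", {
  stub <- make_needs_profile(c(0, 1, 2, NA))
  needs <- lapply(stub, oracle_needs)
  dec <- oracle_allocate(stub, 10)
  expect_equal(excessive_use(dec, stub, needs), 0)  # oracle never wastes
  # force a wasteful decision set and recompute by hand
  dec$units_used <- c(1L, 2L, 2L, 2L)
  manual <- sum(pmax(0, dec$units_used - c(0, 1, 2, 0)))
  expect_equal(excessive_use(dec, stub, needs), manual)
  # threshold rule wastes on the 0-need casualty of the standard stub
  dv <- vampire_allocate(stub, 10)
  expect_gte(excessive_use(dv, stub, needs), 1)
})

test_that("relative efficiency matches direct arithmetic and edge rules", {
  expect_equal(relative_efficiency(28, 20, 22, 32), (28 / 20) / (22 / 32),
               tolerance = 1e-12)
  expect_equal(relative_efficiency(28, 20, 22, 32), 2.036, tolerance = 1e-3)
  expect_equal(relative_efficiency(5, 4, 5, 4), 1)
  expect_true(is.na(relative_efficiency(5, 0, 5, 4)))
  expect_true(is.na(relative_efficiency(5, 4, 0, 4)))
  set.seed(30)
  for (i in 1:20) {
    n_a <- sample(0:30, 1); u_a <- sample(1:30, 1)
    n_v <- sample(1:30, 1); u_v <- sample(1:30, 1)
    expect_equal(relative_efficiency(n_a, u_a, n_v, u_v),
                 (n_a / u_a) / (n_v / u_v))
  }
})

test_that("budget sweeps produce coherent tidy results", {
  coh <- mini_cohort()
  sweep <- run_analysis2(coh, perfect_predictor(), budgets = 0:6)
  res <- sweep$results
  expect_setequal(unique(res$method), c("oracle", "ai", "vampire"))
  expect_equal(nrow(res), 3 * 5 * 7)
  expect_true(all(res$units_used <= res$budget))
  expect_true(all(res$restored <= 2))  # group size n_f/5 = 2
  # oracle excess is identically zero
  expect_true(all(res$excess[res$method == "oracle"] == 0))
  # perfect predictor: ai column equals oracle column
  expect_equal(res$restored[res$method == "ai"],
               res$restored[res$method == "oracle"])
  a3 <- run_analysis3(coh, perfect_predictor(), group_sizes = 2,
                      budgets = 0:4)
  expect_equal(a3$restored_ratio_mean[a3$budget == 0], 1)
  expect_equal(a3$R_mean[a3$budget == 0], 1)
  expect_error(run_analysis3(coh, perfect_predictor(), group_sizes = 3),
               "divide")
})
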