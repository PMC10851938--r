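test_that("zero perturbation is a fixed point of the dynamics", {
  p <- subject_params()
  tr <- simulate_vitals(p, sim_input(bleed_rate = 0, t1 = 0, horizon = 60))
  expect_true(tr$completed)
  expect_lt(max(abs(tr$hr - p$HR0)), 1e-9)
  expect_lt(max(abs(tr$sbp - p$SBP0)), 1e-9)
  expect_lt(max(abs(tr$volume - p$V0)), 1e-9)
})

# Independent cumulative-quadrature reconstruction of the volume path from
# the declared flows (left-Riemann at the integrator step).
volume_oracle <- function(params, input) {
  h <- input$step
  n <- input$horizon / h
  tg <- (0:(n - 1)) * h
  b <- ifelse(tg < input$t1 - 1e-12, input$bleed_rate,
              input$f_nc * input$bleed_rate)
  u <- hemotriage:::infusion_rate_at(input$infusion, tg) / 60
  V <- numeric(n + 1)
  V[1] <- params$V0
  for (k in 1:n) {
    V[k + 1] <- V[k] + h * (-b[k] + params$k_r * (params$V0 - V[k]) + u[k])
  }
  V[seq(1, n + 1, by = 1 / h)]
}

test_that("recorded volume matches quadrature of the recorded flows", {
  p <- subject_params()
  inf <- data.frame(start = c(25, 55), end = c(55, 85), rate = c(1.10, 1.10))
  inp <- sim_input(bleed_rate = 0.2, t1 = 10, f_nc = 0.3, infusion = inf,
                   horizon = 90)
  tr <- simulate_vitals(p, inp)
  expect_true(tr$completed)
  expect_lt(max(abs(tr$volume - volume_oracle(p, inp))), 1e-6)

  inp2 <- sim_input(bleed_rate = 0.2, t1 = 10, horizon = 90)
  tr2 <- simulate_vitals(p, inp2)
  expect_lt(max(abs(tr2$volume - volume_oracle(p, inp2))), 1e-6)
  # V(10) = V0 - 2 L + the refill accrued during the bleed
  expect_lt(abs(tr2$volume[11] - volume_oracle(p, inp2)[11]), 1e-6)
  expect_gt(tr2$volume[11], 3.0)
})

test_that("a sustained deficit drives HR and SBP to their piecewise-linear targets", {
  # deficit 0.4 held indefinitely (refill switched off by a negligible k_r)
  p <- subject_params(k_r = 1e-12)
  tr <- simulate_vitals(p, sim_input(bleed_rate = 0.2, t1 = 10,
                                     horizon = 400))
  n <- length(tr$hr)
  expect_equal(tr$hr[n], 75 + 250 * 0.4, tolerance = 1e-6)
  expect_equal(tr$sbp[n], 120 - 40 * 0.15 - 250 * 0.25, tolerance = 1e-6)
})

test_that("hemorrhage response is monotone during the bleed", {
  p <- subject_params(k_r = 1e-12)
  tr <- simulate_vitals(p, sim_input(bleed_rate = 0.15, t1 = 12,
                                     horizon = 30))
  bleed_idx <- which(tr$times <= 12)
  expect_true(all(diff(tr$hr[bleed_idx]) >= -1e-12))
  expect_true(all(diff(tr$sbp[bleed_idx]) <= 1e-12))
})

test_that("more fluid never harms: dominated schedules give dominated vitals", {
  set.seed(42)
  p_nom <- subject_params()
  for (i in 1:20) {
    spec <- sample_hemorrhage(1)
    t2 <- round(spec$T_b + runif(1, 10, 15))
    ref_rate <- runif(1, 0, 1.1)
    add_rate <- ref_rate + runif(1, 0, 1.1)
    ref <- simulate_vitals(p_nom, sim_input(
      spec$rate, spec$T_b,
      infusion = data.frame(start = t2, end = t2 + 60, rate = ref_rate),
      horizon = t2 + 60))
    more <- simulate_vitals(p_nom, sim_input(
      spec$rate, spec$T_b,
      infusion = data.frame(start = t2, end = t2 + 60, rate = add_rate),
      horizon = t2 + 60))
    expect_true(all(more$volume >= ref$volume - 1e-9))
    expect_true(all(more$hr <= ref$hr + 1e-9))
    expect_true(all(more$sbp >= ref$sbp - 1e-9))
  }
})

test_that("numeric failure marks the trajectory incomplete", {
  p <- subject_params()
  # bleed out the whole volume: V crosses zero before the horizon
  tr <- simulate_vitals(p, sim_input(bleed_rate = 0.21, t1 = 30,
                                     horizon = 40))
  expect_false(tr$completed)
  expect_true(anyNA(tr$volume))
  expect_length(tr$volume, 41)
})

test_that("oscillation detector separates relaxation from injected oscillation", {
  p <- subject_params()
  tr <- simulate_vitals(p, sim_input(bleed_rate = 0.15, t1 = 10,
                                     horizon = 90))
  expect_false(detect_oscillation(tr, settle = 10))

  osc <- tr
  osc$hr <- osc$hr + 10 * sin(osc$times / 3)
  expect_true(detect_oscillation(osc, settle = 10))

  short <- tr
  short$times <- short$times[1:5]; short$hr <- short$hr[1:5]
  attr(short, "t1") <- 10
  expect_error(detect_oscillation(short, settle = 10), "settle")
})

test_that("first-order surrogate never oscillates over seeded scenarios", {
  set.seed(7)
  p <- subject_params()
  specs <- sample_hemorrhage(100)
  for (i in 1:100) {
    opt <- sample(1:4, 1)
    times <- sample_event_times(specs$T_b[i])
    tr <- simulate_vitals(p, sim_input(
      specs$rate[i], specs$T_b[i],
      infusion = infusion_schedule(opt, times), horizon = times$t3))
    if (!tr$completed) next
    expect_false(tr$oscillatory)
  }
})

test_that("trajectories survive a CSV + sidecar round trip", {
  p <- subject_params()
  inp <- sim_input(bleed_rate = 0.1, t1 = 10, horizon = 30)
  tr <- simulate_vitals(p, inp)
  path <- file.path(tempdir(), "traj_roundtrip.csv")
  write_trajectory(tr, path, params = p, input = inp)
  back <- read_trajectory(path)
  expect_lt(max(abs(back$hr - tr$hr)), 1e-6)
  expect_lt(max(abs(back$volume - tr$volume)), 1e-6)
  expect_equal(back$completed, tr$completed)
  expect_equal(attr(back, "t1"), 10)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(sim_input(-0.1, 5, horizon = 10), "bleed_rate")
  expect_error(sim_input(0.1, 5, f_nc = 1.5, horizon = 10), "f_nc")
  expect_error(sim_input(0.1, 5, horizon = 10, step = 0.3), "step")
  bad <- data.frame(start = c(0, 5), end = c(10, 15), rate = c(1, 1))
  expect_error(sim_input(0.1, 5, infusion = bad, horizon = 20), "overlap")
})
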