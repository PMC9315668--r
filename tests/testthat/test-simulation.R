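test_that("the deterministic subsystem converges at fourth order in the step size", {
  # smooth configuration: no stimulus, channels frozen, so the RHS is C^inf
  # along the trajectory and the global error scales as dt^4
  run_dt <- function(dt) {
    simulate_bouton(wt_params, NULL,
                    t_end = 20, dt = dt, record_every = 0, seed = 1,
                    freeze_channels = TRUE,
                    stochastic_release = FALSE)$final_state
  }
  ref <- run_dt(0.00025)
  e1 <- max(abs(run_dt(0.004) - ref))
  e2 <- max(abs(run_dt(0.002) - ref))
  expect_gt(e1 / e2, 8)
})

test_that("simulations are bit-identical under a fixed seed and trial", {
  a <- simulate_bouton(wt_params, make_protocol("single", t0 = 20),
                       t_end = 60, seed = 42, trial = 3)
  b <- simulate_bouton(wt_params, make_protocol("single", t0 = 20),
                       t_end = 60, seed = 42, trial = 3)
  expect_identical(a$trace, b$trace)
  expect_identical(a$events, b$events)
  c <- simulate_bouton(wt_params, make_protocol("single", t0 = 20),
                       t_end = 60, seed = 42, trial = 4)
  expect_false(identical(a$trace$po_vgcc, c$trace$po_vgcc))
})

test_that("no stimulation means no action potentials", {
  s <- simulate_bouton(wt_params, NULL, t_end = 500, seed = 2,
                       record_every = 0)
  expect_length(s$ap_times, 0)
})

test_that("transient metrics integrate the response above baseline", {
  # flat trace: no peak to measure
  flat <- tibble::tibble(time = seq(0, 50, by = 0.1),
                         release_rate = 1e-5, ca_az = 0.05)
  win <- tibble::tibble(pulse = 1, start = 0, end = 50)
  expect_error(transient_metrics(flat, win), "peak")
  # synthetic bump: residual is a sub-interval of cumulative
  tt <- seq(0, 50, by = 0.1)
  tr <- tibble::tibble(time = tt,
                       release_rate = 1e-5 + exp(-((tt - 10) / 3)^2),
                       ca_az = 0.05 + 5 * exp(-((tt - 10) / 4)^2))
  tm <- transient_metrics(tr, win)
  expect_lte(tm$residual_ca, tm$cumulative_ca)
  expect_equal(tm$rise_time, 10, tolerance = 0.2)
  expect_gt(tm$decay_time, 0)
})

test_that("ca-clamp dose-response rises in amplitude and accelerates with the step", {
  cc <- run_ca_clamp(c(1, 3, 10, 30, 100), wt_params, t_end = 60)
  expect_true(all(diff(cc$dose$peak_rate) > 0))
  expect_true(all(diff(cc$dose$time_to_peak) <= 1e-9))
  # release transient decays back toward basal within tens of ms
  hi <- cc$profiles[cc$profiles$level == 100, ]
  pk <- which.max(hi$rate_total)
  expect_lt(hi$rate_total[nrow(hi)], 0.15 * hi$rate_total[pk])
  # zero clamp: spontaneous-only flat profile
  c0 <- release_ode(0, 0, 50, wt_params)
  expect_true(all(c0$rate_sync == 0))
  expect_true(all(abs(c0$rate_spont - c0$rate_spont[1]) /
                    c0$rate_spont[1] < 0.3))
})

test_that("glance and tidy summarize a simulation consistently", {
  s <- simulate_bouton(wt_params, make_protocol("single", t0 = 20),
                       t_end = 60, seed = 4)
  g <- glance(s)
  expect_equal(g$n_ap, 1)
  expect_equal(g$pr_total, sum(s$cum_release) / 8)
  long <- tidy(s, variables = c("V", "ca_az"))
  expect_setequal(unique(long$variable), c("V", "ca_az"))
  expect_equal(nrow(long), 2 * nrow(s$trace))
})

test_that("run_single_ap returns one finite summary row per cluster size", {
  res <- run_single_ap(wt_params, n_vgcc = c(20, 60), trials = 4, seed = 1,
                       t0 = 20)
  expect_equal(nrow(res), 2)
  expect_true(all(res$pr >= 0 & res$pr <= 1))
  expect_true(all(res$n_ap == 1))
  expect_true(all(is.finite(res$peak_rate)))
  expect_true(all(res$residual_ca <= res$cumulative_ca))
})
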