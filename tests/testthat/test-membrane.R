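test_that("gating rates evaluate their removable singularities by the analytic limits", {
  r <- hh_rates(c(-34, -30, -44))
  expect_equal(r$alpha_n[1], 0.1)   # 0.01 * 10
  expect_equal(r$alpha_m[2], 1.0)   # 0.1 * 10
  expect_equal(r$beta_n[3], 0.125)  # exponent zero at V = -44
  # continuity across the singular points
  expect_equal(hh_rates(-34 + 1e-7)$alpha_n, 0.1, tolerance = 1e-6)
  expect_equal(hh_rates(-30 - 1e-7)$alpha_m, 1.0, tolerance = 1e-6)
})

test_that("the membrane has a stable resting fixed point and spikes on demand", {
  s <- simulate_bouton(wt_params, NULL, t_end = 200, seed = 1,
                       freeze_channels = TRUE, stochastic_release = FALSE)
  expect_length(s$ap_times, 0)
  tr <- s$trace
  late <- tr$time > 100
  dv <- diff(tr$V[late]) / diff(tr$time[late])
  expect_lt(max(abs(dv)), 0.1) # mV/ms after relaxation
  expect_true(all(tr$n >= 0 & tr$n <= 1))
  expect_true(all(tr$h >= 0 & tr$h <= 1))
  # a single suprathreshold pulse elicits exactly one overshooting AP
  s1 <- simulate_bouton(wt_params, make_protocol("single", t0 = 50),
                        seed = 1, stochastic_release = FALSE)
  expect_length(s1$ap_times, 1)
  expect_gt(max(s1$trace$V), 0)
})

test_that("membrane_rhs reproduces the printed current balance", {
  out <- membrane_rhs(V = -60, n = 0.1, h = 0.8, Iapp = 0, ca_cyt = 1,
                      I_Ca = 0, params = wt_params)
  m <- wt_params$membrane
  # AHP saturation factor Ca/(1+Ca) = 0.5 at 1 uM
  r <- hh_rates(-60)
  IK_manual <- -(m$gK * 0.1^4 + m$gAHP * 0.5) * (-60 - m$E_K) -
    m$gKleak * (-60 - m$E_K)
  expect_equal(out$IK, IK_manual, tolerance = 1e-12)
  expect_equal(out$dn, m$phi * (r$alpha_n * 0.9 - r$beta_n * 0.1),
               tolerance = 1e-12)
})

test_that("stimulation protocols have the documented onset structure", {
  expect_equal(make_protocol("paired")$onsets, c(50, 90))
  tr <- make_protocol("train")
  expect_length(tr$onsets, 20)
  expect_equal(unique(diff(tr$onsets)), 50)
  expect_length(make_protocol("single")$onsets, 1)
  expect_error(make_protocol("paired", interval = -1), "positive")
})

test_that("each pulse evokes exactly one AP in all three protocols", {
  for (kind in c("single", "paired", "train")) {
    proto <- make_protocol(kind, t0 = 30)
    s <- simulate_bouton(wt_params, proto, seed = 2,
                         stochastic_release = FALSE, record_every = 0)
    expect_length(s$ap_times, length(proto$onsets))
  }
})
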