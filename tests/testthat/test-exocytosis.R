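test_that("sensor hazards and rates carry the printed constants", {
  occ <- matrix(0, 6, 3)
  occ[6, 1] <- 1 # one vesicle with a full synchronous sensor
  out <- sensor_rhs(occ, ca = 0, wt_params)
  expect_equal(out$rate_sync, 2.000008)
  expect_equal(out$rate_async, 0)
  occ2 <- matrix(0, 6, 3); occ2[1, 3] <- 1 # full asynchronous sensor
  out2 <- sensor_rhs(occ2, 0, wt_params)
  expect_equal(out2$rate_async, 0.025007 * 2.000008)
  occ3 <- matrix(0, 6, 3); occ3[1, 1] <- 1 # empty sensors
  out3 <- sensor_rhs(occ3, 0, wt_params)
  expect_equal(out3$rate_spont, 9e-6)
  # cooperativity-scaled unbinding from m = 2: 2 beta b
  occ4 <- matrix(0, 6, 3); occ4[3, 1] <- 1
  out4 <- sensor_rhs(occ4, 0, wt_params)
  expect_equal(out4$doccupancy[2, 1], 2 * 2.32 * 0.250007, tolerance = 1e-12)
  expect_equal(out4$doccupancy[2, 1], 1.160, tolerance = 1e-2)
})

test_that("pool kinetics follow mass action with the availability gate", {
  pools <- list(R = 100, U = 10, V = 2, W = 1, refractory = 0)
  d <- pool_rhs(pools, ca_cyt = 0.5, ca_az = 1, wt_params)
  r <- wt_params$release
  expect_equal(d$dR, r$kdemob * 10 - r$kmob * 0.5 * 100)
  # doubling kmob doubles the R->U contribution
  p2 <- unclass_modify(wt_params, "release", "kmob", 2 * r$kmob)
  d2 <- pool_rhs(pools, 0.5, 1, p2)
  expect_equal(d2$dR - d$dR, -r$kmob * 0.5 * 100)
  # zero Ca: only backward rates act
  d0 <- pool_rhs(pools, 0, 0, wt_params)
  expect_equal(d0$dR, r$kdemob * 10)
  expect_equal(d0$dW, -r$kdetach * 1)
  # two-state balance: V/U -> kpriming c / kunpr while sites are free
  c <- 0.8
  u_eq <- 1; v_eq <- r$kpriming * c / r$kunpr * u_eq
  d_eq <- pool_rhs(list(R = 0, U = u_eq, V = v_eq, W = 0, refractory = 0),
                   c, 0, wt_params)
  expect_equal(d_eq$dV + r$kattach * 0 * v_eq, 0, tolerance = 1e-12)
})

test_that("refractory sites recover at kRF with a 100 ms mean dwell", {
  expect_equal(1 / wt_params$release$kRF, 100)
  # empirical: release everything with a strong clamp, then watch recovery
  r <- release_stochastic(0.1, 80, 3000, wt_params, seed = 8,
                          record_every = 1000)
  expect_gt(nrow(r$events), 0)
  # trace and final state agree on the refractory count
  expect_equal(r$trace$refractory[nrow(r$trace)], r$n_refractory)
  # with no fusion events, sites never become refractory
  r0 <- release_stochastic(0, 0, 500, wt_params, seed = 1)
  expect_equal(nrow(r0$events), 0)
  expect_equal(max(r0$trace$refractory), 0)
})

test_that("vesicles are conserved exactly in stochastic mode and to tolerance in the ODE", {
  p <- wt_params
  tot0 <- p$pools$N_reserve + p$pools$N_sites
  r <- release_stochastic(5, 50, 500, p, seed = 12)
  expect_equal(r$vesicles_left + sum(r$cum_release), tot0)
  d <- release_ode(5, 50, 500, p)
  last <- d[nrow(d), ]
  total <- last$R + last$U + last$V + last$W +
    last$cum_spont + last$cum_sync + last$cum_async
  expect_equal(total, tot0, tolerance = 1e-6)
})

test_that("total release rate decomposes into the three modes", {
  d <- release_ode(2, 10, 200, wt_params)
  expect_equal(d$rate_total, d$rate_sync + d$rate_async + d$rate_spont,
               tolerance = 1e-12)
})

test_that("deterministic and stochastic release agree on a fixed Ca waveform", {
  # brief high-AZ-Ca pulse riding on a modest cytosolic level
  dt <- 0.001
  tt <- seq(0, 200 - dt, by = dt)
  az <- 0.05 + 60 * exp(-((tt - 20) / 1)^2) * (tt > 15)
  cyt <- 0.1 + 1.5 * exp(-(tt - 20) / 10) * (tt > 20)
  det <- release_ode(stats::approxfun(tt, cyt, rule = 2),
                     stats::approxfun(tt, az, rule = 2), 200, wt_params)
  exp_cum <- sum(unlist(det[nrow(det), c("cum_spont", "cum_sync", "cum_async")]))
  trials <- 200
  cum <- vapply(seq_len(trials), function(tr) {
    sum(release_stochastic(cyt, az, 200, wt_params, seed = 77, trial = tr,
                           record_every = 0)$cum_release)
  }, numeric(1))
  se <- stats::sd(cum) / sqrt(trials)
  expect_lt(abs(mean(cum) - exp_cum), 3 * se + 0.02)
  # synchronous dominates asynchronous for a brief AZ pulse
  expect_gt(det$cum_sync[nrow(det)], det$cum_async[nrow(det)])
})

test_that("resting spontaneous release sits in the reported window", {
  rate <- steady_state_spontaneous_rate(0.1, wt_params)
  expect_gte(rate, 1e-5)
  expect_lte(rate, 1e-4)
  p0 <- unclass_modify(wt_params, "release", "gamma1", 1e-300)
  expect_lt(steady_state_spontaneous_rate(0.1, p0), 1e-12)
  # hazard is linear in the (0,0)-occupied RRP mass
  p_half <- unclass_modify(wt_params, "pools", "N_sites", 4L)
  expect_equal(steady_state_spontaneous_rate(0.1, p_half),
               steady_state_spontaneous_rate(0.1, wt_params) / 2,
               tolerance = 1e-12)
})

test_that("release probability is counted against the initial RRP", {
  ev <- tibble::tibble(time = c(1, 2, 30))
  expect_equal(release_probability(ev, c(0, 10), 8), 2 / 8)
  expect_equal(release_probability(ev[0, ], c(0, 10), 8), 0)
  expect_equal(release_probability(tibble::tibble(time = 1:8), c(0, 10), 8), 1)
  expect_error(release_probability(ev, c(0, 10), 0), "RRP")
})

test_that("refractoriness marks fused sites and recovers them at kRF", {
  sites <- tibble::tibble(site = 1:4,
                          status = factor(c("occupied", "occupied", "free",
                                            "refractory"),
                                          levels = c("free", "refractory",
                                                     "occupied")))
  # no fusion events, no time step: unchanged
  expect_identical(apply_refractoriness(sites, integer(0), wt_params), sites)
  out <- apply_refractoriness(sites, fused = 2L, wt_params)
  expect_equal(as.character(out$status[2]), "refractory")
  # kRF -> infinity: recovery is immediate
  p_inf <- unclass_modify(wt_params, "release", "kRF", 1e6)
  withr::with_seed(1, {
    out2 <- apply_refractoriness(out, integer(0), p_inf, dt = 1)
  })
  expect_false(any(out2$status == "refractory"))
  # empirical mean dwell ~ 1/kRF = 100 ms
  withr::with_seed(2, {
    dwell <- replicate(400, {
      t <- 0
      repeat {
        t <- t + 1
        s <- apply_refractoriness(tibble::tibble(status = "refractory"),
                                  integer(0), wt_params, dt = 1)
        if (s$status[1] == "free") break
      }
      t
    })
  })
  expect_equal(mean(dwell), 100, tolerance = 0.15)
})
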