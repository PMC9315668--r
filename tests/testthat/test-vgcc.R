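test_that("voltage-dependent rates pass through the printed 0 mV values", {
  r0 <- vgcc_rates(0, wt_params)
  expect_equal(unlist(r0[paste0("alpha", 1:4)]),
               c(alpha1 = 4.04, alpha2 = 6.70, alpha3 = 4.39, alpha4 = 17.33))
  expect_equal(unlist(r0[paste0("beta", 1:4)]),
               c(beta1 = 2.88, beta2 = 6.30, beta3 = 8.16, beta4 = 1.84))
  # one e-fold per slope factor
  rk <- vgcc_rates(wt_params$vgcc$k[1], wt_params)
  expect_equal(rk$alpha1, 4.04 * exp(1), tolerance = 1e-12)
  # positive over the physiological range
  rr <- vgcc_rates(seq(-100, 60, by = 5), wt_params)
  expect_true(all(as.matrix(rr[, -1]) > 0))
})

test_that("the channel is shut at rest and opens with depolarization", {
  expect_lt(vgcc_stationary(-70, wt_params)$p[5], 1e-4)
  expect_gt(vgcc_stationary(0, wt_params)$p[5], 0.3)
  expect_gt(vgcc_stationary(20, wt_params)$p[5],
            vgcc_stationary(-20, wt_params)$p[5])
})

test_that("cluster simulation matches the stationary oracle at clamped voltage", {
  tr <- simulate_vgcc_cluster(-20, 3000, wt_params, seed = 4)
  oracle_po <- vgcc_stationary_oracle(-20, wt_params)[5]
  emp <- mean(tr$open_fraction[tr$time > 5])
  n_eff <- 3000 / 5 * wt_params$vgcc$N_VGCC # rough decorrelated draws
  expect_equal(emp, oracle_po, tolerance = 5 * sqrt(oracle_po / n_eff) + 0.01)
  # near-zero opening during a 100 ms clamp at rest
  tr_rest <- simulate_vgcc_cluster(-70, 100, wt_params, seed = 4)
  expect_lt(mean(tr_rest$open_fraction), 0.005)
  # reproducibility
  tr2 <- simulate_vgcc_cluster(-20, 100, wt_params, seed = 9)
  tr3 <- simulate_vgcc_cluster(-20, 100, wt_params, seed = 9)
  expect_identical(tr2$n_open, tr3$n_open)
})

test_that("single-channel current is ohmic with the expected sign", {
  expect_equal(vgcc_current(-70, 0, wt_params), 0)
  expect_equal(vgcc_current(wt_params$vgcc$E_Ca, 1, wt_params), 0)
  expect_equal(vgcc_current(-70, 1, wt_params), -324) # 2.7 pS * (-120 mV)
  expect_error(vgcc_current(0, 1.5, wt_params), "\\[0, 1\\]")
})

test_that("calcium flux is positive inward, linear in channel count, and unit-consistent", {
  expect_equal(vgcc_flux(0, wt_params), 0)
  j1 <- vgcc_flux(-324, wt_params)
  expect_gt(j1, 0)
  p2 <- bouton_params("WT", "NC",
                      overrides = list(vgcc = list(N_VGCC = 70L)))
  expect_equal(vgcc_flux(-324, p2), 2 * j1, tolerance = 1e-12)
  # dimensional check: fA -> uM/ms via 1e-15/(z F V_eff) * 1e3
  g <- wt_params$vgcc
  density <- g$N_VGCC / (g$AZ_area * g$N_AZ)
  expected <- -(density * g$cluster_area * -324) * 1e-15 /
    (g$z * g$Faraday * g$V_eff) * 1e3
  expect_equal(j1, expected, tolerance = 1e-12)
})
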