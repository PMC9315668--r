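rest_state <- list(ca_cyt = 0.1, ca_iprn = 0.1, ca_az = 0.05,
                   ca_total = 56, ip3 = 0.1)

test_that("fluxes evaluate the printed forms at half-saturation and rest", {
  st <- rest_state
  st$ca_cyt <- wt_params$calcium$K_PMCA
  fl <- compute_fluxes(st, po_ipr = 0, j_vgcc = 0, wt_params)
  expect_equal(fl$JPMCA, wt_params$calcium$V_PMCA / 2) # 1.5975
  st$ca_cyt <- wt_params$calcium$K_SERCA
  fl <- compute_fluxes(st, 0, 0, wt_params)
  expect_equal(fl$JSERCA, wt_params$calcium$V_SERCA / 2) # 5
  # Jin at the reference IP3
  st <- rest_state
  fl <- compute_fluxes(st, 0, 0, wt_params)
  expect_equal(fl$Jin, 0.03115 + 0.2 * 0.1)
  # ER leak vanishes at zero gradient: choose ca_total so Ca_ER == Ca_cyt
  st2 <- rest_state
  st2$ca_total <- st2$ca_cyt / wt_params$calcium$delta2 + st2$ca_cyt -
    st2$ca_iprn / wt_params$calcium$delta1 + st2$ca_az
  expect_equal(ca_er(st2, wt_params), st2$ca_cyt, tolerance = 1e-12)
  expect_equal(compute_fluxes(st2, 0, 0, wt_params)$JER_leak, 0,
               tolerance = 1e-12)
  expect_error(compute_fluxes(list(ca_cyt = -1, ca_iprn = 0, ca_az = 0,
                                   ca_total = 1, ip3 = 0), 0, 0, wt_params),
               "negative")
})

test_that("coupling flux vanishes on the balance surface and differs between presets", {
  p_nc <- wt_params
  kbar <- p_nc$coupling$kbar
  ca_iprn <- 1
  ca_az <- sqrt(kbar) * ca_iprn
  expect_equal(coupling_flux(ca_az, ca_iprn, p_nc), 0, tolerance = 1e-12)
  expect_gt(coupling_flux(ca_az * 1.1, ca_iprn, p_nc), 0)
  expect_lt(coupling_flux(ca_az * 0.9, ca_iprn, p_nc), 0)
  # kbar = 0 limit: pure AZ -> IPRn transfer with the sign of Vc
  p0 <- unclass_modify(p_nc, "coupling", "kbar", 1e-12)
  expect_gt(coupling_flux(5, 100, p0), 0)
  p_hc <- bouton_params("WT", "HC")
  expect_false(isTRUE(all.equal(coupling_flux(5, 1, p_nc),
                                coupling_flux(5, 1, p_hc))))
})

test_that("compartment right-hand sides implement the printed bookkeeping", {
  fl <- tibble::tibble(Jin = 0, JIPR = 0, JIPR_diff = 0, JPMCA = 0,
                       JSERCA = 0, JER_leak = 0, JVGCC = 0, JVGCC_diff = 0,
                       Jcoupling = 0)
  d0 <- calcium_rhs(rest_state, fl, wt_params)
  expect_true(all(unlist(d0) == 0))
  # conservation by construction: plasma-membrane terms only enter ca_total
  fl2 <- fl; fl2$Jin <- 0.05; fl2$JPMCA <- 0.02; fl2$JVGCC <- 0.01
  d2 <- calcium_rhs(rest_state, fl2, wt_params)
  expect_equal(d2$dca_total, 0.05 - 0.02 + 0.01)
  # coupling moves Ca between microdomains without creating it:
  # delta-weighted contributions cancel
  fl3 <- fl; fl3$Jcoupling <- 0.7
  d3 <- calcium_rhs(rest_state, fl3, wt_params)
  k <- wt_params$calcium
  expect_equal(d3$dca_iprn, 0.7)
  expect_equal(d3$dca_az, -0.7 / k$delta1)
  # (1/delta1)-weighted contributions cancel: Ca is moved, not created
  expect_equal(d3$dca_iprn / k$delta1 + d3$dca_az, 0, tolerance = 1e-12)
  expect_equal(d3$dca_total, 0)
})

test_that("total calcium is conserved in a closed system", {
  s <- simulate_bouton(wt_params, NULL, t_end = 1000, seed = 3,
                       closed_system = TRUE, stochastic_release = FALSE)
  ca_tot <- s$trace$ca_total
  drift <- abs(ca_tot[length(ca_tot)] - ca_tot[1]) / ca_tot[1]
  expect_lt(drift, 1e-6)
})

test_that("IP3 metabolism has the printed structure and fixed points", {
  st <- list(ca_cyt = 0.1, ip3 = 0.1, plc = 0.5, g = 0.5)
  # at the PLC half-saturation Ca, production is half-maximal
  st2 <- st; st2$ca_cyt <- wt_params$ip3$K_PLC
  out <- ip3_rhs(st2, t = 0, wt_params)
  m <- wt_params$ip3
  q0 <- m$abeta_tonic
  VPLC <- m$V0 + m$VQ * q0^2 / (q0^2 + m$KQ^2)
  expect_equal(out$JPLC, VPLC * 0.5 / 2, tolerance = 1e-12)
  # PLC/G fixed points are stationary under the rhs
  fp <- plc_g_rest(wt_params)
  out2 <- ip3_rhs(list(ca_cyt = 0.1, ip3 = 0.1, plc = fp$plc, g = fp$g),
                  t = 0, wt_params)
  expect_equal(out2$dplc, 0, tolerance = 1e-15)
  expect_equal(out2$dg, 0, tolerance = 1e-15)
  # the resting IP3 equals the metabolism fixed point at the reference Ca
  fpv <- ip3_fixed_point(wt_params, 0.1)
  out3 <- ip3_rhs(list(ca_cyt = 0.1, ip3 = fpv, plc = fp$plc, g = fp$g),
                  t = 0, wt_params)
  expect_equal(out3$dip3, 0, tolerance = 1e-12)
  expect_equal(fpv, 0.1, tolerance = 1e-4) # WT calibration anchor
  expect_gt(ip3_fixed_point(ad_params, 0.1), 0.4) # AD rests elevated
})

test_that("the unstimulated model relaxes to a finite resting state", {
  s <- simulate_bouton(wt_params, NULL, t_end = 500, seed = 5)
  expect_true(all(is.finite(unlist(s$final_state))))
  tr <- s$trace
  late <- tr$ca_cyt[tr$time > 300]
  # time-averaged level in the basin of the printed resting values;
  # individual samples spike briefly during stochastic ER puffs
  expect_gt(mean(late), 0.05)
  expect_lt(mean(late), 0.3)
  expect_gt(min(late), 0)
  expect_true(all(tr$ca_er > 0))
  expect_true(all(tr$ca_cyt >= 0 & tr$ca_az >= 0 & tr$ca_iprn >= 0))
})

test_that("AD rests with more cytosolic calcium than WT at identical (non-)stimulation", {
  s_wt <- simulate_bouton(wt_params, NULL, t_end = 400, seed = 6)
  s_ad <- simulate_bouton(ad_hc_params, NULL, t_end = 400, seed = 6)
  expect_gt(mean(s_ad$trace$ca_cyt), mean(s_wt$trace$ca_cyt))
})
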