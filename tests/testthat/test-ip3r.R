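test_that("occupancy factors saturate and half-saturate as Hill functions", {
  g <- wt_params$ip3r
  # the shallow Hill exponent of the A factor (nA ~ 0.09) saturates only
  # at astronomically large IP3; use a value deep in every saturation
  occ_hi <- ip3r_occupancy(1e80, wt_params)
  expect_equal(occ_hi$KO, g$a1, tolerance = 1e-6)
  expect_equal(occ_hi$KA, g$a2, tolerance = 1e-6)
  expect_equal(occ_hi$KI, g$a3, tolerance = 1e-6)
  occ_half <- ip3r_occupancy(g$KOd, wt_params)
  expect_equal(occ_half$KO, g$a1 / 2, tolerance = 1e-12)
  # direct evaluation at a working concentration
  occ10 <- ip3r_occupancy(10, wt_params)
  by_hand <- g$a1 * 10^g$nO / (10^g$nO + g$KOd^g$nO)
  expect_equal(occ10$KO, by_hand, tolerance = 1e-10)
  expect_error(ip3r_occupancy(-1, wt_params), ">= 0")
})

test_that("transition rates follow the harmonic-composition forms", {
  # series composition of the two Ca-binding steps at ca = 1
  g <- wt_params$ip3r
  r <- ip3r_rates(1, 10, wt_params)
  expect_equal(r$kRA, 1 / (1 / g$j01 + 1 / g$j12), tolerance = 1e-12)
  expect_equal(r$kRA, 156.4, tolerance = 0.001) # harmonic-sum arithmetic
  # algebraic identities kAO*KA = kOA*KO = j22 on a random ligand grid
  set.seed(42)
  ca <- runif(20, 0.05, 5); ip3 <- runif(20, 0.1, 20)
  occ <- ip3r_occupancy(ip3, wt_params)
  rr <- ip3r_rates(ca, ip3, wt_params)
  expect_equal(rr$kAO * occ$KA, rep(g$j22, 20), tolerance = 1e-10)
  expect_equal(rr$kOA * occ$KO, rep(g$j22, 20), tolerance = 1e-10)
})

test_that("stationary distribution is a probability vector matching the generator null space", {
  set.seed(7)
  for (i in 1:10) {
    ca <- runif(1, 0.05, 3); ip3 <- runif(1, 0.1, 15)
    po <- ip3r_open_probability(ca, ip3, wt_params)
    pvec <- c(po$pR, po$pA, po$pO, po$pI)
    expect_true(all(pvec >= 0))
    expect_equal(sum(pvec), 1, tolerance = 1e-12)
    oracle <- ip3r_stationary_oracle(ca, ip3, wt_params)
    expect_equal(pvec, unname(oracle), tolerance = 1e-8)
  }
})

test_that("the AD receptor opens more than WT and opening grows with IP3", {
  grid <- tidyr::expand_grid(ca = c(0.05, 0.1, 0.25, 0.5, 1, 2),
                             ip3 = c(0.1, 0.3, 1, 3, 10))
  po_wt <- ip3r_open_probability(grid$ca, grid$ip3, wt_params)$po
  po_ad <- ip3r_open_probability(grid$ca, grid$ip3, ad_params)$po
  expect_true(all(po_ad >= po_wt))
  for (ca in c(0.05, 0.5, 2)) {
    po <- ip3r_open_probability(ca, c(0.1, 0.3, 1, 3, 10), wt_params)$po
    expect_true(all(diff(po) >= -1e-12))
  }
})

test_that("channel simulation is reproducible, respects the zero-Ca limit, and matches theory", {
  t1 <- simulate_ip3r(0.5, 5, 2000, wt_params, seed = 11)
  t2 <- simulate_ip3r(0.5, 5, 2000, wt_params, seed = 11)
  expect_identical(t1$state, t2$state)
  expect_identical(t1$enter, t2$enter)
  t0 <- simulate_ip3r(0, 5, 100, wt_params, seed = 3)
  expect_identical(levels(droplevels(t0$state)), "R")
  # long-run open fraction against the analytic stationary value
  tl <- simulate_ip3r(1, 10, 60000, wt_params, seed = 5)
  po_th <- ip3r_open_probability(1, 10, wt_params)$po
  se <- stats::sd(attr(tl, "batch_po")) / sqrt(length(attr(tl, "batch_po")))
  expect_lt(abs(attr(tl, "po_emp") - po_th), 4 * se + 0.005)
})

test_that("dwell-time statistics recover the closed-form mean open time", {
  traj <- simulate_ip3r(1, 10, 60000, wt_params, seed = 9)
  st <- dwell_time_stats(traj)
  r <- ip3r_rates(1, 10, wt_params)
  tau_o_th <- 1 / (r$kOA + r$kOI)
  expect_equal(st$tau_o, tau_o_th, tolerance = 4 / sqrt(st$n_openings))
  expect_gt(st$tau_c, st$tau_o) # mostly closed at these ligands
  # fully-open synthetic trajectory
  synth <- tibble::tibble(state = factor(c("O"), levels = c("R", "A", "O", "I")),
                          enter = 0, duration = 100)
  expect_error(dwell_time_stats(synth), "sojourn")
  no_open <- tibble::tibble(state = factor("R", levels = c("R", "A", "O", "I")),
                            enter = 0, duration = 100)
  expect_error(dwell_time_stats(no_open), "no openings")
})

test_that("AD gating lengthens openings and shortens closures at the reference ligands", {
  wt <- dwell_time_stats(simulate_ip3r(1, 10, 30000, wt_params, seed = 2))
  ad <- dwell_time_stats(simulate_ip3r(1, 10, 30000, ad_params, seed = 2))
  expect_gt(ad$tau_o, wt$tau_o)
  expect_lt(ad$tau_c, wt$tau_c)
  expect_gt(ad$po_emp, wt$po_emp)
})

test_that("cluster open fraction counts open channels", {
  expect_equal(cluster_open_fraction(factor(rep("R", 10),
                                            levels = c("R", "A", "O", "I"))), 0)
  st <- factor(c(rep("O", 3), rep("A", 7)), levels = c("R", "A", "O", "I"))
  expect_equal(cluster_open_fraction(st), 0.3)
  expect_equal(cluster_open_fraction(factor("O", levels = c("R", "A", "O", "I"))), 1)
  expect_error(cluster_open_fraction(character(0)), "empty")
})
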