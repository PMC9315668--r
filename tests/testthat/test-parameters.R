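test_that("presets carry the condition- and coupling-specific constants", {
  expect_equal(wt_params$ip3r$a1, 17.05043)
  expect_equal(ad_params$ip3r$a1, 1.108278e2)
  hc <- bouton_params("AD", "HC")
  expect_equal(hc$coupling[c("Vc", "kbar", "Kc")], list(Vc = 118, kbar = 15, Kc = 10))
  nc <- wt_params$coupling
  expect_equal(nc[c("kbar", "Kc")], list(kbar = 5, Kc = 20))
  # derived asynchronous fusion rate
  expect_equal(wt_params$release$a * wt_params$release$gamma2,
               0.025007 * 2.000008)
})

test_that("WT and AD presets differ only in the condition-dependent blocks", {
  groups <- setdiff(names(wt_params), c("condition", "ip3", "ip3r", "calcium"))
  for (g in groups) expect_identical(wt_params[[g]], ad_params[[g]])
  # within the gating block, exactly the fitted condition-dependent entries
  differing <- names(wt_params$ip3r)[vapply(names(wt_params$ip3r), function(f)
    !identical(wt_params$ip3r[[f]], ad_params$ip3r[[f]]), logical(1))]
  expect_setequal(differing, c("a1", "a3", "j22", "j23", "j45", "jt45"))
  # resting-state initials differ because the AD terminal rests elevated
  same_ca <- setdiff(names(wt_params$calcium),
                     c("ca_cyt0", "ca_iprn0", "ca_az0", "ca_total0", "ip3_0"))
  expect_identical(wt_params$calcium[same_ca], ad_params$calcium[same_ca])
  expect_gt(ad_params$calcium$ca_cyt0, wt_params$calcium$ca_cyt0)
  expect_gt(ad_params$calcium$ip3_0, wt_params$calcium$ip3_0)
})

test_that("invalid configurations are rejected with named violations", {
  expect_error(bouton_params("XX"), "unknown condition")
  expect_error(bouton_params("WT", "ZZ"), "unknown coupling")
  expect_error(bouton_params("WT", "NC",
                             overrides = list(release = list(kRF = -1))),
               "kRF")
  v <- validate_bouton_params(
    unclass_modify(wt_params, "calcium", "delta1", 0))
  expect_equal(nrow(v), 1)
  expect_match(v$field, "delta1")
  v2 <- validate_bouton_params(unclass_modify(wt_params, "release", "b", 1.5))
  expect_equal(nrow(v2), 1)
  expect_match(v2$rule, "cooperativity")
  expect_equal(nrow(validate_bouton_params(wt_params)), 0)
})

test_that("JSON serialization round-trips every numeric field exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  write_params_json(ad_hc_params, f)
  back <- read_params_json(f)
  tab_a <- param_table(ad_hc_params)
  tab_b <- param_table(back)
  expect_identical(tab_a$value, tab_b$value)
  expect_identical(back$condition, "AD")
  expect_identical(back$coupling_preset, "HC")
})

test_that("overrides replace single fields and reject unknown names", {
  p <- bouton_params("WT", "NC", overrides = list(vgcc = list(N_VGCC = 70L)))
  expect_equal(p$vgcc$N_VGCC, 70L)
  expect_equal(p$vgcc$g, wt_params$vgcc$g)
  expect_error(bouton_params("WT", "NC", overrides = list(vgcc = list(nope = 1))),
               "unknown parameter")
})
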