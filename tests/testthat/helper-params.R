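# shared fixtures: default parameter sets built once per test run
wt_params <- bouton_params("WT", "NC")
ad_params <- bouton_params("AD", "NC")
ad_hc_params <- bouton_params("AD", "HC")

# independent stationary-distribution oracle: build the explicit 4x4
# generator from a rate tibble and solve its null space
ip3r_stationary_oracle <- function(ca, ip3, params) {
  r <- ip3r_rates(ca, ip3, params)
  Q <- matrix(0, 4, 4, dimnames = list(c("R", "A", "O", "I"),
                                       c("R", "A", "O", "I")))
  Q["R", "A"] <- r$kRA; Q["A", "R"] <- r$kAR
  Q["A", "O"] <- r$kAO; Q["O", "A"] <- r$kOA
  Q["O", "I"] <- r$kOI; Q["I", "O"] <- r$kIO
  Q["R", "I"] <- r$kRI; Q["I", "R"] <- r$kIR
  diag(Q) <- -rowSums(Q)
  ns <- svd(t(Q))
  v <- abs(ns$v[, 4])
  v / sum(v)
}

# 5-state VGCC stationary oracle from the explicit generator
vgcc_stationary_oracle <- function(V, params) {
  r <- vgcc_rates(V, params)
  Q <- matrix(0, 5, 5)
  for (i in 1:4) {
    Q[i, i + 1] <- r[[paste0("alpha", i)]]
    Q[i + 1, i] <- r[[paste0("beta", i)]]
  }
  diag(Q) <- -rowSums(Q)
  ns <- svd(t(Q))
  v <- abs(ns$v[, 5])
  v / sum(v)
}

# tweak one field of a params object without triggering constructor
# validation (for exercising the validator directly)
unclass_modify <- function(p, group, field, value) {
  q <- unclass(p)
  q[[group]][[field]] <- value
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
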