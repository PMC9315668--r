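#' Build a validated parameter set for the bouton model
#'
#' Assembles every model constant — calcium fluxes and compartment
#' geometry, ER–active-zone coupling, IP3 metabolism, IP3-receptor
#' gating, Cav2.1 (VGCC) gating, membrane excitability, and the vesicle
#' release machinery — into one validated list, with the wild-type
#' (`"WT"`) or familial-AD (`"AD"`, 3xTg mouse fit) column selected for
#' the condition-dependent blocks and the normal- (`"NC"`) or
#' high-coupling (`"HC"`) preset for the ER–AZ transfer flux.
#'
#' Internal units are ms, uM and mV throughout.  Rate constants printed
#' by the source tables in "per microsecond" for the slow IP3/PLC/G
#' kinetics are interpreted as per second and stored in per millisecond
#' (see `$meta$unit_note`): IP3 must turn over on a timescale of
#' hundreds of milliseconds to act as a slow second messenger.
#'
#' @param condition `"WT"` or `"AD"`: selects the IP3-receptor gating
#'   and IP3-metabolism parameterization.
#' @param coupling `"NC"` (normal) or `"HC"` (high) ER–AZ coupling
#'   preset, standing in for normal vs. down-regulated Ca2+ buffering.
#' @param overrides named list of replacement values, addressed as
#'   `list(group = list(field = value))`, e.g.
#'   `list(vgcc = list(N_VGCC = 70))`.
#' @return An object of class `bouton_params`: a named list of parameter
#'   groups (`calcium`, `coupling`, `ip3`, `ip3r`, `vgcc`, `membrane`,
#'   `release`, `pools`, `numerics`, `meta`).
#' @examples
#' p <- bouton_params("AD", "HC")
#' p$coupling$kbar
#' p$ip3r$a1
#' @export
bouton_params <- function(condition = c("WT", "AD"),
                          coupling = c("NC", "HC"),
                          overrides = list()) {
  if (length(condition) == 1 && !condition %in% c("WT", "AD")) {
    stop("unknown condition: ", condition, " (expected WT or AD)", call. = FALSE)
  }
  if (length(coupling) == 1 && !coupling %in% c("NC", "HC")) {
    stop("unknown coupling: ", coupling, " (expected NC or HC)", call. = FALSE)
  }
  condition <- match.arg(condition)
  coupling <- match.arg(coupling)

  # sphere of volume 0.122 um^3: radius and surface, for the ICa/Area term
  v_bouton_um3 <- 0.122
  r_um <- (3 * v_bouton_um3 / (4 * pi))^(1 / 3)
  area_cm2 <- 4 * pi * r_um^2 * 1e-8

  p <- list(
    condition = condition,
    coupling_preset = coupling,

    calcium = list(
      Jleak_in   = 0.03115, # uM/ms, plasma-membrane leak influx
      Vleak_in   = 0.2,     # ms^-1, R/SOCC flux coefficient (x IP3)
      k_IPR_diff = 10,      # ms^-1, IP3R-microdomain -> cytosol diffusion
      k_VGCC_diff = 0.071,  # ms^-1, AZ-microdomain -> cytosol diffusion
      k_ER_leak  = 0.0022,  # ms^-1
      k_IPR      = 5,       # ms^-1, IP3R flux coefficient
      N_IPR      = 10L,     # channels in the IP3R cluster
      V_PMCA     = 3.195,   # uM/ms
      K_PMCA     = 0.5,     # uM
      n_P        = 2,
      V_SERCA    = 10,      # uM/ms
      K_SERCA    = 0.26,    # uM
      n_S        = 1.75,
      delta1     = 100,     # cytosol : IP3R-microdomain volume ratio
      delta2     = 10,      # cytosol : ER volume ratio
      delta3     = 60,      # cytosol : AZ-microdomain volume ratio
      # resting state (uM): set below to the relaxed resting state of the
      # selected condition/coupling (see rest_state_defaults)
      ca_cyt0    = 0.1,
      ca_iprn0   = 0.1,
      ca_az0     = 0.05,
      ca_total0  = 56,
      ip3_0      = 0.1,
      ca_ext     = 2000     # uM, extracellular Ca2+
    ),

    coupling = list(
      Vc   = 118, # uM/ms, max ER-AZ transfer
      kbar = if (coupling == "HC") 15 else 5,  # concentrating factor (dimensionless)
      Kc   = if (coupling == "HC") 10 else 20, # uM, half-maximal constant
      # the printed transfer flux has a subtractive denominator with a pole
      # at Ca_AZ = Kc; default is the singularity-free additive form used by
      # bidirectional SERCA-type models
      printed_denominator = FALSE,
      guard_band = 1e-3
    ),

    ip3 = ip3_metabolism_defaults(condition),
    ip3r = ip3r_gating_defaults(condition),

    vgcc = list(
      alpha0 = c(4.04, 6.70, 4.39, 17.33), # ms^-1 at 0 mV
      beta0  = c(2.88, 6.30, 8.16, 1.84),  # ms^-1 at 0 mV
      k      = c(49.14, 42.08, 55.31, 26.55), # mV slope factors
      g      = 2.7,      # pS single-channel conductance (calibration; not printed)
      E_Ca   = 50,       # mV reversal potential (calibration; not printed)
      N_VGCC = 35L,      # channels per cluster
      cluster_area = 0.001963, # um^2
      AZ_area = 0.04,    # um^2
      N_AZ    = 1.3,
      V_eff   = 4.2e-17,  # L; effective flux-conversion volume. The single
                          # calibration knob of the influx pathway: set to
                          # ~bouton volume / 2.9 so the wild-type synapse with
                          # a 35-channel cluster releases with probability
                          # ~0.14 on the first pulse of a 20 Hz train (the
                          # model's reference operating point)
      z       = 2,
      Faraday = 96485    # C/mol
    ),

    membrane = list(
      Cm      = 1,       # uF/cm^2
      gNa     = 120,     # mS/cm^2
      gK      = 36,
      gNaleak = 0.0175,
      gKleak  = 0.05,
      gClleak = 0.05,
      phi     = 5.0,
      gAHP    = 0.01,
      E_Na    = 55,      # mV (standard for the membrane formulation; not printed)
      E_K     = -90,
      E_Cl    = -75,     # places the leak balance below spike threshold
                         # (the terminal must be silent without stimulation)
      area_cm2 = area_cm2, # surface of the 0.122 um^3 spherical bouton
      V0      = -70      # mV, initial membrane potential
    ),

    release = list(
      kmob     = 5.0e-5,   # uM^-1 ms^-1, reserve -> docked
      kdemob   = 0.0022,   # ms^-1
      kpriming = 0.027990, # uM^-1 ms^-1 (acts on Ca_cyt)
      kunpr    = 0.005356, # ms^-1
      kattach  = 0.0015,   # uM^-1 ms^-1 (acts on Ca_AZ)
      kdetach  = 0.001158, # ms^-1
      kRF      = 0.01,     # ms^-1, release-site refractoriness recovery
      alpha    = 0.061200, # uM^-1 ms^-1, synchronous sensor association
      beta     = 2.32,     # ms^-1, synchronous sensor dissociation
      lambda   = 0.002933, # uM^-1 ms^-1, asynchronous sensor association
      delta    = 0.014829, # ms^-1, asynchronous sensor dissociation
      gamma1   = 9e-6,     # ms^-1, spontaneous fusion ((0,0) sensor state)
      gamma2   = 2.000008, # ms^-1, synchronous fusion (S sensor full, m = 5)
      a        = 0.025007, # gamma3 = a * gamma2
      b        = 0.250007  # unbinding cooperativity, in (0, 1]
    ),

    pools = list(
      N_sites   = 8L,   # release sites; initial RRP = V + W = N_sites
      N_reserve = 100L  # reserve-pool vesicles
    ),

    numerics = list(
      dt = 0.001,        # ms; hybrid integrator fixed step
      record_every = 10L # store every k-th step in traces
    ),

    meta = list(
      unit_note = paste(
        "k3k, k5p, kf_PLC, kb_PLC, kf_G, kb_G printed as 'us^-1' are",
        "interpreted as s^-1 and stored in ms^-1 (x 1e-3)."
      )
    )
  )

  # each condition rests at its own IP3 metabolic fixed point (the WT
  # fixed point equals the printed resting IP3 of 0.1 uM by calibration
  # of the tonic background; the AD column rests elevated), and
  # simulations start from the relaxed resting state of the selected
  # condition/coupling so that short protocols are not contaminated by a
  # long settling transient
  p$calcium$ip3_0 <- ip3_fixed_point(p, 0.1)
  rest <- rest_state_defaults(condition, coupling)
  p$calcium[names(rest)] <- rest

  p <- apply_overrides(p, overrides)
  class(p) <- "bouton_params"

  viol <- validate_bouton_params(p)
  if (nrow(viol) > 0) {
    stop("invalid parameter set:\n",
         paste0("  - ", viol$field, ": ", viol$rule, collapse = "\n"),
         call. = FALSE)
  }
  p
}

# condition-dependent IP3 metabolism block (PLC / G-protein / amyloid input).
# Rates printed "us^-1" stored as s^-1 -> ms^-1.
ip3_metabolism_defaults <- function(condition) {
  wt <- condition == "WT"
  list(
    V0     = if (wt) 0.15 else 0.19,    # uM, baseline PLC-mediated IP3 production
    VQ     = if (wt) 7.82 else 380,     # uM, amyloid influence on IP3 production
    KQ     = 0.0086,                    # ug/mL
    K_IP3k = if (wt) 0.6 else 1.6,      # uM, 3-kinase half-activation
    K_PLC  = if (wt) 0.01 else 0.016,   # uM, PLC sensitivity to Ca2+
    k3k    = (if (wt) 1.5 else 0.7) * 1e-3,    # ms^-1, IP3 phosphorylation
    k5p    = (if (wt) 0.01 else 0.005) * 1e-3, # ms^-1, IP3 dephosphorylation
    kf_PLC = (if (wt) 0.35 else 0.75) * 1e-3,  # ms^-1
    kb_PLC = (if (wt) 22 else 200) * 1e-3,     # ms^-1
    PLC_tot = 1,
    kf_G   = (if (wt) 0.33 else 0.047) * 1e-3, # ms^-1
    kb_G   = (if (wt) 2.17 else 4.7) * 1e-3,   # ms^-1
    delta_G = if (wt) 0.01 else 0.012,  # intrinsic G-protein activity
    VR     = if (wt) 7.4 else 10,       # maximal G-protein activation
    KR     = if (wt) 4467 else 2000,    # ug/mL
    G_tot  = 1,
    abeta  = 0,     # ug/mL, amyloid-beta pulse amplitude (0 = no transient)
    abeta_r = 0.001, # ms^-1, amyloid pulse decay
    abeta_t1 = 0,   # ms, amyloid pulse onset
    # Tonic agonist/amyloid background (ug/mL), identical in both
    # conditions.  Calibrated once so that the WT IP3 production-degradation
    # fixed point equals the printed resting IP3 of 0.1 uM; the AD column
    # then rests at its own elevated IP3, which is how the
    # condition-dependent production parameters (V0, VQ, KR, VR) express
    # the disease phenotype.  With a zero background the cascade is inert
    # and resting IP3 is not a fixed point of the metabolism equations.
    abeta_tonic = 105.1589
  )
}

# condition-dependent IP3R gating block (four-state model fit).
ip3r_gating_defaults <- function(condition) {
  wt <- condition == "WT"
  list(
    a1  = if (wt) 17.05043 else 1.108278e2,   # uM^-2
    nO  = 2.473407,
    KOd = 0.909078,                           # uM
    a2  = 18.49186,                           # uM^-2
    nA  = 0.093452,
    KAd = 1.955650,                           # uM
    a3  = if (wt) 2.340259e2 else 1.4041556e2, # uM^-5
    nI  = 56.84823,
    KId = 0.089938,                           # uM
    j01 = 3.031635e2,                         # uM^-1 ms^-1
    j12 = 3.230063e2,                         # uM^-2 ms^-1
    j22 = if (wt) 4.814111 else 5.3978052,    # uM^-2 ms^-1
    j23 = if (wt) 5.356155 else 2.0652269e3,  # uM^-3 ms^-1
    j45 = if (wt) 5.625616 else 5.4319289,    # uM^-5 ms^-1
    jt01 = 3.013284e2,                        # uM^-1 ms^-1
    jt45 = if (wt) 2.648741 else 8.512829e-8  # uM^-5 ms^-1
  )
}

apply_overrides <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("overrides must be a fully named list", call. = FALSE)
  }
  for (grp in names(overrides)) {
    if (!grp %in% names(p)) stop("unknown parameter group: ", grp, call. = FALSE)
    if (!is.list(overrides[[grp]])) { # top-level scalar (e.g. condition)
      p[[grp]] <- overrides[[grp]]
      next
    }
    for (fld in names(overrides[[grp]])) {
      if (!fld %in% names(p[[grp]])) {
        stop("unknown parameter: ", grp, "$", fld, call. = FALSE)
      }
      p[[grp]][[fld]] <- overrides[[grp]][[fld]]
    }
  }
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model constants: positivity
#' of rates, capacities and Hill exponents; volume ratios; the
#' cooperativity bound 0 < b <= 1; pool sizes; and tag validity.  This
#' is a reporting operation: it returns the violations rather than
#' throwing.
#'
#' @param p a `bouton_params` object (or plain list with the same shape).
#' @return A tibble with columns `field`, `rule`, `value`; zero rows iff
#'   the set is valid.
#' @export
validate_bouton_params <- function(p) {
  bad <- list()
  note <- function(field, rule, value) {
    bad[[length(bad) + 1]] <<- tibble::tibble(
      field = field, rule = rule,
      value = if (is.numeric(value) && length(value) == 1) value else NA_real_
    )
  }
  pos <- function(group, fields) {
    for (f in fields) {
      v <- p[[group]][[f]]
      if (is.null(v) || any(!is.finite(v)) || any(v <= 0)) {
        note(paste0(group, "$", f), "must be positive and finite", v)
      }
    }
  }

  if (!isTRUE(p$condition %in% c("WT", "AD"))) {
    note("condition", "must be WT or AD", NA)
  }
  if (!isTRUE(p$coupling_preset %in% c("NC", "HC"))) {
    note("coupling_preset", "must be NC or HC", NA)
  }

  pos("calcium", c("Jleak_in", "Vleak_in", "k_IPR_diff", "k_VGCC_diff",
                   "k_ER_leak", "k_IPR", "V_PMCA", "K_PMCA", "n_P",
                   "V_SERCA", "K_SERCA", "n_S", "delta1", "delta2", "delta3",
                   "ca_cyt0", "ca_az0", "ca_total0", "ip3_0", "ca_ext"))
  if (!is.null(p$calcium$N_IPR) && p$calcium$N_IPR < 1) {
    note("calcium$N_IPR", "at least one IP3R channel", p$calcium$N_IPR)
  }
  pos("coupling", c("Vc", "kbar", "Kc"))
  pos("ip3", c("V0", "VQ", "KQ", "K_IP3k", "K_PLC", "k3k", "k5p",
               "kf_PLC", "kb_PLC", "PLC_tot", "kf_G", "kb_G", "VR", "KR",
               "G_tot"))
  if (!is.null(p$ip3$abeta) && (!is.finite(p$ip3$abeta) || p$ip3$abeta < 0)) {
    note("ip3$abeta", "amyloid amplitude must be >= 0", p$ip3$abeta)
  }
  pos("ip3r", c("a1", "nO", "KOd", "a2", "nA", "KAd", "a3", "nI", "KId",
                "j01", "j12", "j22", "j23", "j45", "jt01", "jt45"))
  pos("vgcc", c("alpha0", "beta0", "k", "g", "N_VGCC", "cluster_area",
                "AZ_area", "N_AZ", "V_eff", "z", "Faraday"))
  for (f in c("Cm", "gNa", "gK", "phi", "area_cm2")) pos("membrane", f)
  for (f in c("gNaleak", "gKleak", "gClleak", "gAHP")) {
    v <- p$membrane[[f]]
    if (is.null(v) || !is.finite(v) || v < 0) {
      note(paste0("membrane$", f), "conductance must be >= 0", v)
    }
  }
  pos("release", c("kmob", "kdemob", "kpriming", "kunpr", "kattach",
                   "kdetach", "kRF", "alpha", "beta", "lambda", "delta",
                   "gamma1", "gamma2", "a"))
  bb <- p$release$b
  if (is.null(bb) || !is.finite(bb) || bb <= 0 || bb > 1) {
    note("release$b", "cooperativity must satisfy 0 < b <= 1", bb)
  }
  if (!is.null(p$pools$N_sites) && p$pools$N_sites < 1) {
    note("pools$N_sites", "at least one release site", p$pools$N_sites)
  }
  if (!is.null(p$pools$N_reserve) && p$pools$N_reserve < 0) {
    note("pools$N_reserve", "reserve pool must be >= 0", p$pools$N_reserve)
  }
  pos("numerics", "dt")

  if (length(bad) == 0) {
    tibble::tibble(field = character(), rule = character(), value = double())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Flatten a parameter set into a tidy table
#'
#' @param p a `bouton_params` object.
#' @return A tibble with columns `group`, `name`, `value` (numeric
#'   fields only; tags and notes are carried in attributes of the
#'   parameter object itself).
#' @export
param_table <- function(p) {
  groups <- setdiff(names(p), c("condition", "coupling_preset", "meta"))
  purrr::map_dfr(groups, function(g) {
    flds <- p[[g]]
    keep <- vapply(flds, is.numeric, logical(1))
    purrr::map_dfr(names(flds)[keep], function(f) {
      tibble::tibble(group = g, name = f,
                     index = seq_along(flds[[f]]),
                     value = as.numeric(flds[[f]]))
    })
  })
}

#' Serialize / restore a parameter set as JSON
#'
#' The round trip is exact: every numeric field is written with 17
#' significant digits, enough to restore the double bit-for-bit.
#'
#' @param p a `bouton_params` object.
#' @param path file to write.
#' @return `write_params_json` returns `path` invisibly;
#'   `read_params_json` returns the restored `bouton_params`.
#' @export
write_params_json <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # integer-valued counts come back as doubles; restore storage mode
  for (f in c("N_IPR")) raw$calcium[[f]] <- as.integer(raw$calcium[[f]])
  raw$vgcc$N_VGCC <- as.integer(raw$vgcc$N_VGCC)
  raw$pools <- lapply(raw$pools, as.integer)
  raw$numerics$record_every <- as.integer(raw$numerics$record_every)
  class(raw) <- "bouton_params"
  raw
}

#' @export
print.bouton_params <- function(x, ...) {
  cat("<bouton_params> condition =", x$condition,
      "| ER-AZ coupling =", x$coupling_preset, "\n")
  cat("  IP3R: a1 =", x$ip3r$a1, ", a3 =", x$ip3r$a3, "\n")
  cat("  coupling: Vc =", x$coupling$Vc, ", kbar =", x$coupling$kbar,
      ", Kc =", x$coupling$Kc, "\n")
  cat("  VGCC cluster:", x$vgcc$N_VGCC, "channels; release sites:",
      x$pools$N_sites, "\n")
  invisible(x)
}

#' Fixed point of the IP3 metabolism at clamped Ca2+
#'
#' Solves `JPLC = Jdeg` with PLC and G at their own fixed points under
#' the tonic background input.  Used to initialize the resting IP3 of
#' each condition.
#'
#' @param p a `bouton_params` object (or the assembled list).
#' @param ca clamped cytosolic Ca2+ (uM).
#' @return Resting IP3 (uM).
#' @export
ip3_fixed_point <- function(p, ca = p$calcium$ca_cyt0) {
  m <- p$ip3
  q <- m$abeta_tonic
  rho <- m$VR * q / (q + m$KR)
  g <- m$kf_G * (rho + m$delta_G) * m$G_tot /
    (m$kf_G * (rho + m$delta_G) + m$kb_G)
  plc <- m$kf_PLC * g * m$PLC_tot / (m$kf_PLC * g + m$kb_PLC)
  VPLC <- m$V0 + m$VQ * q^2 / (q^2 + m$KQ^2)
  JPLC <- VPLC * plc * ca^2 / (ca^2 + m$K_PLC^2)
  eta <- m$k3k / (m$k3k + m$k5p)
  JPLC / (eta * ca^2 / (ca^2 + m$K_IP3k^2) + (1 - eta))
}

# Relaxed resting state of each condition/coupling combination: the mean
# over seconds 5-8 of three long unstimulated runs of the full hybrid
# model (the model\'s own steady state; reproducible with
# simulate_bouton(params, NULL, t_end = 8000)).  The printed reference
# resting values (Ca_cyt 0.1, Ca_AZ 0.05, Ca_total 56 uM) are the
# calibration anchors, not dynamical fixed points of the assembled model.
rest_state_defaults <- function(condition, coupling) {
  key <- paste(condition, coupling)
  tab <- list(
    "WT NC" = list(ca_cyt0 = 0.0635, ca_iprn0 = 0.0668, ca_az0 = 0.0902,
                   ca_total0 = 32.99),
    "WT HC" = list(ca_cyt0 = 0.0643, ca_iprn0 = 0.0744, ca_az0 = 0.0912,
                   ca_total0 = 33.54),
    "AD NC" = list(ca_cyt0 = 0.1122, ca_iprn0 = 0.1300, ca_az0 = 0.1366,
                   ca_total0 = 71.37),
    "AD HC" = list(ca_cyt0 = 0.1121, ca_iprn0 = 0.1312, ca_az0 = 0.1554,
                   ca_total0 = 72.25)
  )
  tab[[key]]
}
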