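#' Derived ER calcium concentration
#'
#' The ER pool is slaved to the conservation expression
#' `Ca_ER = delta2 * (Ca_total - Ca_cyt + Ca_IPRn/delta1 - Ca_AZ)`
#' rather than integrated.
#'
#' @param state a list or one-row data frame with `ca_cyt`, `ca_iprn`,
#'   `ca_az`, `ca_total` (uM).
#' @param params a [bouton_params()] object.
#' @return Ca_ER in uM (vectorized).
#' @export
ca_er <- function(state, params) {
  k <- params$calcium
  k$delta2 * (state$ca_total - state$ca_cyt + state$ca_iprn / k$delta1 -
                state$ca_az)
}

#' ER - active zone coupling flux
#'
#' Bidirectional transfer between the AZ and IP3R microdomains,
#' `J = Vc (Ca_AZ^2 - kbar Ca_IPRn^2) / (Ca_AZ^2 + Kc^2)`.
#' The flux vanishes on the surface `Ca_AZ^2 = kbar * Ca_IPRn^2` and
#' reverses sign across it.  The additive denominator is the
#' singularity-free bidirectional-SERCA form; the subtractive variant
#' (with a guard band around its pole at `Ca_AZ = Kc`) is available via
#' `params$coupling$printed_denominator`.
#'
#' @param ca_az,ca_iprn microdomain Ca2+ (uM), vectorized.
#' @param params a [bouton_params()] object (uses the `$coupling` block).
#' @return Flux in uM/ms; positive = transfer from AZ to the IP3R
#'   microdomain.
#' @export
coupling_flux <- function(ca_az, ca_iprn, params) {
  cp <- params$coupling
  num <- cp$Vc * (ca_az^2 - cp$kbar * ca_iprn^2)
  if (isTRUE(cp$printed_denominator)) {
    den <- ca_az^2 - cp$Kc^2
    den <- sign(den) * pmax(abs(den), cp$guard_band)
  } else {
    den <- ca_az^2 + cp$Kc^2
  }
  num / den
}

#' Evaluate every calcium flux of the compartment model
#'
#' @param state list/one-row data frame with `ca_cyt`, `ca_iprn`,
#'   `ca_az`, `ca_total`, `ip3` (uM).
#' @param po_ipr open fraction of the IP3R cluster in `[0, 1]`.
#' @param j_vgcc VGCC Ca2+ flux (uM/ms, bouton-referenced), e.g. from
#'   [vgcc_flux()].
#' @param params a [bouton_params()] object.
#' @return A one-row tibble of fluxes (uM/ms): `Jin`, `JIPR`,
#'   `JIPR_diff`, `JPMCA`, `JSERCA`, `JER_leak`, `JVGCC`, `JVGCC_diff`,
#'   `Jcoupling`.
#' @export
compute_fluxes <- function(state, po_ipr, j_vgcc, params) {
  if (any(unlist(state[c("ca_cyt", "ca_iprn", "ca_az")]) < 0)) {
    stop("negative concentration", call. = FALSE)
  }
  if (any(po_ipr < 0 | po_ipr > 1)) stop("po_ipr must lie in [0,1]", call. = FALSE)
  k <- params$calcium
  caer <- ca_er(state, params)
  hill <- function(c, K, n) c^n / (c^n + K^n)
  tibble::tibble(
    Jin = k$Jleak_in + k$Vleak_in * state$ip3,
    JIPR = k$k_IPR * po_ipr * (caer - state$ca_iprn),
    JIPR_diff = k$k_IPR_diff * (state$ca_iprn - state$ca_cyt),
    JPMCA = k$V_PMCA * hill(state$ca_cyt, k$K_PMCA, k$n_P),
    JSERCA = k$V_SERCA * hill(state$ca_cyt, k$K_SERCA, k$n_S),
    JER_leak = k$k_ER_leak * (caer - state$ca_cyt),
    JVGCC = j_vgcc,
    JVGCC_diff = k$k_VGCC_diff * (state$ca_az - state$ca_cyt),
    Jcoupling = coupling_flux(state$ca_az, state$ca_iprn, params)
  )
}

#' Right-hand side of the four-compartment calcium system
#'
#' `dCa_cyt = Jin + JIPR_diff - JPMCA + JER_leak + JVGCC_diff - JSERCA`;
#' `dCa_IPRn = delta1 (JIPR - JIPR_diff) + Jcoupling`;
#' `dCa_AZ = delta3 (JVGCC - JVGCC_diff) - Jcoupling/delta1`;
#' `dCa_total = Jin - JPMCA + JVGCC`.
#' All fluxes are bouton-referenced; the volume ratios express the
#' faster concentration changes of the microdomains.
#'
#' @param state as in [compute_fluxes()].
#' @param fluxes a flux tibble from [compute_fluxes()].
#' @param params a [bouton_params()] object.
#' @return A one-row tibble: `dca_cyt`, `dca_iprn`, `dca_az`,
#'   `dca_total` (uM/ms).
#' @export
calcium_rhs <- function(state, fluxes, params) {
  k <- params$calcium
  tibble::tibble(
    dca_cyt = fluxes$Jin + fluxes$JIPR_diff - fluxes$JPMCA +
      fluxes$JER_leak + fluxes$JVGCC_diff - fluxes$JSERCA,
    dca_iprn = k$delta1 * (fluxes$JIPR - fluxes$JIPR_diff) + fluxes$Jcoupling,
    dca_az = k$delta3 * (fluxes$JVGCC - fluxes$JVGCC_diff) -
      fluxes$Jcoupling / k$delta1,
    dca_total = fluxes$Jin - fluxes$JPMCA + fluxes$JVGCC
  )
}

#' IP3 metabolism right-hand side
#'
#' PLC-delta production gated by cytosolic Ca2+ and the (optional)
#' amyloid-beta input, balanced against Ca2+-dependent degradation by
#' the 3-kinase and 5-phosphatase:
#' `dIP3/dt = (JPLC - Jdeg)/tau_IP3` with `tau_IP3 = 1/(k3k + k5p)`,
#' `JPLC = VPLC * PLC * Ca^2/(Ca^2 + K_PLC^2)`,
#' `VPLC = V0 + VQ q^2/(q^2 + KQ^2)`,
#' `q = Abeta exp(-r (t - t1)) H(t - t1)`, and
#' `Jdeg = [eta Ca^2/(Ca^2 + K_IP3k^2) + (1 - eta)] IP3`,
#' `eta = k3k/(k3k + k5p)`.  PLC and G-protein activities follow
#' first-order kinetics with the G-protein driven by
#' `rho = VR q/(q + KR)` plus its intrinsic activity.
#'
#' @param state list with `ca_cyt`, `ip3`, `plc`, `g` (scaled
#'   activities in `[0, 1]`).
#' @param t time (ms), for the amyloid input.
#' @param params a [bouton_params()] object.
#' @return A one-row tibble: `dip3`, `dplc`, `dg` (per ms), plus the
#'   intermediate `JPLC` and `Jdeg`.
#' @export
ip3_rhs <- function(state, t, params) {
  m <- params$ip3
  q <- m$abeta_tonic +
    if (t >= m$abeta_t1) m$abeta * exp(-m$abeta_r * (t - m$abeta_t1)) else 0
  VPLC <- m$V0 + m$VQ * q^2 / (q^2 + m$KQ^2)
  rho <- m$VR * q / (q + m$KR)
  ca2 <- state$ca_cyt^2
  JPLC <- VPLC * state$plc * ca2 / (ca2 + m$K_PLC^2)
  eta <- m$k3k / (m$k3k + m$k5p)
  Jdeg <- (eta * ca2 / (ca2 + m$K_IP3k^2) + (1 - eta)) * state$ip3
  tau <- 1 / (m$k3k + m$k5p)
  tibble::tibble(
    dip3 = (JPLC - Jdeg) / tau,
    dplc = m$kf_PLC * state$g * (m$PLC_tot - state$plc) - m$kb_PLC * state$plc,
    dg = m$kf_G * (rho + m$delta_G) * (m$G_tot - state$g) - m$kb_G * state$g,
    JPLC = JPLC, Jdeg = Jdeg
  )
}

#' Resting PLC and G-protein activities
#'
#' Fixed points of the first-order PLC/G kinetics under the tonic
#' agonist/amyloid background, used as initial conditions.
#'
#' @param params a [bouton_params()] object.
#' @return list with `plc`, `g`.
#' @export
plc_g_rest <- function(params) {
  m <- params$ip3
  rho0 <- m$VR * m$abeta_tonic / (m$abeta_tonic + m$KR)
  g <- m$kf_G * (rho0 + m$delta_G) * m$G_tot /
    (m$kf_G * (rho0 + m$delta_G) + m$kb_G)
  plc <- m$kf_PLC * g * m$PLC_tot / (m$kf_PLC * g + m$kb_PLC)
  list(plc = plc, g = g)
}
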