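#' Phases of release events relative to the AP train
#'
#' Each release event is assigned the normalized position of its time
#' within the bracketing AP interval,
#' `phi = (t_event - T_AP(k)) / (T_AP(k+1) - T_AP(k))`, the standard
#' event-phase transform used with the Pinsky-Rinzel synchrony measure.
#' Events before the first or after the last AP are dropped and
#' counted.  A literal reading of the printed transform — pairing the
#' k-th event with the k-th AP — is available for comparison via
#' `pairing = "indexed"`.
#'
#' @param ap_times strictly increasing AP times (ms); at least 2.
#' @param event_times strictly increasing release-event times (ms).
#' @param pairing `"bracket"` (default) or `"indexed"`.
#' @return A tibble with column `phase` in `[0, 1)`; attribute
#'   `dropped` gives the number of out-of-range events.
#' @export
event_phases <- function(ap_times, event_times,
                         pairing = c("bracket", "indexed")) {
  pairing <- match.arg(pairing)
  if (length(ap_times) < 2) stop("need at least 2 APs", call. = FALSE)
  if (is.unsorted(ap_times, strictly = TRUE)) {
    stop("ap_times must be strictly increasing", call. = FALSE)
  }
  event_times <- sort(event_times)
  if (pairing == "bracket") {
    keep <- event_times >= ap_times[1] & event_times < ap_times[length(ap_times)]
    ev <- event_times[keep]
    k <- findInterval(ev, ap_times)
    phi <- (ev - ap_times[k]) / (ap_times[k + 1] - ap_times[k])
    dropped <- sum(!keep)
  } else {
    n <- min(length(event_times), length(ap_times) - 1)
    ev <- event_times[seq_len(n)]
    k <- seq_len(n)
    phi <- (ap_times[k] - ev) / (ap_times[k + 1] - ap_times[k])
    phi <- phi %% 1
    dropped <- length(event_times) - n
  }
  out <- tibble::tibble(phase = phi)
  attr(out, "dropped") <- dropped
  out
}

#' Kuramoto order parameter of a phase set
#'
#' The modulus of the mean complex phase vector,
#' `abs(mean(exp(2i * pi * phi)))`, between 0 (uniformly dispersed
#' events) and 1 (perfectly aligned events).
#'
#' @param phases a tibble with a `phase` column (as from
#'   [event_phases()]) or a bare numeric vector of phases.
#' @return Scalar `r` in `[0, 1]`.
#' @export
synchrony_index <- function(phases) {
  phi <- if (is.data.frame(phases)) phases$phase else phases
  if (length(phi) < 1) stop("empty phase set", call. = FALSE)
  Mod(mean(exp(2i * pi * phi)))
}

#' Relative synchrony change between conditions
#'
#' Per matched release-probability bin, `(r_WT - r_AD) / r_WT`:
#' positive values mean the AD synapse is less synchronized with the
#' stimulus than the WT synapse.
#'
#' @param wt,ad tibbles with columns `pr` (the matching key, e.g. the
#'   first-pulse release probability of the configuration) and `r`;
#'   rows must correspond (matched grids, e.g. the same VGCC sweep).
#' @return A tibble with `pr_wt`, `pr_ad`, `r_wt`, `r_ad`, `delta_r`.
#' @export
relative_synchrony_change <- function(wt, ad) {
  if (nrow(wt) != nrow(ad)) stop("mismatched grids", call. = FALSE)
  tibble::tibble(
    pr_wt = wt$pr, pr_ad = ad$pr,
    r_wt = wt$r, r_ad = ad$r,
    delta_r = (wt$r - ad$r) / wt$r
  )
}

#' Phase histogram
#'
#' @param phases as in [synchrony_index()].
#' @param bins number of bins over `[0, 1)` (default 50).
#' @return A tibble with `bin_mid` and `count`.
#' @export
phase_histogram <- function(phases, bins = 50) {
  phi <- if (is.data.frame(phases)) phases$phase else phases
  br <- seq(0, 1, length.out = bins + 1)
  h <- graphics::hist(phi, breaks = br, plot = FALSE, include.lowest = TRUE)
  tibble::tibble(bin_mid = h$mids, count = h$counts)
}
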