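#' Simulate the full bouton model
#'
#' Hybrid integration: the deterministic subsystem (four Ca2+
#' compartments, IP3/PLC/G metabolism, membrane voltage) advances by
#' fixed-step RK4 while the IP3R cluster, the VGCC cluster and (in
#' stochastic-release mode) the per-vesicle release machinery advance by
#' a fixed-step Markov-chain update equivalent to the Gillespie
#' algorithm in the small-step limit.  Traces are reproducible
#' bit-for-bit under a fixed `(seed, trial)` pair, and trial substreams
#' are independent: adding trials never reshuffles earlier ones.
#'
#' @param params a [bouton_params()] object.
#' @param protocol a [make_protocol()] object, or `NULL` for no
#'   stimulation.
#' @param t_end simulated time (ms); defaults to 50 ms past the last
#'   pulse onset.
#' @param dt integration step (ms); default from `params$numerics`.
#' @param record_every store every k-th step in the trace (0 = no trace;
#'   AP times and the event log are always kept at full resolution).
#' @param seed,trial integers selecting the random substream.
#' @param stochastic_release simulate vesicles stochastically (default);
#'   if `FALSE` the release machinery is omitted.
#' @param freeze_channels keep both channel clusters in their initial
#'   state (fully deterministic run; used for integrator-order checks).
#' @param closed_system zero all plasma-membrane Ca2+ fluxes (Jin,
#'   JPMCA, JVGCC), making total Ca2+ exactly conserved.
#' @return An object of class `bouton_sim`: list with `trace` (tibble),
#'   `events` (tibble: time, mode, pool), `ap_times`, `final_state`,
#'   `cum_release`, `initial_rrp`, and `config`.
#' @export
simulate_bouton <- function(params, protocol = make_protocol("single"),
                            t_end = NULL, dt = params$numerics$dt,
                            record_every = params$numerics$record_every,
                            seed = 1L, trial = 0L,
                            stochastic_release = TRUE,
                            freeze_channels = FALSE,
                            closed_system = FALSE) {
  onsets <- if (is.null(protocol)) numeric(0) else protocol$onsets
  amplitude <- if (is.null(protocol)) 0 else protocol$amplitude
  width <- if (is.null(protocol)) 1 else protocol$width
  if (is.null(t_end)) {
    if (length(onsets) == 0) stop("t_end required without a protocol", call. = FALSE)
    t_end <- max(onsets) + 50
  }
  res <- simulate_bouton_cpp(unclass(params), onsets, amplitude, width,
                             t_end, dt, as.integer(record_every),
                             as.integer(seed), as.integer(trial),
                             stochastic_release, freeze_channels,
                             closed_system)
  trace <- NULL
  if (record_every > 0) {
    nr <- as.integer(res$n_rec)
    tr <- res$trace[seq_len(nr), , drop = FALSE]
    colnames(tr) <- c("time", "ca_cyt", "ca_iprn", "ca_az", "ca_total",
                      "ca_er", "ip3", "plc", "g", "V", "n", "h",
                      "po_ipr", "po_vgcc", "j_vgcc", "release_rate",
                      "pool_R", "pool_U", "pool_V", "pool_W", "refractory",
                      "cum_spont", "cum_sync", "cum_async")
    trace <- tibble::as_tibble(tr)
  }
  events <- tibble::tibble(
    time = res$events$time,
    mode = factor(c("spont", "sync", "async")[res$events$mode],
                  levels = c("spont", "sync", "async")),
    pool = factor(c("V", "W")[res$events$pool + 1L], levels = c("V", "W"))
  )
  structure(list(
    trace = trace,
    events = events,
    ap_times = res$ap_times,
    final_state = stats::setNames(res$final_state,
                                  c("ca_cyt", "ca_iprn", "ca_az", "ca_total",
                                    "ip3", "plc", "g", "V", "n", "h")),
    cum_release = stats::setNames(res$cum_release, c("spont", "sync", "async")),
    initial_rrp = params$pools$N_sites,
    config = list(condition = params$condition,
                  coupling = params$coupling_preset,
                  n_vgcc = params$vgcc$N_VGCC,
                  protocol = protocol, t_end = t_end, dt = dt,
                  seed = seed, trial = trial,
                  stochastic_release = stochastic_release)
  ), class = "bouton_sim")
}

#' @export
print.bouton_sim <- function(x, ...) {
  cat("<bouton_sim>", x$config$condition, "/", x$config$coupling,
      "| N_VGCC =", x$config$n_vgcc, "| T =", x$config$t_end, "ms\n")
  cat("  APs:", length(x$ap_times), "; releases:",
      sum(x$cum_release), "(", paste(names(x$cum_release), x$cum_release,
                                     collapse = ", "), ")\n")
  invisible(x)
}

#' Per-pulse scoring windows of a protocol
#'
#' Each stimulus owns the window from its onset to the next onset (the
#' last or a single pulse gets onset + 50 ms).
#'
#' @param protocol a [make_protocol()] object.
#' @return A tibble with `pulse`, `start`, `end` (ms).
#' @export
pulse_windows <- function(protocol) {
  on <- protocol$onsets
  tibble::tibble(pulse = seq_along(on), start = on,
                 end = c(on[-1], on[length(on)] + 50))
}

# run `trials` stochastic repeats and return pooled events, mean trace and
# per-trial release counts per window
run_trials <- function(params, protocol, trials, seed, t_end = NULL,
                       record_every = 100L) {
  win <- pulse_windows(protocol)
  ev_all <- vector("list", trials)
  ap_all <- vector("list", trials)
  pr_mat <- matrix(0, trials, nrow(win))
  mean_trace <- NULL
  for (tr in seq_len(trials)) {
    sim <- simulate_bouton(params, protocol, t_end = t_end, seed = seed,
                           trial = tr, record_every = record_every)
    ev_all[[tr]] <- dplyr::mutate(sim$events, trial = tr)
    ap_all[[tr]] <- sim$ap_times
    for (w in seq_len(nrow(win))) {
      pr_mat[tr, w] <- release_probability(sim$events,
                                           c(win$start[w], win$end[w]),
                                           sim$initial_rrp)
    }
    if (record_every > 0) {
      m <- as.matrix(sim$trace)
      mean_trace <- if (is.null(mean_trace)) m / trials else
        mean_trace + m / trials
    }
  }
  trace <- NULL
  if (!is.null(mean_trace)) {
    trace <- tibble::as_tibble(mean_trace)
  }
  list(events = dplyr::bind_rows(ev_all), ap_times = ap_all,
       pr = pr_mat, windows = win, trace = trace)
}

#' Transient metrics of a stimulus response
#'
#' For each scoring window: rise time (stimulus onset to peak release
#' rate), decay time (peak to first return within basal + 5% of peak),
#' cumulative AZ Ca2+ (area of the Ca2+ transient above its
#' window-start baseline) and residual AZ Ca2+ (the same integral
#' restricted to after the Ca2+ peak).
#'
#' @param trace a trace tibble with `time`, `release_rate`, `ca_az`
#'   columns (typically a trial-averaged trace).
#' @param windows a tibble with `start`, `end` (ms), as from
#'   [pulse_windows()].
#' @param basal_frac tolerance band for the decay-time return, as a
#'   fraction of the peak (default 0.05).
#' @param strict error when a window has no release peak above its
#'   baseline (default); with `strict = FALSE` such windows report
#'   `NA` rise/decay times instead (late train pulses of a depleted
#'   terminal may release nothing).
#' @return A tibble with one row per window: `peak_rate`, `rise_time`,
#'   `decay_time`, `cumulative_ca`, `residual_ca`.
#' @export
transient_metrics <- function(trace, windows, basal_frac = 0.05,
                              strict = TRUE) {
  purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    sel <- trace$time >= windows$start[w] & trace$time < windows$end[w]
    tt <- trace$time[sel]
    rate <- trace$release_rate[sel]
    caz <- trace$ca_az[sel]
    if (length(tt) < 3) stop("window contains too few samples", call. = FALSE)
    basal <- rate[1]
    ipk <- which.max(rate)
    peak <- rate[ipk]
    no_peak <- !is.finite(peak) || peak <= basal
    if (no_peak && strict) {
      stop("no release peak found in window ", w, call. = FALSE)
    }
    if (no_peak) {
      rise <- NA_real_; decay <- NA_real_
    } else {
      rise <- tt[ipk] - windows$start[w]
      thr <- basal + basal_frac * (peak - basal)
      after <- which(seq_along(rate) > ipk & rate <= thr)
      decay <- if (length(after) > 0) tt[after[1]] - tt[ipk] else
        tt[length(tt)] - tt[ipk]
    }
    dtv <- diff(tt)
    mid <- function(x) (x[-1] + x[-length(x)]) / 2
    base_ca <- caz[1]
    excess <- pmax(caz - base_ca, 0)
    cum_ca <- sum(mid(excess) * dtv)
    ica <- which.max(caz)
    resid <- if (ica < length(tt)) {
      sum(mid(excess)[ica:(length(tt) - 1)] * dtv[ica:(length(tt) - 1)])
    } else 0
    tibble::tibble(pulse = w, peak_rate = peak, rise_time = rise,
                   decay_time = decay, cumulative_ca = cum_ca,
                   residual_ca = resid)
  })
}

#' Single action potential experiment
#'
#' Runs `trials` stochastic repeats of a single-AP stimulus for each
#' VGCC cluster size and summarizes release probability and the
#' transient metrics of the trial-averaged response.
#'
#' @param params a [bouton_params()] object.
#' @param n_vgcc integer vector of cluster sizes to sweep.
#' @param trials stochastic repeats per cluster size.
#' @param seed integer master seed.
#' @param t0 onset of the stimulus (ms); the scoring window runs 50 ms
#'   past it.
#' @return A tibble with one row per `n_vgcc`: `pr`, `pr_se`,
#'   `peak_rate`, `rise_time`, `decay_time`, `cumulative_ca`,
#'   `residual_ca`, `n_ap` (mean APs per trial).
#' @export
run_single_ap <- function(params, n_vgcc = params$vgcc$N_VGCC, trials = 30,
                          seed = 1L, t0 = 20) {
  purrr::map_dfr(n_vgcc, function(nv) {
    p <- params
    p$vgcc$N_VGCC <- as.integer(nv)
    proto <- make_protocol("single", t0 = t0)
    res <- run_trials(p, proto, trials, seed)
    tm <- transient_metrics(res$trace, res$windows, strict = FALSE)
    tibble::tibble(
      condition = params$condition, coupling = params$coupling_preset,
      n_vgcc = nv,
      pr = mean(res$pr[, 1]), pr_se = stats::sd(res$pr[, 1]) / sqrt(trials),
      peak_rate = tm$peak_rate[1], rise_time = tm$rise_time[1],
      decay_time = tm$decay_time[1], cumulative_ca = tm$cumulative_ca[1],
      residual_ca = tm$residual_ca[1],
      n_ap = mean(lengths(res$ap_times))
    )
  })
}

#' Paired-pulse experiment
#'
#' Two pulses separated by `interval` ms; the paired-pulse ratio is
#' `PPR = Pr2 / Pr1` of the trial-averaged per-pulse release
#' probabilities.
#'
#' @inheritParams run_single_ap
#' @param interval inter-pulse interval (ms), default 40.
#' @return A tibble per `n_vgcc`: `pr1`, `pr2`, `ppr`, their standard
#'   errors, `residual_ca2` (residual AZ Ca2+ after the second pulse)
#'   and `n_ap`.
#' @export
run_paired_pulse <- function(params, n_vgcc = params$vgcc$N_VGCC,
                             interval = 40, trials = 30, seed = 1L, t0 = 20) {
  if (interval <= 0) stop("interval must be positive", call. = FALSE)
  purrr::map_dfr(n_vgcc, function(nv) {
    p <- params
    p$vgcc$N_VGCC <- as.integer(nv)
    proto <- make_protocol("paired", t0 = t0, interval = interval)
    res <- run_trials(p, proto, trials, seed)
    tm <- transient_metrics(res$trace, res$windows, strict = FALSE)
    pr1 <- mean(res$pr[, 1]); pr2 <- mean(res$pr[, 2])
    tibble::tibble(
      condition = params$condition, coupling = params$coupling_preset,
      n_vgcc = nv, pr1 = pr1, pr2 = pr2,
      pr1_se = stats::sd(res$pr[, 1]) / sqrt(trials),
      pr2_se = stats::sd(res$pr[, 2]) / sqrt(trials),
      ppr = if (pr1 > 0) pr2 / pr1 else NA_real_,
      residual_ca2 = tm$residual_ca[2],
      n_ap = mean(lengths(res$ap_times))
    )
  })
}

#' Stimulus-train experiment
#'
#' A train of `n_pulses` action potentials at `freq` Hz (default 20 at
#' 20 Hz).  Per pulse: trial-averaged release probability, peak total /
#' synchronous / asynchronous release rates of the averaged response,
#' facilitation ratios relative to the first pulse, and the RRP
#' occupancy at pulse onset.  Pooled event and AP times are returned
#' for synchrony analysis.
#'
#' @inheritParams run_single_ap
#' @param n_pulses number of APs (default 20).
#' @param freq stimulation frequency (Hz; default 20).
#' @return list with `per_pulse` (tibble), `events` (pooled, with
#'   `trial`), `ap_times` (list per trial), `pr1`, `pr1_se`, and
#'   `synchrony` (tibble: `r`, `n_events`, `dropped`).
#' @export
run_train <- function(params, n_vgcc = params$vgcc$N_VGCC, n_pulses = 20,
                      freq = 20, trials = 25, seed = 1L, t0 = 20) {
  if (n_pulses < 2) stop("a train needs at least 2 pulses", call. = FALSE)
  nv <- as.integer(n_vgcc[1])
  p <- params
  p$vgcc$N_VGCC <- nv
  proto <- make_protocol("train", t0 = t0, interval = 1000 / freq,
                         n_pulses = n_pulses)
  res <- run_trials(p, proto, trials, seed)
  win <- res$windows
  tm <- transient_metrics(res$trace, win, strict = FALSE)

  # per-pulse peak sync/async rates from the pooled event histogram (1 ms bins)
  rate_of <- function(ev_times, t0w, t1w) {
    if (length(ev_times) == 0) return(0)
    h <- graphics::hist(ev_times[ev_times >= t0w & ev_times < t1w],
                        breaks = seq(t0w, t1w, by = 1), plot = FALSE)
    max(h$counts) / trials # vesicles / ms, trial-averaged
  }
  sync_t <- res$events$time[res$events$mode == "sync"]
  async_t <- res$events$time[res$events$mode == "async"]
  per_pulse <- tibble::tibble(
    pulse = win$pulse,
    pr = colMeans(res$pr),
    pr_se = apply(res$pr, 2, stats::sd) / sqrt(trials),
    peak_rate = tm$peak_rate,
    peak_sync = purrr::map2_dbl(win$start, win$end, ~rate_of(sync_t, .x, .y)),
    peak_async = purrr::map2_dbl(win$start, win$end, ~rate_of(async_t, .x, .y)),
    rrp_onset = purrr::map_dbl(win$start, function(s) {
      i <- which.min(abs(res$trace$time - s))
      res$trace$pool_V[i] + res$trace$pool_W[i]
    })
  )
  per_pulse$facil_pr <- per_pulse$pr / per_pulse$pr[1]
  per_pulse$facil_rate <- per_pulse$peak_rate / per_pulse$peak_rate[1]

  # stimulus-release synchrony over pooled trials
  aps <- res$ap_times[[1]]
  phases <- purrr::map_dfr(seq_len(trials), function(tr) {
    evt <- res$events$time[res$events$trial == tr]
    apt <- res$ap_times[[tr]]
    if (length(apt) >= 2 && length(evt) > 0) event_phases(apt, evt)
    else tibble::tibble(phase = double())
  })
  sync <- tibble::tibble(
    r = if (nrow(phases) > 0) synchrony_index(phases) else NA_real_,
    n_events = nrow(phases)
  )
  list(per_pulse = per_pulse, events = res$events, ap_times = res$ap_times,
       trace = res$trace,
       pr1 = per_pulse$pr[1], pr1_se = per_pulse$pr_se[1],
       synchrony = sync, condition = params$condition,
       coupling = params$coupling_preset, n_vgcc = nv, trials = trials)
}

#' Calcium-clamp dose-response of the release machinery
#'
#' Clamps cytosolic (and active-zone) Ca2+ at each level and integrates
#' the deterministic release expectation; the release rate rises to a
#' peak and decays back towards basal within tens of milliseconds as
#' the sensors load and the releasable pool drains.
#'
#' @param levels clamp levels (uM), e.g. `c(1, 3, 10, 30, 100)`.
#' @param params a [bouton_params()] object.
#' @param t_end integration time per level (ms).
#' @return list with `profiles` (tibble: `level`, `time`,
#'   `rate_total`, ...) and `dose` (tibble: `level`, `peak_rate`,
#'   `time_to_peak`).
#' @export
run_ca_clamp <- function(levels, params, t_end = 100) {
  if (any(levels < 0)) stop("clamp levels must be >= 0", call. = FALSE)
  profiles <- purrr::map_dfr(levels, function(lv) {
    out <- release_ode(lv, lv, t_end, params, dt_out = 0.2)
    dplyr::mutate(out, level = lv)
  })
  dose <- profiles |>
    dplyr::summarise(
      peak_rate = max(.data$rate_total),
      time_to_peak = .data$time[which.max(.data$rate_total)],
      .by = "level"
    )
  list(profiles = profiles, dose = dose)
}
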