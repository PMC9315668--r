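#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bouton simulation
#'
#' Returns the (downsampled) state trace as a long-format tibble, one
#' row per time point and variable.
#'
#' @param x a `bouton_sim` object.
#' @param variables which trace columns to keep (default: the main
#'   state variables).
#' @param ... unused.
#' @return A tibble with `time`, `variable`, `value`.
#' @export
tidy.bouton_sim <- function(x, variables = c("ca_cyt", "ca_az", "ca_er",
                                             "ip3", "V", "po_ipr",
                                             "po_vgcc", "release_rate"),
                            ...) {
  if (is.null(x$trace)) stop("simulation was run without a trace", call. = FALSE)
  x$trace |>
    dplyr::select(dplyr::all_of(c("time", variables))) |>
    tidyr::pivot_longer(-"time", names_to = "variable", values_to = "value")
}

#' One-row summary of a bouton simulation
#'
#' @param x a `bouton_sim` object.
#' @param ... unused.
#' @return A one-row tibble: condition, coupling, VGCC count, AP count,
#'   releases by mode, overall release probability.
#' @export
glance.bouton_sim <- function(x, ...) {
  tibble::tibble(
    condition = x$config$condition,
    coupling = x$config$coupling,
    n_vgcc = x$config$n_vgcc,
    t_end = x$config$t_end,
    n_ap = length(x$ap_times),
    n_spont = unname(x$cum_release["spont"]),
    n_sync = unname(x$cum_release["sync"]),
    n_async = unname(x$cum_release["async"]),
    pr_total = sum(x$cum_release) / x$initial_rrp
  )
}
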