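#' Broom-style tidiers and autoplot methods
#'
#' Every result object has a tabular face: `tidy()` returns the long
#' tibble a downstream analysis wants, `glance()` a one-row summary, and
#' `autoplot()` a ggplot2 figure.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tidiers
#' @param x a result object
#' @param ... unused
#' @export
tidy.dm_sim_run <- function(x, ...) x$series

#' @rdname tidiers
#' @export
glance.dm_sim_run <- function(x, ...) {
  last <- x$bookkeeping[x$bookkeeping$step == max(x$bookkeeping$step), ]
  tibble::tibble(
    n_steps = max(x$bookkeeping$step),
    n_types = length(unique(x$bookkeeping$entity_type)),
    total_births = sum(last$births_cum),
    total_deaths = sum(last$deaths_cum),
    final_alive = sum(last$alive)
  )
}

#' @rdname tidiers
#' @param object a result object
#' @export
autoplot.dm_sim_run <- function(object, ...) {
  totals <- sim_totals(object)
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$step, y = .data$total,
                               colour = .data$entity_type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "living agents", colour = "entity type",
                  title = "Population dynamics") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
tidy.dm_flow_run <- function(x, ...) x$occupancy

#' @rdname tidiers
#' @export
glance.dm_flow_run <- function(x, ...) {
  tibble::tibble(
    perspective = x$perspective,
    n_steps = max(x$occupancy$step),
    final_tokens = flow_token_count(x$final_state),
    total_firings = sum(x$final_state$fired),
    tokens_consumed = x$final_state$consumed
  )
}

#' @rdname tidiers
#' @export
autoplot.dm_flow_run <- function(object, ...) {
  ggplot2::ggplot(object$occupancy,
                  ggplot2::aes(x = .data$step, y = .data$count,
                               colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "tokens", colour = "activity",
                  title = paste("Token flow:", object$perspective)) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
tidy.dm_consistency_report <- function(x, ...) x$violations

#' @rdname tidiers
#' @export
glance.dm_consistency_report <- function(x, ...) {
  tibble::tibble(
    pass = nrow(x$violations) == 0L,
    n_violations = nrow(x$violations),
    n_rules = nrow(x$summary),
    fingerprint = x$fingerprint
  )
}
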