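#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation trajectory
#'
#' One row per output time and tracked quantity: substrate pools
#' (`accessible`, `inaccessible`, `uptake_available` per class), community
#' `biomass` and untracked `residues`, and cumulative `co2`.
#'
#' @param x a `cstability_sim`.
#' @param ... unused.
#' @return tibble with columns `time`, `pool`, `class`, `carbon` (`class`
#'   holds the community name for biomass/residue rows and `NA` for CO2).
#' @export
tidy.cstability_sim <- function(x, ...) {
  pools <- tidyr::pivot_longer(
    x$pools, c("accessible", "inaccessible", "uptake_available"),
    names_to = "pool", values_to = "carbon")
  orgs <- tidyr::pivot_longer(
    dplyr::rename(x$organisms, class = "community"),
    c("biomass", "residues"), names_to = "pool", values_to = "carbon")
  co2 <- dplyr::transmute(x$co2, time = .data$time, class = NA_character_,
                          pool = "co2", carbon = .data$co2)
  dplyr::arrange(
    dplyr::bind_rows(pools[c("time", "class", "pool", "carbon")],
                     orgs[c("time", "class", "pool", "carbon")], co2),
    .data$time, .data$pool, .data$class)
}

#' One-row summary of a simulation
#'
#' @param x a `cstability_sim`.
#' @param ... unused.
#' @return tibble with the horizon, initial and final system carbon, final
#'   cumulative CO2, the total input delivered, and `closure_error`: the
#'   largest relative deviation of total system carbon from the
#'   input-corrected budget along the trajectory.
#' @export
glance.cstability_sim <- function(x, ...) {
  tot <- total_system_carbon(x)
  input_rate <- sum(vapply(x$config$classes, function(cl) {
    cl$input_accessible + cl$input_inaccessible
  }, 0))
  budget <- tot$total_carbon[1] + input_rate * tot$time
  tibble::tibble(
    t_end = max(x$times),
    initial_carbon = tot$total_carbon[1],
    final_carbon = utils::tail(tot$total_carbon, 1),
    final_co2 = utils::tail(x$co2$co2, 1),
    total_input = input_rate * max(x$times),
    closure_error = max(abs(tot$total_carbon - budget)) /
      max(tot$total_carbon[1], .Machine$double.eps)
  )
}

#' @export
tidy.cstability_steady <- function(x, ...) {
  dplyr::bind_rows(
    x$stocks,
    tibble::tibble(class = "microbial_biomass", stock = x$c_mic,
                   share = x$microbial_share))
}

#' @export
glance.cstability_steady <- function(x, ...) {
  tibble::tibble(total = x$total, c_mic = x$c_mic,
                 microbial_share = x$microbial_share,
                 n_classes = nrow(x$stocks))
}

#' @export
tidy.cstability_sobol <- function(x, ...) x$indices

#' @export
glance.cstability_sobol <- function(x, ...) {
  tibble::tibble(n_evals = x$n_evals, n_block = x$n_block, seed = x$seed,
                 n_parameters = length(unique(x$indices$parameter)),
                 n_outputs = length(unique(x$indices$output)))
}

#' Plot a simulation trajectory
#'
#' Carbon time series: per-class substrate (accessible + inaccessible),
#' living biomass per community, cumulative CO2 and untracked residues.
#'
#' @param object a `cstability_sim`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cstability_sim <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, .data$pool != "uptake_available")
  d$series <- ifelse(is.na(d$class), d$pool, paste(d$class, d$pool, sep = ":"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$carbon,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (d)", y = expression(carbon ~ (g[C])),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot stored polymerization distributions
#'
#' Density over the polymerization coordinate at the stored snapshot
#' times, faceted by class and pool.
#'
#' @param sim a `cstability_sim`.
#' @return a ggplot object.
#' @export
plot_distributions <- function(sim) {
  stopifnot(inherits(sim, "cstability_sim"))
  ggplot2::ggplot(sim$snapshots,
                  ggplot2::aes(.data$p, .data$density,
                               colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(pool ~ class) +
    ggplot2::labs(x = "polymerization p", y = expression(g[C] ~ p^{-1}),
                  colour = "time (d)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cstability_steady <- function(object, ...) {
  g <- object$grid
  d <- purrr::map_dfr(names(object$solutions), function(cl) {
    tibble::tibble(class = cl, p = g$centers,
                   density = pmax(object$solutions[[cl]]$chi(g$centers), 0))
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$p, .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.6) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "polymerization p",
                  y = expression(steady ~ density ~ (g[C] ~ p^{-1}))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cstability_sobol <- function(object, ...) {
  d <- object$indices
  d$output <- as.numeric(d$output)
  ggplot2::ggplot(d, ggplot2::aes(.data$output, .data$share,
                                  fill = .data$parameter)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "time (d)", y = "normalized first-order index",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
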