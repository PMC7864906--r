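#' Steady-state microbial biomass
#'
#' Closed form for the microbial carbon at steady state under constant
#' total input `I`: mortality balances assimilation while respiration
#' balances input, giving
#' \deqn{C_{mic} = \frac{e^0 I}{(1 - e^0)\, m^0}.}
#'
#' @param e0 carbon use efficiency, in (0, 1).
#' @param m0 mortality rate (1/d), > 0.
#' @param I total carbon input rate (g_C/d).
#' @return biomass carbon (g_C).
#' @examples
#' steady_microbial_biomass(0.4, 0.02, 2.74e-4)
#' @export
steady_microbial_biomass <- function(e0, m0, I) {
  if (e0 >= 1) stop("no steady state exists for e0 >= 1", call. = FALSE)
  stopifnot(e0 > 0, m0 > 0, I >= 0)
  e0 * I / ((1 - e0) * m0)
}

## Extract the scalar parameters the closed form needs from a configuration:
## one community, uniform e0 and u0, one enzyme per class, all pools
## accessible, constant accessible input.
steady_params <- function(cfg) {
  validate_config(cfg)
  if (length(cfg$communities) != 1) {
    stop("the closed-form steady state assumes a single community",
         call. = FALSE)
  }
  com <- cfg$communities[[1]]
  e0 <- unique(unname(com$e0)); u0 <- unique(unname(com$u0))
  if (length(e0) != 1 || length(u0) != 1) {
    stop("the closed-form steady state assumes uniform e0 and u0 across ",
         "classes", call. = FALSE)
  }
  I <- sum(vapply(cfg$classes, `[[`, 0, "input_accessible"))
  cls <- lapply(cfg$classes, function(cl) {
    enz <- Filter(function(e) e$target == cl$name, cfg$enzymes)
    if (length(enz) != 1) {
      stop(sprintf("class '%s' needs exactly one enzyme family", cl$name),
           call. = FALSE)
    }
    sfrac <- com$signature[cl$name]
    list(name = cl$name, tau0 = enz[[1]]$tau0, alpha = enz[[1]]$alpha,
         input_frac = if (I > 0) cl$input_accessible / I else 0,
         sig_frac = if (is.na(sfrac)) 0 else unname(sfrac),
         center_frac = cl$center_frac, sd_frac = cl$sd_frac)
  })
  list(e0 = e0, u0 = u0, m0 = com$m0, I = I, classes = cls,
       grid = cfg$grid)
}

## Unit-mass truncated-Gaussian profile helpers (closed forms via pnorm)
profile_fns <- function(grid, center_frac, sd_frac) {
  len <- grid$p_max - grid$p_min
  mu <- grid$p_max - center_frac * len
  sd <- sd_frac * len
  Z <- stats::pnorm(grid$p_max, mu, sd) - stats::pnorm(grid$p_min, mu, sd)
  list(
    phi = function(p) stats::dnorm(p, mu, sd) / Z,
    upper = function(p) (stats::pnorm(grid$p_max, mu, sd) -
                           stats::pnorm(p, mu, sd)) / Z
  )
}

#' Steady-state source profile \eqn{\theta_*(p)}
#'
#' The per-unit-biomass carbon source of a class at steady state: necromass
#' return plus external input,
#' \eqn{\theta_*(p) = m^0 s_*(p) + i_*(p) / C_{mic}}.  For plant classes
#' (input, no signature) this specializes to
#' \eqn{m^0 (1 - e^0)\, i_*(p) / (e^0 I)}; for microbial classes (signature,
#' no input) to \eqn{m^0 s_*(p)}.
#'
#' @param cfg a steady-state-compatible [cstability_config()], e.g.
#'   [scenario_steady_state()].
#' @param class class name.
#' @param p polymerization coordinates at which to evaluate.
#' @return numeric vector of source densities (g_C / g_C / p / d).
#' @export
theta_profile <- function(cfg, class, p) {
  pr <- steady_params(cfg)
  cl <- pr$classes[[class]]
  if (is.null(cl)) stop(sprintf("unknown class '%s'", class), call. = FALSE)
  g <- polymer_grid(pr$grid$p_min, pr$grid$p_max, pr$grid$dp,
                    pr$grid$uptake_frac)
  fns <- profile_fns(g, cl$center_frac, cl$sd_frac)
  cmic <- steady_microbial_biomass(pr$e0, pr$m0, pr$I)
  tm <- pr$m0 * cl$sig_frac + cl$input_frac * pr$I / cmic
  tm * fns$phi(p)
}

## Closed-form steady distribution evaluator for one class.
## Returns a function chi(p), vectorized, plus the class stock by adaptive
## quadrature.  theta_mass is the integral of theta over the interval.
steady_class_solution <- function(grid, tau0, alpha, u0, theta_mass,
                                  center_frac = 0.25, sd_frac = 0.05) {
  p_min <- grid$p_min; p_max <- grid$p_max; p_u <- grid$p_u
  fns <- profile_fns(grid, center_frac, sd_frac)
  th <- function(p) theta_mass * fns$phi(p)
  TH <- function(p) theta_mass * fns$upper(p)   # \int_p^{pmax} theta
  beta <- (tau0 - alpha * u0) / (tau0 + u0)
  if (u0 > 0 && beta >= 1) {
    stop("beta >= 1: steady distribution not integrable", call. = FALSE)
  }

  chi_hi <- function(p) th(p) / tau0 + (alpha + 1) / (p - p_min) * TH(p) / tau0

  # inner power-weighted integral of the uptake region, H(p) = \int_p^{p_u}
  # (p' - p_min)^(beta - 1) theta(p') dp', tabulated once on a fine grid
  # with the power-law endpoint handled by substitution q = (p - p_min)^beta
  # when beta is positive (integrand singular at p_min otherwise).
  n_fine <- 4000
  if (beta > 0) {
    # dH = (p' - p_min)^{beta-1} theta dp' = theta dq / beta with
    # q = (p' - p_min)^beta, which removes the endpoint singularity
    q <- seq(0, (p_u - p_min)^beta, length.out = n_fine + 1)
    pf <- p_min + q^(1 / beta)
    gq <- th(pf) / beta
    rev_int <- rev(cumsum(rev((gq[-1] + gq[-length(gq)]) / 2 * diff(q))))
    Hfun <- stats::approxfun(pf, c(rev_int, 0), yleft = rev_int[1],
                             yright = 0)
  } else {
    pf <- seq(p_min, p_u, length.out = n_fine + 1)
    integrand <- ifelse(pf > p_min, (pf - p_min)^(beta - 1), 0) * th(pf)
    rev_int <- rev(cumsum(rev((integrand[-1] + integrand[-length(integrand)]) /
                                2 * diff(pf))))
    Hfun <- stats::approxfun(pf, c(rev_int, 0), yleft = rev_int[1],
                             yright = 0)
  }

  chi_lo <- function(p) {
    s <- tau0 + u0
    th(p) / s +
      (alpha + 1) * (p_u - p_min)^(beta - 1) / (p - p_min)^beta * TH(p_u) / s +
      (alpha + 1) * tau0 / s^2 * Hfun(p) / (p - p_min)^beta
  }

  chi <- function(p) {
    ifelse(p >= p_u, chi_hi(pmax(p, p_min + 1e-12)),
           ifelse(p > p_min, chi_lo(pmax(p, p_min + 1e-12)), 0))
  }

  stock_hi <- TH(p_u) / tau0 + (alpha + 1) / tau0 *
    stats::integrate(function(p) TH(p) / (p - p_min), p_u, p_max,
                     rel.tol = 1e-10)$value
  # without an uptake sink nothing removes carbon at the low-p end and the
  # steady stock diverges logarithmically; the distribution itself is
  # still well defined pointwise
  stock_lo <- if (u0 > 0) {
    stats::integrate(function(p) chi_lo(p), p_min, p_u,
                     rel.tol = 1e-8, subdivisions = 400L)$value
  } else {
    Inf
  }
  list(chi = chi, stock = stock_hi + stock_lo, beta = beta)
}

#' Closed-form steady state of the substrate-microbe system
#'
#' Evaluates the analytic steady state of a single-community, all-accessible
#' configuration under constant input: the microbial biomass
#' ([steady_microbial_biomass()]) and, per class, the steady polymerization
#' distribution obtained from the source profile \eqn{\theta_*} by inverting
#' the depolymerization-uptake balance on the two sub-domains (above the
#' uptake cut, and inside the uptake domain where the extra sink
#' \eqn{u^0 C_{mic}} applies with exponent
#' \eqn{\beta = (\tau^0 - \alpha u^0)/(\tau^0 + u^0)}).
#' Class stocks are adaptive-quadrature integrals of the distributions.
#'
#' @param cfg a steady-state-compatible [cstability_config()].
#' @return an object of class `cstability_steady`: list with `c_mic`,
#'   tibble `stocks` (class, stock, share), `total` (substrate + biomass),
#'   and the distribution evaluators.
#' @examples
#' ss <- steady_state(scenario_steady_state())
#' ss$total
#' @export
steady_state <- function(cfg) {
  pr <- steady_params(cfg)
  g <- polymer_grid(pr$grid$p_min, pr$grid$p_max, pr$grid$dp,
                    pr$grid$uptake_frac)
  cmic <- steady_microbial_biomass(pr$e0, pr$m0, pr$I)
  sols <- lapply(pr$classes, function(cl) {
    tm <- pr$m0 * cl$sig_frac + cl$input_frac * pr$I / cmic
    steady_class_solution(g, cl$tau0, cl$alpha, pr$u0, tm,
                          cl$center_frac, cl$sd_frac)
  })
  stocks <- vapply(sols, `[[`, 0, "stock")
  total <- sum(stocks) + cmic
  structure(
    list(
      c_mic = cmic,
      stocks = tibble::tibble(
        class = names(sols), stock = unname(stocks),
        share = unname(stocks) / total),
      total = total,
      microbial_share = cmic / total,
      solutions = sols, grid = g, params = pr, config = cfg),
    class = "cstability_steady"
  )
}

#' @export
print.cstability_steady <- function(x, ...) {
  cat(sprintf("<cstability_steady> total stock %.4g g_C (biomass %.2g%%)\n",
              x$total, 100 * x$microbial_share))
  print(x$stocks)
  invisible(x)
}

#' Steady polymerization distribution of one class
#'
#' @param cfg a steady-state-compatible [cstability_config()].
#' @param class class name.
#' @return a [polymer_distribution()] on the configuration grid.
#' @export
steady_distribution <- function(cfg, class) {
  ss <- if (inherits(cfg, "cstability_steady")) cfg else steady_state(cfg)
  sol <- ss$solutions[[class]]
  if (is.null(sol)) stop(sprintf("unknown class '%s'", class), call. = FALSE)
  polymer_distribution(ss$grid, pmax(sol$chi(ss$grid$centers), 0))
}

#' Parameter perturbation study of the steady state
#'
#' Recomputes the analytic steady state with one parameter scaled by
#' `1 + delta` for each `delta`, and reports the relative change of the
#' total stock and of every class stock against the reference.  Parameters:
#' `"u0"`, `"e0"`, `"m0"`, `"tau0_<enzyme>"`, `"alpha_<enzyme>"`.
#' A perturbation pushing `e0` to 1 or beyond has no steady state and is
#' flagged with `NA`.
#'
#' @param cfg a steady-state-compatible [cstability_config()].
#' @param parameters character vector of parameter names (default: all).
#' @param deltas relative perturbations (default `c(-0.5, 0.5)`).
#' @return tibble with columns `parameter`, `delta`, `quantity` (class
#'   names, `"microbial_biomass"`, `"total"`), `stock`, `reference` and
#'   `rel_change`.
#' @examples
#' ps <- perturbation_study(scenario_steady_state(), "m0")
#' @export
perturbation_study <- function(cfg, parameters = NULL,
                               deltas = c(-0.5, 0.5)) {
  ref <- steady_state(cfg)
  enz <- names(cfg$enzymes)
  parameters <- parameters %||%
    c("u0", "e0", "m0", paste0("tau0_", enz), paste0("alpha_", enz))
  com_name <- names(cfg$communities)[1]

  perturb <- function(param, delta) {
    cfg2 <- cfg
    f <- 1 + delta
    if (param == "u0") {
      cfg2$communities[[1]]$u0 <- cfg$communities[[1]]$u0 * f
    } else if (param == "e0") {
      e0 <- cfg$communities[[1]]$e0 * f
      if (any(e0 >= 1)) return(NULL)
      cfg2$communities[[1]]$e0 <- e0
    } else if (param == "m0") {
      cfg2$communities[[1]]$m0 <- cfg$communities[[1]]$m0 * f
    } else if (startsWith(param, "tau0_")) {
      e <- sub("^tau0_", "", param)
      cfg2$enzymes[[e]]$tau0 <- cfg$enzymes[[e]]$tau0 * f
    } else if (startsWith(param, "alpha_")) {
      e <- sub("^alpha_", "", param)
      cfg2$enzymes[[e]]$alpha <- cfg$enzymes[[e]]$alpha * f
    } else {
      stop(sprintf("unknown parameter '%s'", param), call. = FALSE)
    }
    steady_state(cfg2)
  }

  ref_tab <- c(stats::setNames(ref$stocks$stock, ref$stocks$class),
               microbial_biomass = ref$c_mic, total = ref$total)
  purrr::map_dfr(parameters, function(param) {
    purrr::map_dfr(deltas, function(delta) {
      ss <- perturb(param, delta)
      new <- if (is.null(ss)) {
        rep(NA_real_, length(ref_tab))
      } else {
        c(stats::setNames(ss$stocks$stock, ss$stocks$class),
          microbial_biomass = ss$c_mic, total = ss$total)[names(ref_tab)]
      }
      tibble::tibble(
        parameter = param, delta = delta, quantity = names(ref_tab),
        stock = unname(new), reference = unname(ref_tab),
        rel_change = unname(new / ref_tab - 1))
    })
  })
}
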