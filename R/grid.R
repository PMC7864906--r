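#' Polymerization grid
#'
#' Discretizes a polymerization interval \eqn{[p_{min}, p_{max}]} into uniform
#' bins.  Every biochemical class lives on such an interval of length two, in
#' its own abstract polymerization coordinate: large `p` means long polymers,
#' small `p` means monomers and small oligomers.  Two sub-domains matter for
#' the dynamics: the microbial uptake domain \eqn{D_u = [p_{min}, p_u)}
#' covering the leftmost `uptake_frac` of the interval (only carbon there can
#' be taken up by microbes), and the enzyme domain `enzyme_domain` on which
#' depolymerization acts (the full interval by default).
#'
#' @param p_min,p_max interval bounds (dimensionless polymerization
#'   coordinate); the interval length is 2 by convention.
#' @param dp grid step (default 0.01); `(p_max - p_min)/dp` must be integral.
#' @param uptake_frac relative length of the uptake domain (default 0.20).
#' @param enzyme_domain length-2 numeric, sub-interval on which enzymes act.
#'
#' @return an object of class `polymer_grid`: a list with `p_min`, `p_max`,
#'   `dp`, bin `edges` (length n+1), bin `centers` (length n), `p_u`,
#'   `in_uptake` (logical per bin, center strictly below `p_u`) and
#'   `in_enzyme` (logical per bin).
#' @examples
#' g <- polymer_grid()
#' sum(g$in_uptake) # 40 of 200 bins
#' @export
polymer_grid <- function(p_min = 0, p_max = 2, dp = 0.01, uptake_frac = 0.2,
                         enzyme_domain = c(p_min, p_max)) {
  stopifnot(p_max > p_min, dp > 0, uptake_frac > 0, uptake_frac < 1)
  n <- (p_max - p_min) / dp
  if (abs(n - round(n)) > 1e-8) {
    stop("`dp` must divide the interval length exactly", call. = FALSE)
  }
  n <- as.integer(round(n))
  if (enzyme_domain[1] < p_min - 1e-12 || enzyme_domain[2] > p_max + 1e-12) {
    stop("`enzyme_domain` must lie within [p_min, p_max]", call. = FALSE)
  }
  edges <- p_min + dp * (0:n)
  centers <- (edges[-1] + edges[-(n + 1)]) / 2
  p_u <- p_min + uptake_frac * (p_max - p_min)
  structure(
    list(
      p_min = p_min, p_max = p_max, dp = dp, n = n,
      edges = edges, centers = centers,
      p_u = p_u,
      in_uptake = centers < p_u,
      in_enzyme = centers > enzyme_domain[1] & centers < enzyme_domain[2]
    ),
    class = "polymer_grid"
  )
}

#' @export
print.polymer_grid <- function(x, ...) {
  cat(sprintf(
    "<polymer_grid> [%g, %g], dp = %g (%d bins), uptake domain [%g, %g)\n",
    x$p_min, x$p_max, x$dp, x$n, x$p_min, x$p_u
  ))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n == b$n && isTRUE(all.equal(c(a$p_min, a$p_max), c(b$p_min, b$p_max)))
}

#' Carbon distribution over a polymerization grid
#'
#' A `polymer_distribution` pairs a [polymer_grid()] with a carbon density
#' (g_C per unit polymerization) evaluated at bin centers.  The carbon held
#' on any sub-interval is the midpoint-rule integral of the density, so a
#' bin's carbon content is `density * dp`.
#'
#' @param grid a [polymer_grid()].
#' @param density numeric vector of length `grid$n`, non-negative.
#' @return an object of class `polymer_distribution`.
#' @export
polymer_distribution <- function(grid, density) {
  stopifnot(inherits(grid, "polymer_grid"), length(density) == grid$n)
  if (any(density < 0)) {
    stop("carbon density must be non-negative", call. = FALSE)
  }
  structure(list(grid = grid, density = as.numeric(density)),
            class = "polymer_distribution")
}

#' @export
print.polymer_distribution <- function(x, ...) {
  cat(sprintf("<polymer_distribution> %d bins, total carbon %.6g\n",
              x$grid$n, total_carbon(x)))
  invisible(x)
}

#' Truncated-Gaussian carbon profile
#'
#' Builds the standard initial (or input) profile: a Gaussian in `p` centred
#' a relative distance `center_frac` below `p_max`, with standard deviation
#' `sd_frac` of the interval length, truncated to the grid and renormalized
#' so that its midpoint-rule integral equals `mass` exactly.  Fresh plant
#' litter and microbial necromass both enter the system with this shape.
#'
#' @param grid a [polymer_grid()].
#' @param mass total carbon (g_C) carried by the profile; must be >= 0.
#' @param center_frac relative distance of the peak below `p_max`
#'   (default 0.25, i.e. peak at `p_max - 0.5` on a length-2 interval).
#' @param sd_frac standard deviation as a fraction of the interval length
#'   (default 0.05, i.e. 0.1 on a length-2 interval).
#' @return a [polymer_distribution()] whose total carbon is exactly `mass`.
#' @examples
#' g <- polymer_grid()
#' d <- gaussian_profile(g, mass = 95)
#' total_carbon(d) # 95
#' @export
gaussian_profile <- function(grid, mass, center_frac = 0.25, sd_frac = 0.05) {
  stopifnot(inherits(grid, "polymer_grid"), sd_frac > 0, sd_frac < 1)
  if (mass < 0) stop("`mass` must be non-negative", call. = FALSE)
  if (mass == 0) {
    return(polymer_distribution(grid, rep(0, grid$n)))
  }
  len <- grid$p_max - grid$p_min
  mu <- grid$p_max - center_frac * len
  sd <- sd_frac * len
  d <- stats::dnorm(grid$centers, mu, sd)
  polymer_distribution(grid, d * mass / (sum(d) * grid$dp))
}

#' Total carbon in a distribution
#'
#' Midpoint-rule integral of the carbon density over the full polymerization
#' interval or a sub-interval.  A bin contributes when its center lies in
#' `[domain[1], domain[2])`, matching the half-open convention used for the
#' uptake domain, so the integral is additive over disjoint domains.
#'
#' @param dist a [polymer_distribution()].
#' @param domain optional length-2 numeric sub-interval of the grid.
#' @return carbon mass (g_C).
#' @export
total_carbon <- function(dist, domain = NULL) {
  stopifnot(inherits(dist, "polymer_distribution"))
  g <- dist$grid
  if (is.null(domain)) {
    return(sum(dist$density) * g$dp)
  }
  stopifnot(length(domain) == 2)
  if (domain[1] < g$p_min - 1e-9 || domain[2] > g$p_max + 1e-9) {
    stop("`domain` must lie within the grid interval", call. = FALSE)
  }
  sel <- g$centers >= domain[1] & g$centers < domain[2]
  sum(dist$density[sel]) * g$dp
}

#' Carbon available for microbial uptake
#'
#' Integral of the density over the uptake domain \eqn{D_u}.
#' @param dist a [polymer_distribution()].
#' @return carbon mass (g_C) accessible to microbial uptake.
#' @export
uptake_carbon <- function(dist) {
  sum(dist$density[dist$grid$in_uptake]) * dist$grid$dp
}
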