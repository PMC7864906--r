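#' Cleavage kernel density
#'
#' Density of the depolymerization kernel \eqn{K(p, p')}: the probability
#' density that carbon sitting at polymerization \eqn{p'} lands at \eqn{p}
#' after one enzymatic fragmentation event,
#' \deqn{K(p, p') = 1_{p \le p'} (\alpha + 1)
#'   \frac{(p - p_{min})^{\alpha}}{(p' - p_{min})^{\alpha + 1}}.}
#' Carbon never moves to higher polymerization and the kernel integrates to
#' one over \eqn{p}, so fragmentation redistributes carbon without creating
#' or destroying it.  Low `alpha` (endo-cleavage, random bond scission)
#' spreads fragments over the whole of \eqn{[p_{min}, p']}; high `alpha`
#' (exo-cleavage, end-member attack) leaves most carbon close to \eqn{p'}.
#'
#' @param p destination polymerization (vectorized).
#' @param p_prime source polymerization; must exceed `p_min`.
#' @param alpha cleavage factor, >= 0.
#' @param p_min lower bound of the polymerization interval.
#' @return kernel density values (units 1/p).
#' @examples
#' kernel_density(0.5, 1, alpha = 1, p_min = 0) # 1
#' @export
kernel_density <- function(p, p_prime, alpha, p_min = 0) {
  stopifnot(alpha >= 0, length(p_prime) == 1)
  if (p_prime <= p_min) {
    stop("`p_prime` must be strictly above `p_min` (degenerate source)",
         call. = FALSE)
  }
  out <- ifelse(
    p <= p_prime & p >= p_min,
    (alpha + 1) * (p - p_min)^alpha / (p_prime - p_min)^(alpha + 1),
    0
  )
  as.numeric(out)
}

#' Discrete cleavage operator
#'
#' Builds the matrix form of the cleavage kernel on a grid: entry (i, j) is
#' the fraction of one fragmentation event's carbon that moves from source
#' bin j to destination bin i.  Weights are exact analytic integrals of the
#' kernel over destination bins (the kernel CDF
#' \eqn{((p - p_{min})/(p' - p_{min}))^{\alpha+1}} evaluated at bin edges),
#' with the source evaluated at its bin center and any destination mass
#' falling inside the source bin kept on the diagonal.  Every column
#' therefore sums to exactly one, which is what makes the discretized
#' enzymatic flux conservative to machine precision.  The first bin cannot
#' fragment further and is an identity column.  Columns outside the grid's
#' enzyme domain are identity as well (no enzymatic action there).
#'
#' @param grid a [polymer_grid()].
#' @param alpha cleavage factor, >= 0.
#' @return an n x n matrix of class `cleavage_operator` with attributes
#'   `alpha` and `grid`.
#' @export
cleavage_operator <- function(grid, alpha) {
  stopifnot(inherits(grid, "polymer_grid"), alpha >= 0)
  n <- grid$n
  K <- matrix(0, n, n)
  lo_all <- grid$edges[-(n + 1)] - grid$p_min
  hi_all <- grid$edges[-1] - grid$p_min
  for (j in seq_len(n)) {
    if (j == 1L || !grid$in_enzyme[j]) {
      K[j, j] <- 1
      next
    }
    cj <- grid$centers[j] - grid$p_min
    # CDF differences over destination bins, clipped at the source center
    w <- (pmin(hi_all, cj)^(alpha + 1) - pmin(lo_all, cj)^(alpha + 1)) /
      cj^(alpha + 1)
    if (j < n) w[(j + 1):n] <- 0
    K[, j] <- w
  }
  structure(K, alpha = alpha, grid = grid, class = c("cleavage_operator", "matrix"))
}

#' Enzymatic depolymerization rate
#'
#' The realized rate of an enzyme family, Eq.-style linear in the biomass of
#' the communities that produce it:
#' \eqn{\tau(t) = \tau^0 \sum_{mic} w_{mic} C_{mic}(t)}.
#'
#' @param tau0 action rate per unit of microbial carbon (1/(g_C d)).
#' @param biomasses numeric vector of producer biomasses (g_C).
#' @param weights producer weights (default all 1).
#' @return rate in 1/d.
#' @examples
#' enzyme_rate(1.8, 5) # 9
#' @export
enzyme_rate <- function(tau0, biomasses, weights = rep(1, length(biomasses))) {
  stopifnot(tau0 >= 0, all(biomasses >= 0), length(weights) == length(biomasses))
  tau0 * sum(weights * biomasses)
}

#' Enzymatic flux on a distribution
#'
#' The rate of change of a carbon density under depolymerization: carbon
#' leaves every bin of the enzyme domain at rate `rate` and is redistributed
#' to lower polymerization through the cleavage operator.  The flux
#' integrates to zero over the interval -- enzymes change the shape of the
#' distribution, never its total carbon.
#'
#' @param dist a [polymer_distribution()].
#' @param op a [cleavage_operator()] built on the same grid.
#' @param rate realized enzymatic rate (1/d), see [enzyme_rate()].
#' @return numeric vector: flux density (g_C / p / d) at bin centers.
#' @export
depolymerization_flux <- function(dist, op, rate) {
  stopifnot(inherits(dist, "polymer_distribution"),
            inherits(op, "cleavage_operator"), rate >= 0)
  g <- attr(op, "grid")
  if (!same_grid(dist$grid, g)) {
    stop("distribution and operator grids differ", call. = FALSE)
  }
  chi <- dist$density
  # identity columns (first bin, outside enzyme domain) contribute no net flux
  as.vector(rate * (op %*% chi - chi))
}

#' Mean polymerization of a distribution
#'
#' First moment \eqn{\int p \chi(p) dp / \int \chi(p) dp}; decreases
#' monotonically under depolymerization alone.
#' @param dist a [polymer_distribution()].
#' @return mean polymerization coordinate.
#' @export
mean_polymerization <- function(dist) {
  m <- sum(dist$density) * dist$grid$dp
  if (m <= 0) return(NA_real_)
  sum(dist$grid$centers * dist$density) * dist$grid$dp / m
}
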