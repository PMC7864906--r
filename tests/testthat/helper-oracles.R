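# Independent oracles and small fixtures used across tests.

# analytic kernel CDF: fraction of one event's carbon below p
kernel_cdf <- function(p, p_prime, alpha, p_min = 0) {
  ((p - p_min) / (p_prime - p_min))^(alpha + 1)
}

# discrete steady state by direct linear solve of the stationary balance
# tau0 (K - I) chi - u0 1_Du chi = -theta  (independent of the quadrature
# route used by steady_state())
solve_steady_discrete <- function(grid, tau0, alpha, u0, theta) {
  K <- unclass(cleavage_operator(grid, alpha))
  M <- tau0 * (K - diag(grid$n))
  diag(M)[grid$in_uptake] <- diag(M)[grid$in_uptake] - u0
  solve(M, -theta)
}

# minimal trajectory object with a prescribed class-carbon time series,
# for exercising summary statistics without running the solver
fake_sim <- function(time, carbon, class = "x") {
  structure(
    list(pools = tibble::tibble(time = time, class = class,
                                accessible = carbon, inaccessible = 0,
                                uptake_available = 0),
         plan = list(class_names = class[1])),
    class = "cstability_sim")
}

random_density <- function(grid, seed) {
  set.seed(seed)
  stats::runif(grid$n) + 0.1
}
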