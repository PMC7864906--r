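cfg4 <- scenario_steady_state()

test_that("steady microbial biomass follows the closed form", {
  expect_equal(steady_microbial_biomass(0.5, 0.02, 1), 1 / 0.02)
  expect_equal(steady_microbial_biomass(0.4, 0.02, 2.74e-4),
               0.4 * 2.74e-4 / (0.6 * 0.02), tolerance = 1e-12)
  expect_error(steady_microbial_biomass(1, 0.02, 1), "no steady state")
})

test_that("theta profiles integrate to their source masses", {
  g <- polymer_grid(dp = 1e-3)
  intg <- function(cl) sum(theta_profile(cfg4, cl, g$centers)) * g$dp
  # plant classes: m0 (1 - e0) fraction / e0
  expect_equal(intg("lignin"), 0.02 * 0.6 * 0.24 / 0.4, tolerance = 1e-6)
  expect_equal(intg("plant_sugar"), 0.02 * 0.6 * 0.76 / 0.4,
               tolerance = 1e-6)
  # microbial classes: m0 * signature fraction
  expect_equal(intg("mic_sugar"), 0.02 * 0.5, tolerance = 1e-6)
  expect_equal(intg("protein"), 0.02 * 0.2, tolerance = 1e-6)
})

test_that("a class with neither input nor signature has theta = 0", {
  cfg <- cfg4
  cfg$classes$lipid$input_accessible <- 0
  cfg$communities$general_decomposer$signature <-
    c(mic_sugar = 0.5, protein = 0.2)
  expect_equal(theta_profile(cfg, "lipid", seq(0.1, 1.9, 0.2)),
               rep(0, 10))
})

test_that("without uptake the two branch formulas coincide", {
  g <- polymer_grid()
  sol <- cstability:::steady_class_solution(g, tau0 = 0.36, alpha = 5,
                                            u0 = 0, theta_mass = 0.02)
  fns <- cstability:::profile_fns(g, 0.25, 0.05)
  p <- c(0.05, 0.2, 0.39)  # inside the uptake domain
  chi_hi_form <- 0.02 * fns$phi(p) / 0.36 +
    6 / p * 0.02 * fns$upper(p) / 0.36
  expect_equal(sol$chi(p), chi_hi_form, tolerance = 1e-6)
})

test_that("analytic steady state matches an independent discrete solve", {
  ss <- steady_state(cfg4)
  g <- ss$grid
  pr <- ss$params
  for (cl in pr$classes) {
    theta <- pr$m0 * cl$sig_frac * gaussian_profile(g, 1)$density +
      cl$input_frac * pr$I / ss$c_mic * gaussian_profile(g, 1)$density
    chi_disc <- solve_steady_discrete(g, cl$tau0, cl$alpha, pr$u0, theta)
    stock_disc <- sum(chi_disc) * g$dp
    stock_quad <- ss$stocks$stock[ss$stocks$class == cl$name]
    expect_equal(stock_quad, stock_disc, tolerance = 5e-3)
  }
  # global balance: total uptake-domain carbon supports the biomass
  u_tot <- sum(vapply(pr$classes, function(cl) {
    theta <- (pr$m0 * cl$sig_frac + cl$input_frac * pr$I / ss$c_mic) *
      gaussian_profile(g, 1)$density
    chi <- solve_steady_discrete(g, cl$tau0, cl$alpha, pr$u0, theta)
    sum(chi[g$in_uptake]) * g$dp
  }, 0))
  expect_equal(u_tot, pr$m0 / (pr$u0 * pr$e0), tolerance = 1e-10)
})

test_that("the steady distributions are fixed points of the dynamics", {
  ss <- steady_state(cfg4)
  plan <- cstability:::compile_plan(cfg4)
  chi <- vapply(names(cfg4$classes), function(cl) {
    steady_distribution(ss, cl)$density
  }, numeric(plan$n))
  st <- list(chi_ac = chi, chi_in = matrix(0, plan$n, plan$n_class),
             biomass = ss$c_mic)
  d <- state_derivative(cfg4, st)
  # per-class net rates vanish relative to the gross input flux
  net <- colSums(d$chi_ac) * plan$dp
  expect_lt(max(abs(net)), 0.05 * 2.74e-4)
  expect_equal(unname(d$biomass), 0,
               tolerance = 0.02 * plan$m0[1] * ss$c_mic)
})

test_that("a dynamic run started at the steady state stays there", {
  ss <- steady_state(cfg4)
  plan <- cstability:::compile_plan(cfg4)
  chi <- vapply(names(cfg4$classes), function(cl) {
    steady_distribution(ss, cl)$density
  }, numeric(plan$n))
  sim <- simulate_cstability(
    cfg4, t_end = 2000, dt = 0.5, output_every = 100,
    snapshot_times = numeric(),
    initial_state = list(chi_ac = chi,
                         chi_in = matrix(0, plan$n, plan$n_class),
                         biomass = ss$c_mic))
  final <- dplyr::filter(sim$pools, time == max(time))
  expect_equal(final$accessible,
               ss$stocks$stock[match(final$class, ss$stocks$class)],
               tolerance = 0.01)
  expect_equal(utils::tail(sim$organisms$biomass, 1), ss$c_mic,
               tolerance = 0.01)
})

test_that("perturbations obey the analytic invariances", {
  ps <- perturbation_study(cfg4, c("m0", "e0", "u0"))
  get <- function(param, delta, quantity) {
    ps$rel_change[ps$parameter == param & ps$delta == delta &
                    ps$quantity == quantity]
  }
  # substrate stocks scale linearly with m0 at fixed composition
  for (cl in c("plant_sugar", "lignin", "lipid", "protein", "mic_sugar")) {
    expect_equal(get("m0", -0.5, cl), -0.5, tolerance = 1e-9)
    expect_equal(get("m0", 0.5, cl), 0.5, tolerance = 1e-9)
  }
  # microbe-derived classes are invariant to e0
  for (cl in c("lipid", "protein", "mic_sugar")) {
    expect_equal(get("e0", 0.5, cl), 0, tolerance = 1e-9)
    expect_equal(get("e0", -0.5, cl), 0, tolerance = 1e-9)
  }
  # stocks are insensitive to u0 within a wide band (uptake-limited regime)
  expect_lt(abs(get("u0", 0.5, "total")), 0.01)
  # biomass itself is untouched by u0 and m0-compensated
  expect_equal(get("u0", 0.5, "microbial_biomass"), 0, tolerance = 1e-12)
})

test_that("perturbations without a steady state are flagged, not computed", {
  ps <- perturbation_study(cfg4, "e0", deltas = c(0.5, 2))
  expect_true(all(is.na(ps$stock[ps$delta == 2])))
  expect_false(anyNA(ps$stock[ps$delta == 0.5]))
})

test_that("steady-state tidiers expose stocks and shares", {
  ss <- steady_state(cfg4)
  td <- tidy(ss)
  expect_equal(sum(td$share), 1, tolerance = 1e-9)
  expect_true(all(td$stock >= 0))
  expect_s3_class(autoplot(ss), "ggplot")
  expect_equal(glance(ss)$total, ss$total)
})
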