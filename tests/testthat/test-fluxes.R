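grid1 <- polymer_grid()

test_that("uptake flux is restricted to the uptake domain", {
  d <- polymer_distribution(grid1, random_density(grid1, 7))
  fl <- uptake_flux(d, u0 = 5, biomass = 2)
  expect_true(all(fl[!grid1$in_uptake] == 0))
  expect_equal(sum(fl) * grid1$dp, 5 * 2 * uptake_carbon(d),
               tolerance = 1e-12)
  expect_equal(uptake_flux(d, u0 = 0, biomass = 2), rep(0, grid1$n))
  expect_equal(uptake_flux(d, u0 = 5, biomass = 0), rep(0, grid1$n))
})

test_that("necromass returns with the community signature", {
  com <- microbial_community("mic_decomposer", biomass = 5, e0 = 0.5,
                             m0 = 0.01,
                             u0 = c(mic_sugar = 5, lipid = 5, protein = 5),
                             signature = c(mic_sugar = 0.5, lipid = 0.3,
                                           protein = 0.2))
  fluxes <- vapply(c("mic_sugar", "lipid", "protein"), function(cl) {
    sum(necromass_flux(grid1, com, cl)) * grid1$dp
  }, 0)
  # total necromass rate 0.05 g_C/d split 50/30/20
  expect_equal(sum(fluxes), 0.01 * 5, tolerance = 1e-12)
  expect_equal(unname(fluxes / sum(fluxes)), c(0.5, 0.3, 0.2),
               tolerance = 1e-12)
  expect_equal(necromass_flux(grid1, com, "lipid", biomass = 0),
               rep(0, grid1$n))
  # class absent from the signature receives nothing
  expect_equal(sum(necromass_flux(grid1, com, "lignin")), 0)
})

test_that("accessibility transfers preserve shape and class carbon", {
  ac <- polymer_distribution(grid1, random_density(grid1, 2))
  inx <- polymer_distribution(grid1, random_density(grid1, 3))
  fl <- accessibility_fluxes(ac, inx, to_accessible = 0.2,
                             to_inaccessible = 0.05)
  expect_equal(fl$to_ac, 0.2 * inx$density)
  expect_equal(fl$to_in, 0.05 * ac$density)
  # net class carbon change from the transfer pair is zero
  net_ac <- fl$to_ac - fl$to_in
  net_in <- fl$to_in - fl$to_ac
  expect_equal(sum(net_ac + net_in), 0)
  z <- accessibility_fluxes(ac, inx, 0, 0)
  expect_equal(z$to_ac, rep(0, grid1$n))
  expect_equal(z$to_in, rep(0, grid1$n))
})

test_that("biomass decays purely when no substrate is available", {
  cfg <- scenario_cellulose()
  cfg$classes$plant_sugar$accessible <- 0
  d <- state_derivative(cfg)
  expect_equal(unname(d$biomass), -0.02 * 5, tolerance = 1e-12)
  expect_equal(d$co2, 0)
  expect_equal(sum(d$chi_ac), 0)
})

test_that("uptake splits exactly into assimilation and respiration", {
  cfg <- scenario_cellulose()
  # move some carbon into the uptake domain so uptake is active
  plan <- cstability:::compile_plan(cfg)
  chi <- matrix(gaussian_profile(plan$grid, 95, center_frac = 0.9)$density)
  st <- list(chi_ac = chi, chi_in = matrix(0, plan$n, 1), biomass = 5)
  d <- state_derivative(cfg, st)
  upt <- 5 * (5 / 100) * sum(chi[plan$du, 1]) * plan$dp  # u0*(B/ref)*U
  mort <- 0.02 * 5
  expect_equal(unname(d$biomass), -mort + 0.4 * upt, tolerance = 1e-10)
  expect_equal(d$co2, 0.6 * upt, tolerance = 1e-10)
  expect_equal(unname(d$residues), mort, tolerance = 1e-12)
})

test_that("the assembled derivative conserves carbon: d(total)/dt = input", {
  # closed batch system
  d1 <- state_derivative(scenario_succession(TRUE))
  tot1 <- sum(d1$chi_ac) * 0.01 + sum(d1$chi_in) * 0.01 +
    sum(d1$biomass) + d1$co2 + sum(d1$residues)
  expect_lt(abs(tot1), 1e-12)
  # constant-input system
  cfg <- scenario_steady_state()
  d2 <- state_derivative(cfg)
  tot2 <- sum(d2$chi_ac) * 0.01 + sum(d2$chi_in) * 0.01 +
    sum(d2$biomass) + d2$co2 + sum(d2$residues)
  expect_equal(tot2, 2.74e-4, tolerance = 1e-10)
})

test_that("invalid states are rejected with a diagnostic", {
  cfg <- scenario_cellulose()
  plan <- cstability:::compile_plan(cfg)
  st <- list(chi_ac = matrix(NaN, plan$n, 1), chi_in = matrix(0, plan$n, 1),
             biomass = 5)
  expect_error(state_derivative(cfg, st), "invalid state")
  st2 <- list(chi_ac = matrix(0, plan$n, 1), chi_in = matrix(0, plan$n, 1),
              biomass = -1)
  expect_error(state_derivative(cfg, st2), "invalid state")
})
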