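test_that("a system with no microbes and no input stays frozen", {
  cfg <- scenario_cellulose()
  cfg$communities$plant_decomposer$biomass <- 0
  sim <- simulate_cstability(cfg, t_end = 20)
  p <- dplyr::filter(sim$pools, class == "plant_sugar")
  expect_equal(p$accessible, rep(95, nrow(p)), tolerance = 1e-12)
  expect_equal(max(sim$co2$co2), 0)
})

test_that("closed-system carbon is conserved along the trajectory", {
  sim <- simulate_cstability(scenario_cellulose())
  expect_lt(glance(sim)$closure_error, 1e-6)
  tot <- total_system_carbon(sim)
  expect_equal(tot$total_carbon[1], 100, tolerance = 1e-10)
  # cumulative CO2 never decreases
  expect_true(all(diff(sim$co2$co2) >= 0))
})

test_that("with constant input the carbon budget grows at the input rate", {
  cfg <- scenario_steady_state()
  sim <- simulate_cstability(cfg, t_end = 500, dt = 0.5, output_every = 50,
                             snapshot_times = numeric())
  expect_lt(glance(sim)$closure_error, 1e-6)
  tot <- total_system_carbon(sim)
  slope <- diff(range(tot$total_carbon)) / diff(range(tot$time))
  expect_equal(slope, 2.74e-4, tolerance = 1e-6)
})

test_that("compiled and R reference engines agree", {
  # incl. the gated-transfer and multi-pool paths (lignocellulose)
  for (cfg in list(scenario_cellulose(), scenario_lignocellulose())) {
    cfg$grid$dp <- 0.04
    a <- simulate_cstability(cfg, t_end = 15, engine = "compiled")
    b <- simulate_cstability(cfg, t_end = 15, engine = "R")
    expect_equal(a$pools$accessible, b$pools$accessible, tolerance = 1e-10)
    expect_equal(a$pools$inaccessible, b$pools$inaccessible,
                 tolerance = 1e-10)
    expect_equal(a$organisms$biomass, b$organisms$biomass,
                 tolerance = 1e-10)
    expect_equal(a$co2$co2, b$co2$co2, tolerance = 1e-10)
  }
})

test_that("trajectories converge under time-step refinement", {
  cfg <- scenario_cellulose()
  f <- function(dt) {
    sim <- simulate_cstability(cfg, t_end = 60, dt = dt,
                               snapshot_times = numeric())
    p <- dplyr::filter(sim$pools, class == "plant_sugar")
    c(utils::tail(p$accessible, 1),
      utils::tail(sim$organisms$biomass, 1))
  }
  expect_equal(f(0.2), f(0.1), tolerance = 1e-3)
})

test_that("trajectories converge under grid refinement", {
  f <- function(dp) {
    cfg <- scenario_cellulose()
    cfg$grid$dp <- dp
    sim <- simulate_cstability(cfg, t_end = 60, snapshot_times = numeric())
    p <- dplyr::filter(sim$pools, class == "plant_sugar")
    c(utils::tail(p$accessible, 1),
      utils::tail(sim$organisms$biomass, 1))
  }
  expect_equal(f(0.02), f(0.01), tolerance = 2e-3)
})

test_that("densities and biomasses stay non-negative in all scenarios", {
  for (cfg in list(scenario_cellulose(), scenario_lignocellulose())) {
    sim <- simulate_cstability(cfg)
    expect_true(all(sim$pools$accessible >= -1e-10))
    expect_true(all(sim$pools$inaccessible >= -1e-10))
    expect_true(all(sim$organisms$biomass >= 0))
    expect_true(all(sim$snapshots$density >= -1e-10))
  }
})

test_that("decomposition is uptake-saturated: u0 barely matters, tau0 does", {
  resid100 <- function(mutate) {
    cfg <- mutate(scenario_cellulose())
    sim <- simulate_cstability(cfg, t_end = 100, snapshot_times = numeric())
    p <- dplyr::filter(sim$pools, class == "plant_sugar")
    utils::tail(p$accessible, 1)
  }
  base <- resid100(identity)
  d_u <- abs(resid100(function(cfg) {
    cfg$communities$plant_decomposer$u0 <- c(plant_sugar = 5 * 1.05); cfg
  }) - base)
  d_tau <- abs(resid100(function(cfg) {
    cfg$enzymes$cellulolysis$tau0 <- 1.8 * 1.05; cfg
  }) - base)
  expect_lt(d_u, d_tau / 10)
})

test_that("mean residence time recovers closed forms", {
  # pure exponential decay with rate k: MRT = 1/k
  t <- seq(0, 400, by = 0.5)
  expect_equal(mean_residence_time(fake_sim(t, 10 * exp(-0.05 * t))), 20,
               tolerance = 1e-3)
  # combined pools: initial-carbon-weighted mean of the pool MRTs
  two <- 8 * exp(-0.1 * t) + 2 * exp(-0.05 * t)
  expect_equal(mean_residence_time(fake_sim(t, two)),
               0.8 * 10 + 0.2 * 20, tolerance = 1e-2)
  # non-decayed trajectories are refused
  short <- fake_sim(seq(0, 5, 0.5), 10 * exp(-0.05 * seq(0, 5, 0.5)))
  expect_error(mean_residence_time(short), "decayed")
})

test_that("depletion_time interpolates threshold crossings", {
  t <- 0:100
  sim <- fake_sim(t, 100 * exp(-0.1 * t))
  expect_equal(depletion_time(sim, fraction = 0.05), log(20) / 0.1,
               tolerance = 0.05)
  expect_true(is.na(depletion_time(sim, fraction = 1e-9)))
})

test_that("t_end = 0 returns the initial state only", {
  sim <- simulate_cstability(scenario_cellulose(), t_end = 0)
  expect_equal(length(sim$times), 1L)
  expect_equal(total_system_carbon(sim)$total_carbon, 100, tolerance = 1e-10)
})

test_that("tidy/glance/autoplot provide the standard views", {
  sim <- simulate_cstability(scenario_cellulose(), t_end = 5)
  td <- tidy(sim)
  expect_named(td, c("time", "class", "pool", "carbon"))
  expect_setequal(unique(td$pool),
                  c("accessible", "inaccessible", "uptake_available",
                    "biomass", "residues", "co2"))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_distributions(sim), "ggplot")
  expect_equal(nrow(glance(sim)), 1L)
})
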