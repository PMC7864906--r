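test_that("scenario builders are pure and validate", {
  for (b in list(scenario_cellulose, scenario_lignocellulose,
                 scenario_succession, scenario_steady_state)) {
    cfg1 <- b(); cfg2 <- b()
    expect_identical(cfg1, cfg2)
    expect_silent(validate_config(cfg1))
  }
})

test_that("cellulose scenario starts from 95 + 5 g_C", {
  cfg <- scenario_cellulose()
  expect_equal(cfg$classes$plant_sugar$accessible, 95)
  expect_equal(cfg$communities$plant_decomposer$biomass, 5)
  expect_equal(cfg$reference_mass, 100)
  sim0 <- simulate_cstability(cfg, t_end = 0)
  expect_equal(total_system_carbon(sim0)$total_carbon, 100,
               tolerance = 1e-10)
  p <- dplyr::filter(sim0$pools, class == "plant_sugar")
  expect_equal(p$accessible + p$inaccessible, 95, tolerance = 1e-10)
})

test_that("lignocellulose scenario embeds cellulose in lignin", {
  cfg <- scenario_lignocellulose()
  expect_equal(cfg$classes$plant_sugar$accessible, 0)
  expect_equal(cfg$classes$plant_sugar$inaccessible, 95)
  expect_equal(cfg$classes$lignin$accessible, 30)
  gate <- cfg$classes$plant_sugar$to_accessible
  expect_s3_class(gate, "cs_gate")
  expect_equal(gate$coef, 13)
  expect_equal(gate$enzyme, "lignolysis")
})

test_that("the gated transfer rate follows the lignolytic activity", {
  cfg <- scenario_lignocellulose()
  d0 <- state_derivative(cfg)
  # initial transfer flux = 13 * tau0_lig * (B/ref) * C_lig_ac * chi_in
  plan <- cstability:::compile_plan(cfg)
  rate <- 13 * 1 * (5 / 100) * (30 / 100)
  expect_equal(sum(d0$chi_in[, 1]) * plan$dp, -rate * 95, tolerance = 1e-9)
  # shape is preserved: transfer flux proportional to the inaccessible pool
  chi_in <- plan$state0[seq_len(plan$n) + plan$n] * plan$ref  # g_C / p
  expect_equal(d0$chi_ac[, 1], unname(rate * chi_in), tolerance = 1e-9)
})

test_that("succession scenario wires cross-feeding through the cheating flag", {
  nc <- scenario_succession(FALSE)
  ch <- scenario_succession(TRUE)
  expect_equal(unname(nc$communities$mic_decomposer$u0[c("plant_sugar",
                                                         "lignin")]),
               c(0, 0))
  expect_equal(unname(ch$communities$mic_decomposer$u0[c("plant_sugar",
                                                         "lignin")]),
               c(3, 3))
  expect_equal(unname(ch$communities$plant_decomposer$u0[c("mic_sugar",
                                                           "lipid",
                                                           "protein")]),
               c(3, 3, 3))
  for (m in nc$communities) expect_equal(sum(m$signature), 1)
  # both communities share the 50/30/20 signature
  expect_equal(nc$communities$plant_decomposer$signature,
               nc$communities$mic_decomposer$signature)
})

test_that("steady-state scenario uses in-situ rates and areal input", {
  cfg <- scenario_steady_state()
  expect_equal(cfg$reference_mass, 1)
  taus <- vapply(cfg$enzymes, `[[`, 0, "tau0")
  expect_equal(unname(taus[c("cellulolysis", "lignolysis", "lipidolysis",
                             "proteolysis", "mic_sugar_lysis")]),
               c(0.36, 0.2, 0.16, 0.36, 0.36))
  alphas <- vapply(cfg$enzymes, `[[`, 0, "alpha")
  expect_equal(unname(alphas[c("cellulolysis", "lignolysis", "lipidolysis",
                               "proteolysis", "mic_sugar_lysis")]),
               c(5, 7, 1.5, 5.5, 5))
  I <- sum(vapply(cfg$classes, `[[`, 0, "input_accessible"))
  expect_equal(I, 2.74e-4, tolerance = 1e-12)
  expect_equal(cfg$classes$plant_sugar$input_accessible / I, 0.76)
})

test_that("builders round-trip through the YAML fixtures", {
  for (nm in c("cellulose", "lignocellulose", "succession",
               "succession_cheating", "steady_state")) {
    path <- system.file("extdata", paste0(nm, ".yaml"),
                        package = "cstability")
    expect_true(nzchar(path))
    cfg <- config_read(path)
    builder <- switch(nm,
      cellulose = scenario_cellulose(),
      lignocellulose = scenario_lignocellulose(),
      succession = scenario_succession(FALSE),
      succession_cheating = scenario_succession(TRUE),
      steady_state = scenario_steady_state())
    expect_equal(cfg, builder, tolerance = 1e-12)
    # a further write/read cycle is lossless
    tmp <- withr::local_tempfile(fileext = ".yaml")
    config_write(cfg, tmp)
    expect_equal(config_read(tmp), cfg, tolerance = 1e-12)
  }
})
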