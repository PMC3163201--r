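# Synthetic plate generator: growth law, reporter kinetics, determinism.

test_that("logistic growth matches the ODE solution and its degenerate limits", {
  des <- plate_design(seed = 1)
  # carrying capacity equal to the inoculum: no net growth
  flat <- simulate_growth(des, growth_params(od_initial = 0.01, od_max = 0.01))
  expect_true(all(flat$od == 0.01))
  # zero growth rate
  still <- simulate_growth(des, growth_params(od_initial = 0.005,
                                              growth_rate = 0))
  expect_true(all(still$od == 0.005))

  # independent oracle: numerical integration of dOD/dt = r OD (1 - OD/K)
  gp <- growth_params(od_initial = 0.005, od_max = 0.5, growth_rate = 0.7)
  od <- simulate_growth(des, gp)
  sol <- deSolve::ode(
    y = c(od = gp$od_initial), times = od$time_h,
    func = function(t, y, p) list(p$r * y * (1 - y / p$K)),
    parms = list(r = gp$growth_rate, K = gp$od_max),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(od$od, unname(sol[, "od"]), tolerance = 1e-7)

  # closed-form logistic value at a chosen time
  t0 <- 6
  oracle <- 0.5 / (1 + (0.5 - 0.005) / 0.005 * exp(-0.7 * t0))
  expect_equal(od$od[od$time_h == t0], oracle, tolerance = 1e-9)

  expect_true(all(diff(od$od) > 0))  # strictly increasing towards plateau
  expect_error(growth_params(od_initial = NaN), "finite")
  expect_error(growth_params(od_initial = 0.6, od_max = 0.5), "exceed")
})

test_that("reporter kinetics follow dGFP/dt = PA*OD plus autofluorescence", {
  des <- plate_design(seed = 1)
  od <- simulate_growth(des)
  # promoterless, zero noise: GFP is pure autofluorescence, 100 * OD(t)
  w0 <- simulate_reporter(od, 0, 0, noise = noiseless(100),
                          genotype = "promoterless")
  expect_equal(w0$gfp, 100 * od$od, tolerance = 1e-12)

  # constant OD = 0.1, PA = 50, no autofluorescence: GFP(t) = 5 t
  odc <- constant_od_series(0.1)
  w1 <- simulate_reporter(odc, 50, 1, noise = noiseless(0),
                          genotype = "mutant_noNAR")
  expect_equal(w1$gfp, 5 * odc$time_h, tolerance = 1e-12)

  expect_error(simulate_reporter(odc, 50, -1, noise = noiseless(0)),
               "nonnegative")

  # same seed reproduces the noisy trace exactly
  a <- simulate_reporter(od, 100, 1, seed = 9, genotype = "mutant_noNAR")
  b <- simulate_reporter(od, 100, 1, seed = 9, genotype = "mutant_noNAR")
  expect_identical(a, b)
})

test_that("plate layout, determinism and per-well noise streams", {
  des <- plate_design(seed = 3)
  plate <- generate_experiment(des, model_spec_hill(1000, 42, 1.9))
  # 12 concentrations x 2 reporter genotypes x 3 replicates + 3 background
  expect_identical(length(unique(plate$well_id)), 75L)
  expect_identical(sum(plate$genotype == "promoterless") /
                     length(unique(plate$time_h)), 3)

  # byte-identical regeneration with the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_plate_csv(plate, f1)
  write_plate_csv(generate_experiment(des, model_spec_hill(1000, 42, 1.9)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # a different seed gives different noise
  des2 <- plate_design(seed = 4)
  plate2 <- generate_experiment(des2, model_spec_hill(1000, 42, 1.9))
  expect_false(identical(plate$gfp, plate2$gfp))

  # adding concentrations must not perturb existing wells' noise draws
  des_small <- plate_design(concentrations = c(0, 1, 10),
                            genotypes = c("mutant_noNAR", "promoterless"),
                            seed = 3)
  des_big <- plate_design(concentrations = c(0, 1, 5, 10),
                          genotypes = c("mutant_noNAR", "promoterless"),
                          seed = 3)
  ps <- generate_experiment(des_small, model_spec_hill(1000, 42, 1.9))
  pb <- generate_experiment(des_big, model_spec_hill(1000, 42, 1.9))
  for (conc in c(0, 1, 10)) {
    gs <- ps$gfp[ps$arabinose_mM == conc & ps$genotype == "mutant_noNAR"]
    gb <- pb$gfp[pb$arabinose_mM == conc & pb$genotype == "mutant_noNAR"]
    expect_identical(gs, gb)
  }

  expect_error(generate_experiment(des, list(name = "nonsense")),
               "unknown model")
})

test_that("noiseless GFP increments are ordered by the Hill input", {
  des <- plate_design(concentrations = c(0, 1, 10),
                      genotypes = c("mutant_noNAR", "promoterless"),
                      replicates_per_condition = 1, seed = 1)
  plate <- generate_experiment(des, model_spec_hill(1000, 42, 1.9),
                               noise = noiseless())
  inc <- sapply(c(0, 1, 10), function(conc) {
    g <- plate$gfp[plate$arabinose_mM == conc &
                     plate$genotype == "mutant_noNAR"]
    o <- plate$od[plate$arabinose_mM == conc &
                    plate$genotype == "mutant_noNAR"]
    # subtract the shared autofluorescence term before comparing
    sum(diff(g - 100 * o))
  })
  expect_true(inc[1] < inc[2] && inc[2] < inc[3])
})

test_that("plate CSV round-trips through read/write", {
  des <- plate_design(concentrations = c(0, 1), replicates_per_condition = 1,
                      genotypes = c("mutant_noNAR", "promoterless"), seed = 2)
  plate <- generate_experiment(des, model_spec_hill(1000, 42, 1.9))
  f <- tempfile(fileext = ".csv")
  write_plate_csv(plate, f)
  back <- read_plate_csv(f)
  expect_equal(back$gfp, plate$gfp, tolerance = 1e-12)
  expect_identical(back$genotype, plate$genotype)
})
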