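# Promoter-activity extraction: background subtraction, dGFP/dt/OD, and
# round trips against the generating input function.

test_that("background subtraction removes the time-matched control mean", {
  t <- seq(0, 10, by = 0.5)
  well <- data.frame(time_h = t, od = 0.1, gfp = 300)
  bg1 <- data.frame(time_h = t, od = 0.1, gfp = 90)
  bg2 <- data.frame(time_h = t, od = 0.1, gfp = 110)
  out <- subtract_background(well, list(bg1, bg2))
  expect_equal(out$gfp, rep(200, length(t)))

  # a well equal to the background corrects to exactly zero
  same <- subtract_background(bg1, list(bg1))
  expect_true(all(same$gfp == 0))

  expect_error(subtract_background(well, list()), "empty")
  bg_short <- data.frame(time_h = seq(2, 5, 0.5), od = 0.1, gfp = 100)
  expect_error(subtract_background(well, list(bg_short)), "interpolate")
})

test_that("promoter activity recovers analytic dGFP/dt over OD", {
  # constant OD = 0.1, GFP = 5 t: PA = 50 at any window
  odc <- constant_od_series(0.1)
  w <- data.frame(time_h = odc$time_h, od = 0.1, gfp = 5 * odc$time_h)
  pa <- promoter_activity(w, window = c(2, 8))
  expect_equal(pa$activity, 50, tolerance = 1e-10)

  # constant GFP: zero activity
  w0 <- data.frame(time_h = odc$time_h, od = 0.1, gfp = 7)
  expect_equal(promoter_activity(w0, window = c(2, 8))$activity, 0)

  # exponential growth with GFP'(t) = 200 * OD(t): the local regression
  # slope has only the O((r dt)^2) curvature bias
  t <- seq(0, 10, by = 8 / 60)
  od <- 0.01 * exp(0.7 * t)
  gfp <- 200 / 0.7 * 0.01 * (exp(0.7 * t) - 1)
  we <- data.frame(time_h = t, od = od, gfp = gfp)
  expect_equal(promoter_activity(we, window = c(5, 7))$activity, 200,
               tolerance = 0.01)

  expect_error(promoter_activity(w, window = c(9, 12)), "outside")
  expect_error(promoter_activity(w, window = c(5, 4)), "increasing")
  wlow <- data.frame(time_h = odc$time_h, od = 1e-5, gfp = 5 * odc$time_h)
  expect_error(promoter_activity(wlow, window = c(2, 8)), "floor")
})

test_that("replicate aggregation uses the standard error of the mean", {
  odc <- constant_od_series(0.1)
  mk <- function(pa, conc) data.frame(time_h = odc$time_h, od = 0.1,
                                      gfp = pa * 0.1 * odc$time_h,
                                      arabinose_mM = conc)
  fn <- build_input_function(list(mk(48, 1), mk(50, 1), mk(52, 1)),
                             window = c(2, 8))
  expect_equal(fn$activity, 50, tolerance = 1e-9)
  expect_equal(fn$activity_se, 2 / sqrt(3), tolerance = 1e-6)

  one <- build_input_function(list(mk(50, 1)), window = c(2, 8))
  expect_identical(nrow(one), 1L)
  expect_error(build_input_function(list()), "no wells")
})

test_that("zero-noise plates reproduce the generating input function", {
  des <- mutant_design(seed = 1, replicates = 1)
  plate <- generate_experiment(des, model_spec_hill(1000, 42, 1.9),
                               noise = noiseless())
  fn <- extract_input_functions(plate)
  truth <- hill_value(fn$arabinose_mM, 1000, 42, 1.9)
  nz <- truth > 0
  expect_true(all(abs(fn$activity[nz] / truth[nz] - 1) < 0.02))
  # zero-concentration well: activity indistinguishable from zero
  expect_lt(abs(fn$activity[!nz]), 0.02 * max(truth))
  # ordering and length conserved
  expect_identical(nrow(fn), length(des$concentrations))
  expect_identical(fn$arabinose_mM, sort(des$concentrations))
})

test_that("promoterless wells read as zero activity after subtraction", {
  # zero noise: residual PA is far below the induced activity
  des <- plate_design(concentrations = c(0, 100),
                      replicates_per_condition = 2, seed = 2)
  plate <- generate_experiment(des, model_spec_hill(1000, 42, 1.9),
                               noise = noiseless())
  bg <- split(plate[plate$genotype == "promoterless", ],
              plate$well_id[plate$genotype == "promoterless"])
  corrected <- subtract_background(bg[[1]], bg)
  pa0 <- promoter_activity(corrected)
  induced <- hill_value(100, 1000, 42, 1.9)
  expect_lt(abs(pa0$activity), 0.05 * induced)

  # default noise: |PA| < 3 s.e.
  platen <- generate_experiment(des, model_spec_hill(1000, 42, 1.9))
  bgn <- split(platen[platen$genotype == "promoterless", ],
               platen$well_id[platen$genotype == "promoterless"])
  for (j in seq_along(bgn)) {
    cw <- subtract_background(bgn[[j]], bgn[-j])
    pan <- promoter_activity(cw)
    expect_lt(abs(pan$activity), 3 * pan$se +
                .Machine$double.eps)
  }
})

test_that("autofluorescence is fully handled by background subtraction", {
  # identical wells except for the autofluorescence level give the same PA
  # once each is corrected with its matching background
  des <- mutant_design(seed = 5, replicates = 1)
  pa_for <- function(auto) {
    plate <- generate_experiment(des, model_spec_hill(1000, 42, 1.9),
                                 noise = noiseless(auto))
    fn <- extract_input_functions(plate)
    fn$activity
  }
  expect_equal(pa_for(100), pa_for(0), tolerance = 1e-8)
})
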