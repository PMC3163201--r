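# Seeded synthetic plate-reader experiments: logistic growth, GFP
# accumulation proportional to promoter activity times OD, autofluorescence
# proportional to OD, and multiplicative measurement noise.  The defaults
# emulate the design of a 96-well reporter assay: ~12 arabinose levels
# spanning > 4 decades, a parental (auto-regulated) and a mutant
# (constitutive-regulator) genotype, promoterless background wells,
# 8-minute sampling over 20 hours, and a 1:600 inoculation so that the
# 5-7 h analysis window falls in exponential phase.

GENOTYPES <- c("parental_NAR", "mutant_noNAR", "promoterless")

#' Default arabinose concentration series
#'
#' Zero plus half-log steps from 0.01 to 1000 mM (12 levels), covering an
#' induction range of 10 uM to above 100 mM with margin on both sides.
#'
#' @return Numeric vector of concentrations in mM.
#' @export
default_concentrations <- function() c(0, 10^seq(-2, 3, by = 0.5))

#' Plate design
#'
#' Describes the layout of a synthetic reporter experiment.
#'
#' @param concentrations Arabinose levels in mM (must include or allow 0);
#'   sorted ascending, nonnegative.
#' @param genotypes Subset of `"parental_NAR"`, `"mutant_noNAR"`,
#'   `"promoterless"`.  Promoterless wells (the autofluorescence background
#'   set shared by all reporter genotypes) are laid out once per replicate
#'   at zero arabinose.
#' @param replicates_per_condition Wells per (genotype, concentration).
#' @param sample_interval Sampling interval in hours (default 8 minutes).
#' @param duration Total run length in hours.
#' @param seed Integer seed; every well derives its own noise stream from
#'   `(seed, genotype, concentration, replicate)`.
#' @return A list of class `"plate_design"`.
#' @export
plate_design <- function(concentrations = default_concentrations(),
                         genotypes = GENOTYPES,
                         replicates_per_condition = 3L,
                         sample_interval = 8 / 60,
                         duration = 20,
                         seed = 1L) {
  .check_number(concentrations, "concentrations", nonnegative = TRUE,
                scalar = FALSE)
  if (is.unsorted(concentrations, strictly = FALSE))
    stop("concentrations must be sorted ascending")
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  genotypes <- match.arg(genotypes, GENOTYPES, several.ok = TRUE)
  .check_number(replicates_per_condition, "replicates_per_condition",
                positive = TRUE)
  .check_number(sample_interval, "sample_interval", positive = TRUE)
  .check_number(duration, "duration", positive = TRUE)
  if (duration < sample_interval)
    stop("duration must cover at least one sample interval")
  .check_number(seed, "seed")
  structure(list(concentrations = concentrations, genotypes = genotypes,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 sample_interval = sample_interval, duration = duration,
                 seed = as.integer(seed)),
            class = "plate_design")
}

#' Growth parameters
#'
#' Logistic growth constants.  Defaults (`od_initial = 0.005`,
#' `od_max = 0.5`, `growth_rate = 0.7`/h) mimic a 1:600 inoculation reaching
#' stationary phase within ~20 h, with the 5-7 h window in exponential
#' phase.
#'
#' @param od_initial Starting OD600, `0 < od_initial <= od_max`.
#' @param od_max Carrying capacity (OD600).
#' @param growth_rate Logistic rate in 1/h (>= 0; 0 means no growth).
#' @return A list of class `"growth_params"`.
#' @export
growth_params <- function(od_initial = 0.005, od_max = 0.5,
                          growth_rate = 0.7) {
  .check_number(od_initial, "od_initial", positive = TRUE)
  .check_number(od_max, "od_max", positive = TRUE)
  .check_number(growth_rate, "growth_rate", nonnegative = TRUE)
  if (od_initial > od_max) stop("od_initial must not exceed od_max")
  structure(list(od_initial = od_initial, od_max = od_max,
                 growth_rate = growth_rate),
            class = "growth_params")
}

#' Measurement noise model
#'
#' Multiplicative per-sample noise on fluorescence and OD, plus a cellular
#' autofluorescence background proportional to OD.  Defaults (3% relative
#' GFP noise, 2% relative OD noise, 100 fluorescence units per OD unit)
#' give Hill-fit standard errors of the same order as typical reporter-assay
#' fits.
#'
#' @param gfp_sd_rel Relative s.d. of fluorescence readings.
#' @param od_sd_rel Relative s.d. of OD readings.
#' @param autofluorescence_per_od Fluorescence per OD unit contributed by
#'   cells without a reporter.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(gfp_sd_rel = 0.03, od_sd_rel = 0.02,
                        autofluorescence_per_od = 100) {
  .check_number(gfp_sd_rel, "gfp_sd_rel", nonnegative = TRUE)
  .check_number(od_sd_rel, "od_sd_rel", nonnegative = TRUE)
  .check_number(autofluorescence_per_od, "autofluorescence_per_od",
                nonnegative = TRUE)
  structure(list(gfp_sd_rel = gfp_sd_rel, od_sd_rel = od_sd_rel,
                 autofluorescence_per_od = autofluorescence_per_od),
            class = "noise_model")
}

#' Simulate a noiseless growth curve
#'
#' Closed-form logistic dynamics
#' `dOD/dt = r OD (1 - OD/od_max)`: strictly increasing towards the
#' carrying capacity, identical for every well of a condition (the noise
#' model perturbs readings, not the underlying trajectory).
#'
#' @param design A [plate_design()] (supplies the time grid).
#' @param growth A [growth_params()] object.
#' @return A data frame with `time_h` and `od`.
#' @export
simulate_growth <- function(design, growth = growth_params()) {
  stopifnot(inherits(design, "plate_design"), inherits(growth, "growth_params"))
  time <- seq(0, design$duration, by = design$sample_interval)
  x0 <- growth$od_initial; K <- growth$od_max; r <- growth$growth_rate
  od <- if (r == 0 || K == x0) {
    rep(x0, length(time))
  } else {
    K / (1 + (K - x0) / x0 * exp(-r * time))
  }
  data.frame(time_h = time, od = od)
}

#' Simulate one reporter well
#'
#' Integrates the reporter balance forward on the OD grid: noiseless GFP
#' obeys `dGFP/dt = PA * OD(t) + d(autofluorescence_per_od * OD)/dt` with
#' `GFP(0) = autofluorescence_per_od * OD(0)` (trapezoidal integration of
#' the promoter-activity term).  GFP is treated as stable, so no
#' degradation term appears; dilution is implicit in the promoter-activity
#' definition.  Multiplicative Gaussian noise is applied per sample to both
#' channels, from a per-well stream derived from `(seed, genotype,
#' concentration, replicate)`.
#'
#' @param od_series Data frame with `time_h`, `od` (see
#'   [simulate_growth()]).
#' @param input_function Function mapping concentration (mM) to promoter
#'   activity (fluorescence/OD/h), or a single nonnegative number.
#'   Ignored for the promoterless genotype, which has no promoter
#'   (`PA = 0`).
#' @param concentration Arabinose concentration of the well (mM, >= 0).
#' @param noise A [noise_model()]; set the relative s.d. fields to 0 for a
#'   noiseless well.
#' @param seed Experiment seed used to derive the per-well stream, or
#'   `NULL` for no noise regardless of the noise model.
#' @param genotype One of `"parental_NAR"`, `"mutant_noNAR"`,
#'   `"promoterless"`.
#' @param replicate Replicate index.
#' @param well_id Well identifier string.
#' @return A data frame (one row per time point) with columns `well_id`,
#'   `genotype`, `arabinose_mM`, `replicate`, `time_h`, `od`, `gfp`.
#' @export
simulate_reporter <- function(od_series, input_function, concentration,
                              noise = noise_model(), seed = NULL,
                              genotype = "parental_NAR", replicate = 1L,
                              well_id = "W001") {
  stopifnot(is.data.frame(od_series),
            all(c("time_h", "od") %in% names(od_series)))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop("concentration must be a single nonnegative number")
  genotype <- match.arg(genotype, GENOTYPES)
  pa <- if (genotype == "promoterless") {
    0
  } else if (is.function(input_function)) {
    input_function(concentration)
  } else {
    .check_number(input_function, "input_function", nonnegative = TRUE)
  }
  if (!is.finite(pa) || pa < 0)
    stop("input_function must return a nonnegative promoter activity")

  time <- od_series$time_h
  od <- od_series$od
  auto <- noise$autofluorescence_per_od
  gfp <- pa * cumtrapz(time, od) + auto * od

  if (!is.null(seed) && (noise$gfp_sd_rel > 0 || noise$od_sd_rel > 0)) {
    ws <- well_seed(seed, genotype, concentration, replicate)
    noisy <- with_seed(ws, list(
      od = od * (1 + stats::rnorm(length(od), 0, noise$od_sd_rel)),
      gfp = gfp * (1 + stats::rnorm(length(gfp), 0, noise$gfp_sd_rel))
    ))
    od <- noisy$od
    gfp <- noisy$gfp
  }
  data.frame(well_id = well_id, genotype = genotype,
             arabinose_mM = concentration, replicate = as.integer(replicate),
             time_h = time, od = od, gfp = gfp)
}

#' Model specifications for plate generation
#'
#' Declare which input-function model generates a synthetic experiment.
#' `model_spec_hill()` applies the same Hill curve to every reporter
#' genotype; `model_spec_nar()` derives the parental curve from
#' [input_function_with_nar()] and the mutant curve from
#' [input_function_no_nar()]; `model_spec_mass_action()` uses the dual
#' activator/repressor model, with the mutant's regulator clamped at the
#' parental steady-state level at the highest plated concentration.
#' [generate_experiment()] also accepts a named list of per-genotype specs,
#' e.g. `list(parental_NAR = model_spec_nar(), mutant_noNAR =
#' model_spec_hill(1400, 42, 1.9))`.
#'
#' @param beta,K,n Hill parameters (activity units, mM, dimensionless).
#' @param params Model parameters ([nar_params()] or [dual_reg_params()]).
#' @param x_solver Steady-state solver for the NAR curve.
#' @return A list of class `"model_spec"`.
#' @name model_spec
#' @export
model_spec_hill <- function(beta = 1400, K = 42, n = 1.9) {
  structure(list(name = "hill",
                 params = list(beta = beta, K = K, n = n)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_spec_nar <- function(params = nar_params(),
                           x_solver = c("closed_form", "exact")) {
  stopifnot(inherits(params, "nar_params"))
  structure(list(name = "nar_simple", params = params,
                 x_solver = match.arg(x_solver)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_spec_mass_action <- function(params = dual_reg_params()) {
  stopifnot(inherits(params, "dual_reg_params"))
  structure(list(name = "mass_action", params = params),
            class = "model_spec")
}

# Resolve a model spec into a concentration -> PA function per genotype.
.resolve_input_function <- function(spec, genotype, design) {
  if (genotype == "promoterless") return(function(s) 0 * s)
  if (!inherits(spec, "model_spec")) {
    if (is.list(spec) && genotype %in% names(spec))
      return(.resolve_input_function(spec[[genotype]], genotype, design))
    stop("unknown model specification for genotype ", genotype)
  }
  switch(spec$name,
    hill = {
      p <- spec$params
      function(s) hill_value(s, p$beta, p$K, p$n)
    },
    nar_simple = {
      if (genotype == "parental_NAR")
        input_function_with_nar(spec$params, x_solver = spec$x_solver)
      else
        input_function_no_nar(spec$params)
    },
    mass_action = {
      if (genotype == "parental_NAR") {
        function(s) arabad_activity(s, spec$params)
      } else {
        s_top <- max(design$concentrations)
        Xc <- dual_steady_state(s_top, spec$params)$X
        function(s) arabad_activity(s, spec$params, X_const = Xc)
      }
    },
    stop("unknown model_spec name: ", spec$name)
  )
}

#' Generate a full synthetic plate
#'
#' Lays out wells from the design (reporter genotypes: one well per
#' concentration and replicate; promoterless background: one well per
#' replicate at zero arabinose), simulates growth and reporter kinetics for
#' each, applies per-well noise streams, and returns the long-format plate
#' table.  Deterministic for a given `design$seed`: regenerating with the
#' same seed is byte-identical, and each well's noise depends only on its
#' own identity.
#'
#' @param design A [plate_design()].
#' @param model_spec A [model_spec] object, or a named list of per-genotype
#'   specs.
#' @param growth A [growth_params()] object.
#' @param noise A [noise_model()] object.
#' @param path Optional path; when given the plate CSV (columns `well_id`,
#'   `genotype`, `arabinose_mM`, `replicate`, `time_h`, `od`, `gfp`) is
#'   written there.
#' @return The plate as a long data frame, invisibly when `path` is given.
#' @export
generate_experiment <- function(design, model_spec, growth = growth_params(),
                                noise = noise_model(), path = NULL) {
  stopifnot(inherits(design, "plate_design"))
  od_series <- simulate_growth(design, growth)

  layout <- list()
  for (g in design$genotypes) {
    concs <- if (g == "promoterless") 0 else design$concentrations
    for (conc in concs)
      for (rep_i in seq_len(design$replicates_per_condition))
        layout[[length(layout) + 1L]] <-
          list(genotype = g, conc = conc, replicate = rep_i)
  }

  wells <- vector("list", length(layout))
  for (i in seq_along(layout)) {
    li <- layout[[i]]
    fn <- .resolve_input_function(model_spec, li$genotype, design)
    wells[[i]] <- simulate_reporter(
      od_series, fn, li$conc, noise = noise, seed = design$seed,
      genotype = li$genotype, replicate = li$replicate,
      well_id = sprintf("W%03d", i))
  }
  plate <- do.call(rbind, wells)
  rownames(plate) <- NULL
  if (!is.null(path)) {
    write_plate_csv(plate, path)
    return(invisible(plate))
  }
  plate
}

#' Read and write plate CSVs
#'
#' Long-format plate tables: one row per (well, time point), header row
#' mandatory, `.` decimal separator, UTF-8.
#'
#' @param plate Plate data frame as returned by [generate_experiment()].
#' @param path File path.
#' @return `read_plate_csv()` returns the plate data frame.
#' @export
write_plate_csv <- function(plate, path) {
  need <- c("well_id", "genotype", "arabinose_mM", "replicate", "time_h",
            "od", "gfp")
  if (!all(need %in% names(plate)))
    stop("plate is missing columns: ",
         paste(setdiff(need, names(plate)), collapse = ", "))
  utils::write.csv(plate[need], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("well_id", "genotype", "arabinose_mM", "replicate", "time_h",
            "od", "gfp")
  if (!all(need %in% names(plate)))
    stop("plate CSV is missing columns: ",
         paste(setdiff(need, names(plate)), collapse = ", "))
  plate
}
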