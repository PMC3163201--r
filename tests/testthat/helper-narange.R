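# Shared fixture builders (all data generated in code, no files).

# Small mutant-plus-background design used by several round trips.
mutant_design <- function(seed = 1L, replicates = 3L) {
  plate_design(genotypes = c("mutant_noNAR", "promoterless"),
               replicates_per_condition = replicates, seed = seed)
}

noiseless <- function(autofluorescence = 100) {
  noise_model(gfp_sd_rel = 0, od_sd_rel = 0,
              autofluorescence_per_od = autofluorescence)
}

# A constant-OD series (carrying capacity equal to the inoculum).
constant_od_series <- function(od = 0.1, duration = 10, dt = 8 / 60) {
  data.frame(time_h = seq(0, duration, by = dt), od = od)
}

# Analytic crossing of the composed no-NAR response (squared MM in the
# linear X* regime): solve x^2/(c + x^2) = q * sup with x = X*/X0 and
# c = (K_z/X0)^2, then s = K_s * x/(1 - x).
no_nar_crossing_oracle <- function(q, K_z, X0, K_s) {
  c2 <- (K_z / X0)^2
  x <- sqrt(q * c2 / (1 + c2 - q))
  K_s * x / (1 - x)
}

# Analytic crossing of the with-NAR response (closed-form X, n = 2,
# s >> K_s): X*^2 = u^2/(1+u) in units of A, target q of the asymptote
# means u^2/(1+u) = c2 * q/(1-q) with c2 = (K_z/A)^2.
with_nar_crossing_oracle <- function(q, Kz_over_A, K_s) {
  b <- Kz_over_A^2 * q / (1 - q)
  K_s * (b + sqrt(b^2 + 4 * b)) / 2
}
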