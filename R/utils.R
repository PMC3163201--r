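# Internal helpers: argument checks, seeded evaluation, bracketed root finding.

.check_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                          finite = TRUE, scalar = TRUE) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (scalar && length(x) != 1L)
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonnegative && any(x < 0))
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-well RNG stream: hash the well identity (genotype,
# concentration, replicate) together with the experiment seed, so that adding
# or removing other wells never changes an existing well's noise draws.
well_seed <- function(seed, genotype, concentration, replicate) {
  key <- sprintf("%s|%.12g|%d", genotype, concentration, as.integer(replicate))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + (as.numeric(seed) %% 2147483629) * 7919) %% 2147483629)
}

# Vectorized bisection in log-space for a componentwise strictly decreasing
# function g (production minus removal): finds g(x) = 0 with x in [lo, hi].
# All of g, lo, hi are vectorized; brackets are validated first.
bisect_decreasing <- function(g, lo, hi, rel_tol = 1e-12) {
  flo <- g(lo)
  fhi <- g(hi)
  bad <- !(flo >= 0 & fhi <= 0)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "root not bracketed: g(%.6g) = %.6g, g(%.6g) = %.6g",
      lo[i], flo[i], hi[i], fhi[i]), call. = FALSE)
  }
  llo <- log(lo)
  lhi <- log(hi)
  iters <- ceiling(log2(max(lhi - llo, 1) / rel_tol))
  iters <- min(max(iters, 40L), 200L)
  for (k in seq_len(iters)) {
    mid <- (llo + lhi) / 2
    up <- g(exp(mid)) > 0
    llo <- ifelse(up, mid, llo)
    lhi <- ifelse(up, lhi, mid)
  }
  exp((llo + lhi) / 2)
}

# Trapezoidal cumulative integral of y over x (same length, x increasing).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
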