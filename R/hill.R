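# Hill input functions and the 10-90% input dynamic range statistic.

#' Hill dose-response value
#'
#' Evaluates the activating Hill function
#' \deqn{f(s) = \beta \, s^n / (K^n + s^n)}
#' the standard phenomenological form for a gene input function: `beta` is
#' the maximal promoter activity, `K` the halfway induction point (the input
#' giving half-maximal output) and `n` the apparent Hill coefficient
#' (steepness).
#'
#' @param s Input (inducer) concentration, a nonnegative numeric vector.
#' @param beta Maximal output, > 0.
#' @param K Halfway induction point, > 0, same units as `s`.
#' @param n Apparent Hill coefficient, > 0.
#' @return Numeric vector of outputs, `f(0) = 0` and `f -> beta` as
#'   `s -> Inf`.
#' @examples
#' hill_value(42, beta = 1000, K = 42, n = 1.9)  # half-maximal: 500
#' @export
hill_value <- function(s, beta, K, n) {
  .check_number(beta, "beta", positive = TRUE)
  .check_number(K, "K", positive = TRUE)
  .check_number(n, "n", positive = TRUE)
  .check_number(s, "s", nonnegative = TRUE, scalar = FALSE)
  # (K/s)^n form avoids overflow of s^n at large s and high cooperativity
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- beta / (1 + (K / s[pos])^n)
  out
}

#' Analytic input dynamic range of a Hill curve
#'
#' The input dynamic range is the ratio \eqn{R = s_{90}/s_{10}} of the inputs
#' at which the response reaches 90% and 10% of its maximum.  For a Hill
#' curve with coefficient `n` this has the closed form
#' \deqn{R = 81^{1/n},}
#' since \eqn{s_q/K = (q/(1-q))^{1/n}} so that
#' \eqn{s_{90}/s_{10} = (0.9/0.1 \cdot 0.9/0.1)^{1/n}}.  Michaelis-Menten
#' responses (`n = 1`) span 81-fold in input; a cooperative `n = 2` response
#' only 9-fold; `n = 4` only 3-fold.
#'
#' @param n Apparent Hill coefficient(s), > 0.
#' @return `81^(1/n)`, dimensionless fold-range, vectorized over `n`.
#' @seealso [dynamic_range_numeric()] for arbitrary monotone saturating
#'   response curves.
#' @export
dynamic_range_analytic <- function(n) {
  .check_number(n, "n", positive = TRUE, scalar = FALSE)
  81^(1 / n)
}

#' Construct a response curve
#'
#' Wraps a vectorized function `s -> output` together with its evaluation
#' domain and (optionally) its known supremum, for use with
#' [dynamic_range_numeric()].  Model input functions built by
#' [input_function_with_nar()] and [input_function_no_nar()] return this
#' class with their analytic supremum attached.
#'
#' @param f Vectorized nonnegative function of the input `s`.
#' @param domain Length-2 positive numeric, the evaluation domain; it is
#'   extended adaptively when the 10% or 90% crossing falls outside it.
#' @param sup Known supremum of `f` (the asymptotic maximum), or `NULL` to
#'   have it estimated from the curve's plateau.
#' @return A function of class `"response_curve"`.
#' @export
response_curve <- function(f, domain = c(1e-8, 1e12), sup = NULL) {
  stopifnot(is.function(f), length(domain) == 2L, all(domain > 0),
            domain[1] < domain[2])
  if (!is.null(sup)) .check_number(sup, "sup", positive = TRUE)
  structure(f, domain = as.numeric(domain), sup = sup,
            class = c("response_curve", "function"))
}

# Estimate the supremum of a monotone saturating curve by extending the
# upper end of the domain until the plateau stops growing.
.estimate_sup <- function(f, hi, max_hi = 1e100) {
  f1 <- f(hi)
  repeat {
    hi2 <- hi * 100
    f2 <- f(hi2)
    if (!is.finite(f2)) stop("curve not evaluable while estimating supremum")
    if (f2 - f1 <= 1e-10 * abs(f2) || hi2 >= max_hi) return(max(f1, f2))
    hi <- hi2
    f1 <- f2
  }
}

# Locate the input where f crosses `target`, by log-grid bracketing followed
# by Brent's method on log10(s).  Extends the domain downwards/upwards (up to
# `max_expand` decades) when the crossing lies outside it.
.crossing <- function(f, target, domain, rel_tol = 1e-8, max_expand = 60) {
  lo <- domain[1]; hi <- domain[2]
  expand <- 0
  while (f(lo) > target) {
    lo <- lo / 100; expand <- expand + 2
    if (expand > max_expand)
      stop("curve exceeds target at the lower end of the extended domain")
  }
  expand <- 0
  while (f(hi) < target) {
    hi <- hi * 100; expand <- expand + 2
    if (expand > max_expand)
      stop(sprintf(
        "curve fails to reach %.3g within the extended domain", target))
  }
  r <- stats::uniroot(function(l) f(10^l) - target,
                      lower = log10(lo), upper = log10(hi),
                      tol = rel_tol / log(10) / 2, maxiter = 1000L)
  10^r$root
}

#' Numeric input dynamic range of a monotone saturating response
#'
#' Computes \eqn{R = s_{90}/s_{10}} for an arbitrary monotone nondecreasing,
#' saturating response curve.  The 10% and 90% levels are taken relative to
#' the curve's supremum (its fitted or asymptotic maximum, not the largest
#' sampled value), so that `R` stays well defined when the top plateau is
#' only just reached within the measured range.  Crossings are located by
#' log-grid bracketing plus Brent root refinement to relative tolerance
#' `rel_tol`.
#'
#' @param curve A [response_curve()], or any vectorized function of `s`.
#' @param domain Evaluation domain; defaults to the curve's own, else
#'   `c(1e-8, 1e12)`.  Extended adaptively until the crossings are bracketed.
#' @param sup Supremum to normalize by; defaults to the curve's own, else
#'   estimated from the plateau.
#' @param rel_tol Relative tolerance on the crossing locations.
#' @param check_monotone Verify monotonicity on a log-spaced grid first
#'   (zero-input points are excluded from the check).
#' @return A list of class `"dynamic_range"` with elements `R`, `s10`,
#'   `s90`, `sup`.
#' @examples
#' dr <- dynamic_range_numeric(function(s) hill_value(s, 1, 1, 1), sup = 1)
#' dr$R   # 81: s10 = 1/9, s90 = 9
#' @export
dynamic_range_numeric <- function(curve, domain = NULL, sup = NULL,
                                  rel_tol = 1e-8, check_monotone = TRUE) {
  domain <- domain %||% attr(curve, "domain") %||% c(1e-8, 1e12)
  sup <- sup %||% attr(curve, "sup")
  f <- curve
  if (check_monotone) {
    grid <- 10^seq(log10(domain[1]), log10(domain[2]), length.out = 97L)
    y <- f(grid)
    if (any(!is.finite(y))) stop("curve not finite on its domain")
    tol <- 1e-9 * max(abs(y))
    if (any(diff(y) < -tol)) stop("curve is not monotone nondecreasing")
  }
  if (is.null(sup)) sup <- .estimate_sup(f, domain[2])
  if (!is.finite(sup) || sup <= 0) stop("supremum must be finite and positive")
  s10 <- .crossing(f, 0.1 * sup, domain, rel_tol)
  s90 <- .crossing(f, 0.9 * sup, domain, rel_tol)
  structure(list(R = s90 / s10, s10 = s10, s90 = s90, sup = sup),
            class = "dynamic_range")
}

#' @export
print.dynamic_range <- function(x, ...) {
  cat(sprintf("Input dynamic range R = %.4g (s10 = %.4g, s90 = %.4g, max = %.4g)\n",
              x$R, x$s10, x$s90, x$sup))
  invisible(x)
}

#' Fit a Hill input function
#'
#' Weighted nonlinear least-squares fit of the Hill function
#' `beta * s^n / (K^n + s^n)` to a measured input function (promoter
#' activity versus inducer concentration).  Weights are `1/se^2` when
#' per-point standard errors are available.  The optimizer
#' (Levenberg-Marquardt, via \pkg{minpack.lm}) is restarted from a grid of
#' log-spaced `K` and several `n` values and the best converged solution is
#' kept.  Parameter standard errors come from a seeded parametric bootstrap;
#' the input dynamic range `R = 81^(1/n)` and its standard error
#' (`se_R = R log(81) se_n / n^2`, first-order propagation) are derived from
#' the fitted coefficient.  A numeric `R` computed directly from the fitted
#' curve by [dynamic_range_numeric()] is reported alongside.
#'
#' The error model behind the weights and the bootstrap noise stabilizes
#' the raw per-point standard errors: replicate SEMs from few wells carry
#' only `k - 1` degrees of freedom each, so an additive-plus-proportional
#' variance function is fitted across concentrations and the small-sample
#' bias of the sample s.d. is undone (c4 correction, using the `n_wells`
#' column when present).  When a shared background-subtraction error is
#' known (attribute `"background_se"` set by [extract_input_functions()],
#' or the `background_se` argument), the bootstrap additionally draws one
#' common offset per resample, since the same control-well mean is
#' subtracted from every well of a plate.
#'
#' @param data A data frame with concentration column (`arabinose_mM` or
#'   `concentration`), `activity`, and optionally `activity_se` and
#'   `n_wells`.
#' @param bootstrap Number of parametric-bootstrap resamples for standard
#'   errors (0 disables them).
#' @param seed Seed for the bootstrap resampling.
#' @param background_se Standard deviation of the plate-wide activity
#'   offset induced by background subtraction (overrides the attribute).
#' @param offset Also fit a basal-activity offset (4th parameter); off by
#'   default, matching three-parameter induction fits.
#' @param n_max Upper bound on the Hill coefficient.
#' @return An object of class `"hill_fit"`: fitted `beta`, `K`, `n`, their
#'   bootstrap standard errors, `R` and `se_R`, the numeric dynamic range
#'   `R_numeric` with `s10`/`s90`, fitted values and residuals.
#' @export
fit_hill <- function(data, bootstrap = 200L, seed = 1L, offset = FALSE,
                     n_max = 10, background_se = NULL) {
  d <- .as_inputfn(data)
  conc <- d$concentration
  y <- d$activity
  se <- d$activity_se
  if (length(conc) < 4L || length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations to fit a Hill function")
  if (diff(range(y)) <= 0) stop("degenerate data: all activities equal")

  have_se <- !is.null(se) && any(is.finite(se) & se > 0)
  if (have_se) {
    se <- ifelse(is.finite(se) & se > 0, se, min(se[is.finite(se) & se > 0]))
    # Error model for weighting and bootstrap noise.  Replicate SEMs from
    # few wells are individually very noisy (k = 3 gives 2 d.f.), and raw
    # 1/se^2 weights make the fit chase whichever point's error happened to
    # be underestimated.  Stabilize with an additive-plus-proportional
    # variance function fitted across concentrations, and undo the small-k
    # downward bias of the sample s.d. (c4 correction).
    k_rep <- if ("n_wells" %in% names(data)) as.integer(data$n_wells)
             else rep(NA_integer_, length(y))
    c4 <- ifelse(is.finite(k_rep) & k_rep > 1,
                 sqrt(2 / (k_rep - 1)) * exp(lgamma(k_rep / 2) -
                                               lgamma((k_rep - 1) / 2)),
                 1)
    se_model <- tryCatch({
      # two-component variance model se^2 = a^2 + (c y)^2, with the
      # additive component floored at half the lower-quartile variance so a
      # chance run of tight replicates cannot zero out the low-signal noise
      v <- se^2
      cv <- stats::coef(stats::lm(v ~ I(y^2)))
      a2 <- max(cv[[1]], 0.5 * stats::quantile(v, 0.25, names = FALSE))
      c2 <- max(cv[[2]], 0)
      sqrt(a2 + c2 * y^2)
    }, error = function(e) se)
    if (any(!is.finite(se_model)) || all(se_model <= 0)) se_model <- se
    se_model <- pmax(se_model, 1e-3 * max(se)) / c4
    w <- 1 / se_model^2
    # cap the weight spread: near-zero standard errors (e.g. noiseless
    # synthetic wells) would otherwise make the weighted problem singular
    w <- pmin(w, min(w) * 1e6)
  } else {
    se_model <- NULL
    w <- rep(1, length(y))
  }

  pos <- conc[conc > 0]
  k_starts <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = 5L)
  n_starts <- c(0.7, 1, 2, 4)
  beta0 <- max(y) * 1.05
  lower <- c(beta = max(y) * 1e-6, K = min(pos) * 1e-3, n = 0.05)
  upper <- c(beta = Inf, K = max(pos) * 1e6, n = n_max)
  model <- if (offset) {
    lower <- c(lower, b0 = -Inf); upper <- c(upper, b0 = Inf)
    y ~ b0 + hill_value(conc, beta, K, n)
  } else {
    y ~ hill_value(conc, beta, K, n)
  }

  fit_once <- function(start, yy, ww) {
    # weights are evaluated inside `data`, not in this function's frame
    tryCatch(
      minpack.lm::nlsLM(model, data = data.frame(conc = conc, y = yy, .w = ww),
                        start = start, weights = .w,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  }

  best <- NULL
  for (K0 in k_starts) for (n0 in n_starts) {
    start <- list(beta = beta0, K = K0, n = n0)
    if (offset) start$b0 <- 0
    fit <- fit_once(start, y, w)
    if (!is.null(fit) &&
        (is.null(best) ||
           stats::deviance(fit) < stats::deviance(best) - 1e-12))
      best <- fit
  }
  if (is.null(best)) stop("Hill fit did not converge from any start")

  cf <- stats::coef(best)
  fitted_y <- hill_value(conc, cf[["beta"]], cf[["K"]], cf[["n"]]) +
    if (offset) cf[["b0"]] else 0

  boot <- NULL
  se_cf <- c(beta = NA_real_, K = NA_real_, n = NA_real_)
  if (bootstrap > 0L) {
    sigma <- if (have_se) se_model else {
      rep(sqrt(sum(w * (y - fitted_y)^2) / max(length(y) - length(cf), 1)),
          length(y))
    }
    # background subtraction applies the same (noisy) control-well mean to
    # every reporter well of the plate, so its error is a *shared* additive
    # offset on all activities; extract_input_functions() estimates its
    # s.d. from the control wells and passes it along as an attribute
    bg_se <- attr(data, "background_se") %||% background_se
    start_hat <- as.list(cf)
    boot <- with_seed(seed, {
      out <- matrix(NA_real_, nrow = bootstrap, ncol = 3L,
                    dimnames = list(NULL, c("beta", "K", "n")))
      for (b in seq_len(bootstrap)) {
        yb <- fitted_y + stats::rnorm(length(y), 0, sigma)
        if (is.finite(bg_se %||% NA) && bg_se > 0)
          yb <- yb + stats::rnorm(1L, 0, bg_se)
        fb <- fit_once(start_hat, yb, w)
        if (!is.null(fb)) out[b, ] <- stats::coef(fb)[c("beta", "K", "n")]
      }
      out
    })
    ok <- stats::complete.cases(boot)
    if (sum(ok) >= bootstrap / 2)
      se_cf <- apply(boot[ok, , drop = FALSE], 2, stats::sd)
    else
      warning("more than half of the bootstrap refits failed; no s.e. reported")
  }

  R <- unname(81^(1 / cf[["n"]]))
  se_R <- unname(R * log(81) / cf[["n"]]^2 * se_cf[["n"]])
  curve <- response_curve(
    function(s) hill_value(s, cf[["beta"]], cf[["K"]], cf[["n"]]),
    domain = cf[["K"]] * c(1e-8, 1e8), sup = cf[["beta"]])
  dr <- dynamic_range_numeric(curve, check_monotone = FALSE)

  structure(list(
    beta = unname(cf[["beta"]]), K = unname(cf[["K"]]), n = unname(cf[["n"]]),
    offset = if (offset) unname(cf[["b0"]]) else NULL,
    se_beta = unname(se_cf[["beta"]]), se_K = unname(se_cf[["K"]]),
    se_n = unname(se_cf[["n"]]),
    R = R, se_R = se_R,
    R_numeric = dr$R, s10 = dr$s10, s90 = dr$s90,
    curve = curve,
    fitted = fitted_y, residuals = y - fitted_y,
    data = d, weights = w, deviance = stats::deviance(best),
    n_boot = if (bootstrap > 0L) sum(stats::complete.cases(boot)) else 0L
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, digits = 3, ...) {
  fmt <- function(v, s) {
    if (is.finite(s %||% NA)) sprintf("%.*g ± %.*g", digits, v, 2, s)
    else sprintf("%.*g", digits, v)
  }
  cat("Hill input-function fit\n")
  cat("  beta =", fmt(x$beta, x$se_beta), "\n")
  cat("  K    =", fmt(x$K, x$se_K), "\n")
  cat("  n    =", fmt(x$n, x$se_n), "\n")
  cat("  R (81^(1/n)) =", fmt(x$R, x$se_R),
      sprintf("; numeric R = %.*g\n", digits, x$R_numeric))
  invisible(x)
}

# Normalize an input-function table: accepts `concentration` or
# `arabinose_mM` for the dose column; keeps ordering intact.
.as_inputfn <- function(data) {
  stopifnot(is.data.frame(data))
  cc <- if ("concentration" %in% names(data)) data$concentration
        else if ("arabinose_mM" %in% names(data)) data$arabinose_mM
        else stop("data must have a `concentration` or `arabinose_mM` column")
  if (!"activity" %in% names(data)) stop("data must have an `activity` column")
  .check_number(cc, "concentration", nonnegative = TRUE, scalar = FALSE)
  list(concentration = as.numeric(cc),
       activity = as.numeric(data$activity),
       activity_se = if ("activity_se" %in% names(data))
         as.numeric(data$activity_se) else NULL)
}
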