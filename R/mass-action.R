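# Mass-action steady-state model of a dual transcription factor that both
# activates and represses its target operon (the AraC/araBAD
# configuration).  The regulator's own promoter is repressed by the free
# (inducer-less) form X_f; the target promoter is described by equilibrium
# promoter occupancy with a basal term, an activating site bound by the
# inducer-bound form X*, and a repressing (DNA-looping) site bound by X_f.

#' Parameters of the dual-regulator mass-action model
#'
#' The regulator X is produced from its own (araC-like) promoter at maximal
#' rate `beta_c`, repressed by free X with dissociation constant `K_c`, and
#' removed at rate `alpha`; the inducer binds with dissociation constant
#' `K_s`.  The target (araBAD-like) promoter activity is the occupancy form
#' \deqn{\beta_z \frac{basal + (X^*/K_{act})^{n_{act}}}
#'                   {1 + (X_f/K_{rep})^{n_{rep}} + (X^*/K_{act})^{n_{act}}}.}
#' `beta_x`/`K_x` are aliases for the regulator promoter constants
#' (`beta_c`/`K_c`), kept for symmetry with [nar_params()].
#'
#' Defaults are chosen so that (with concentrations in units of the
#' regulator scale `A = sqrt(K_c beta_c / alpha) = 1`) the parental curve
#' is basal-transcription relieved from looping repression with
#' `X_f ~ 1/sqrt(s)` -- an apparent Hill coefficient near 1, halfway
#' induction near 1 mM -- while the constitutive-regulator variant, with
#' `X_f ~ 1/s`, is steeper (apparent `n ~ 2`) with a halfway point a
#' decade or more higher; the regulator promoter's own response then rises
#' with inducer on the ~0.1-1 M scale.
#'
#' @param beta_c Maximal regulator production rate.
#' @param alpha Degradation/dilution rate.
#' @param K_c Dissociation constant of X_f at the regulator's own promoter.
#' @param K_s Inducer-regulator dissociation constant (mM).
#' @param basal Basal target-promoter activity fraction, in `[0, 1)`.
#' @param K_act Dissociation constant of X* at the activating site.
#' @param K_rep Dissociation constant of X_f at the repressing site.
#' @param n_act,n_rep Hill exponents of the two sites.
#' @param beta_z Maximal target promoter activity.
#' @param beta_x,K_x Aliases for `beta_c`, `K_c`.
#' @return A validated list of class `"dual_reg_params"` (with the derived
#'   scale `A`).
#' @export
dual_reg_params <- function(beta_c = 2326, alpha = 1, K_c = 4.3e-4,
                            K_s = 1.77e-4, basal = 0.3,
                            K_act = 1e5, K_rep = 0.0127,
                            n_act = 2, n_rep = 2, beta_z = 6667,
                            beta_x = beta_c, K_x = K_c) {
  for (nm in c("beta_c", "alpha", "K_c", "K_s", "K_act", "K_rep",
               "n_act", "n_rep", "beta_z", "beta_x", "K_x"))
    .check_number(get(nm), nm, positive = TRUE)
  .check_number(basal, "basal", nonnegative = TRUE)
  if (basal >= 1) stop("basal must be < 1")
  structure(list(beta_c = beta_c, alpha = alpha, K_c = K_c, K_s = K_s,
                 basal = basal, K_act = K_act, K_rep = K_rep,
                 n_act = n_act, n_rep = n_rep, beta_z = beta_z,
                 beta_x = beta_x, K_x = K_x,
                 A = sqrt(K_c * beta_c / alpha)),
            class = "dual_reg_params")
}

#' Steady state of the auto-regulated dual regulator
#'
#' Solves the production-removal balance
#' `beta_c / (1 + X_f/K_c) = alpha X` with `X_f = X K_s/(K_s + s)`, by the
#' same bracketed bisection as [x_steady_exact()] (the two models share
#' this structure; at any `s` the equation is the simple model's with
#' `K_x := K_c`).  Returns the unique positive root together with the
#' derived active and free forms; conservation `X_f + X* = X` is exact.
#'
#' @param s Inducer concentration(s), nonnegative.
#' @param params A [dual_reg_params()] object.
#' @param rel_tol Relative tolerance of the root.
#' @return A list with vectors `X`, `X_star`, `X_f`.
#' @export
dual_steady_state <- function(s, params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "dual_reg_params"))
  .check_number(s, "s", nonnegative = TRUE, scalar = FALSE)
  X <- .tf_steady(s, beta = params$beta_c, alpha = params$alpha,
                  K_own = params$K_c, K_s = params$K_s, rel_tol = rel_tol)
  X_star <- x_active(X, s, params$K_s)
  list(X = X, X_star = X_star, X_f = X - X_star)
}

# Occupancy computed through logs so that huge (X/K)^n terms cannot
# overflow: act = beta_z (basal e^{-m} + e^{la-m}) /
#                 (e^{-m} + e^{lr-m} + e^{la-m}), m = max(0, la, lr).
.occupancy <- function(X_star, X_f, params) {
  la <- ifelse(X_star > 0,
               params$n_act * (log(X_star) - log(params$K_act)), -Inf)
  lr <- ifelse(X_f > 0,
               params$n_rep * (log(X_f) - log(params$K_rep)), -Inf)
  m <- pmax(0, la, lr)
  num <- params$basal * exp(-m) + exp(la - m)
  den <- exp(-m) + exp(lr - m) + exp(la - m)
  params$beta_z * num / den
}

#' Target (araBAD-like) promoter activity
#'
#' Evaluates the dual-regulation occupancy form at the steady-state
#' regulator level, or at a clamped constitutive level `X_const` (the
#' decoupled-regulator mutant).  At `s = 0` the activity reduces to
#' `beta_z basal / (1 + (X_f/K_rep)^n_rep)`; with `X_f = 0` and a
#' saturating activating site it approaches `beta_z`.
#'
#' @inheritParams dual_steady_state
#' @param X_const Optional constitutive regulator level; when given, `X` is
#'   clamped there instead of solving the auto-regulated steady state.
#' @return Promoter activity, vectorized over `s`.
#' @export
arabad_activity <- function(s, params, X_const = NULL) {
  stopifnot(inherits(params, "dual_reg_params"))
  .check_number(s, "s", nonnegative = TRUE, scalar = FALSE)
  if (is.null(X_const)) {
    st <- dual_steady_state(s, params)
  } else {
    .check_number(X_const, "X_const", positive = TRUE)
    Xs <- x_active(rep(X_const, length(s)), s, params$K_s)
    st <- list(X_star = Xs, X_f = X_const - Xs)
  }
  .occupancy(st$X_star, st$X_f, params)
}

#' Regulator (araC-like) promoter activity
#'
#' The regulator promoter is repressed by free X only:
#' `beta_c / (1 + X_f/K_c)`.  Because `X_f` falls as the inducer rises, the
#' activity is nondecreasing in `s` -- the auto-regulated regulator is
#' itself induced by its signal.
#'
#' @inheritParams dual_steady_state
#' @return Promoter activity, vectorized over `s`.
#' @export
arac_activity <- function(s, params) {
  stopifnot(inherits(params, "dual_reg_params"))
  st <- dual_steady_state(s, params)
  params$beta_c / (1 + st$X_f / params$K_c)
}

#' Fit the dual-regulator model to parental and mutant input functions
#'
#' Joint weighted least squares in log-activity space (so that every decade
#' of the dose-response contributes evenly) over the parental curve (full
#' auto-regulated steady state), the mutant curve (regulator clamped at the
#' parental steady-state level at the highest parental concentration), and
#' optionally the regulator's own promoter curve.  The concentration scale
#' of the regulator is fixed by `A = sqrt(K_c beta_c/alpha) = 1` and
#' `alpha = 1` (only dimensionless combinations are identifiable from
#' dose-response shapes); free parameters are `K_s`, `K_c`, `K_act`,
#' `K_rep`, `basal` and one output scale per data set, optimized by
#' Nelder-Mead from multiple starts.
#'
#' @param data_parental,data_mutant Input-function data frames
#'   (`arabinose_mM`/`concentration`, `activity`, optional `activity_se`).
#' @param data_arac Optional regulator-promoter input function.
#' @param n_act,n_rep Hill exponents (held fixed during the fit).
#' @param n_starts Number of optimization starts (the first is the package
#'   default parameter set; the rest are seeded log-scale jitters of it).
#' @param seed Seed for the start jitters.
#' @return An object of class `"dual_fit"`: the fitted
#'   [dual_reg_params()], per-dataset output scales, the clamped mutant
#'   level `X_const`, predicted-curve functions, residual summary, and the
#'   model-implied halfway induction points and numeric dynamic ranges of
#'   both genotypes.
#' @export
fit_dual_model <- function(data_parental, data_mutant, data_arac = NULL,
                           n_act = 2, n_rep = 2, n_starts = 8L, seed = 1L) {
  dp <- .as_inputfn(data_parental)
  dm <- .as_inputfn(data_mutant)
  dc <- if (!is.null(data_arac)) .as_inputfn(data_arac)
  if (max(dp$concentration) <= min(dm$concentration[dm$concentration > 0]) ||
      max(dm$concentration) <= min(dp$concentration[dp$concentration > 0]))
    stop("parental and mutant concentration ranges do not overlap")

  s_top <- max(dp$concentration)
  logw <- function(d) {
    rel <- if (!is.null(d$activity_se))
      abs(d$activity_se) / pmax(abs(d$activity), 1e-12) else rep(0.1, length(d$activity))
    1 / pmax(rel, 0.03)^2
  }
  obs <- function(d) {
    floor_a <- 1e-4 * max(d$activity)
    log(pmax(d$activity, floor_a))
  }
  ww <- list(p = logw(dp), m = logw(dm), c = if (!is.null(dc)) logw(dc))
  yy <- list(p = obs(dp), m = obs(dm), c = if (!is.null(dc)) obs(dc))
  floors <- list(p = 1e-4 * max(dp$activity), m = 1e-4 * max(dm$activity),
                 c = if (!is.null(dc)) 1e-4 * max(dc$activity))

  # theta = log10(K_s, K_c, K_act, K_rep), qlogis(basal),
  #         log10(scale_par, scale_mut[, scale_arac])
  build <- function(theta) {
    K_c <- 10^theta[2]
    dual_reg_params(beta_c = 1 / K_c, alpha = 1, K_c = K_c,
                    K_s = 10^theta[1], basal = stats::plogis(theta[5]),
                    K_act = 10^theta[3], K_rep = 10^theta[4],
                    n_act = n_act, n_rep = n_rep, beta_z = 1)
  }
  predict_sets <- function(theta) {
    p <- build(theta)
    Xc <- dual_steady_state(s_top, p)$X
    out <- list(
      p = 10^theta[6] * arabad_activity(dp$concentration, p),
      m = 10^theta[7] * arabad_activity(dm$concentration, p, X_const = Xc))
    if (!is.null(dc))
      out$c <- 10^theta[8] * arac_activity(dc$concentration, p) / p$beta_c
    out
  }
  objective <- function(theta) {
    pred <- tryCatch(predict_sets(theta), error = function(e) NULL)
    if (is.null(pred)) return(1e10)
    tot <- 0
    for (k in names(pred)) {
      lp <- log(pmax(pred[[k]], floors[[k]]))
      tot <- tot + sum(ww[[k]] * (lp - yy[[k]])^2)
    }
    if (!is.finite(tot)) 1e10 else tot
  }

  d0 <- dual_reg_params(n_act = n_act, n_rep = n_rep)
  theta0 <- c(log10(d0$K_s), log10(d0$K_c), log10(d0$K_act),
              log10(d0$K_rep), stats::qlogis(d0$basal),
              log10(max(dp$activity)), log10(max(dm$activity)))
  if (!is.null(dc)) theta0 <- c(theta0, log10(max(dc$activity)))

  starts <- with_seed(seed, {
    c(list(theta0), lapply(seq_len(max(n_starts - 1L, 0L)), function(i) {
      jit <- stats::runif(length(theta0), -1, 1)
      jit[5] <- jit[5] * 2          # basal on the logit scale
      jit[6:length(theta0)] <- jit[6:length(theta0)] * 0.2
      theta0 + jit
    }))
  })

  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, objective, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
    o <- stats::optim(o$par, objective, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("dual-model fit failed to converge from all starts (best objective ",
         format(best$value), ")")

  theta <- best$par
  params <- build(theta)
  Xc <- dual_steady_state(s_top, params)$X
  curve_par <- response_curve(
    function(s) 10^theta[6] * arabad_activity(s, params),
    domain = params$K_s * c(1e-6, 1e12))
  curve_mut <- response_curve(
    function(s) 10^theta[7] * arabad_activity(s, params, X_const = Xc),
    domain = params$K_s * c(1e-6, 1e12))

  implied <- lapply(list(parental = curve_par, mutant = curve_mut),
                    function(cv) {
    sup <- .estimate_sup(cv, attr(cv, "domain")[2])
    dr <- dynamic_range_numeric(cv, sup = sup, check_monotone = FALSE)
    K <- .crossing(cv, 0.5 * sup, attr(cv, "domain"))
    list(R = dr$R, K = K, s10 = dr$s10, s90 = dr$s90, sup = sup)
  })

  structure(list(
    params = params,
    scale_parental = 10^theta[6], scale_mutant = 10^theta[7],
    scale_arac = if (!is.null(dc)) 10^theta[8],
    X_const = Xc,
    curve_parental = curve_par, curve_mutant = curve_mut,
    R_parental = implied$parental$R, R_mutant = implied$mutant$R,
    K_parental = implied$parental$K, K_mutant = implied$mutant$K,
    objective = best$value, convergence = best$convergence,
    theta = theta
  ), class = "dual_fit")
}

#' @export
print.dual_fit <- function(x, ...) {
  cat("Dual-regulator mass-action fit\n")
  cat(sprintf("  K_s = %.3g mM, K_c = %.3g, K_act = %.3g, K_rep = %.3g, basal = %.3g\n",
              x$params$K_s, x$params$K_c, x$params$K_act, x$params$K_rep,
              x$params$basal))
  cat(sprintf("  implied parental: K = %.3g mM, R = %.3g\n",
              x$K_parental, x$R_parental))
  cat(sprintf("  implied mutant:   K = %.3g mM, R = %.3g (X clamped at %.3g)\n",
              x$K_mutant, x$R_mutant, x$X_const))
  cat(sprintf("  weighted log-space objective: %.4g\n", x$objective))
  invisible(x)
}
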