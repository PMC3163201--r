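# Promoter-activity extraction from OD/GFP kinetics: background
# subtraction against promoterless control wells, then the rate of GFP
# accumulation per OD unit, PA = (dGFP/dt)/OD, averaged over an
# exponential-phase window.

#' Subtract autofluorescence background from a reporter well
#'
#' The GFP background at each time point is the mean GFP of the
#' promoterless control wells, interpolated onto the reporter well's time
#' grid; it is subtracted from the reporter GFP.  An optional media blank
#' is removed from OD, which is then clipped at a small positive floor (OD
#' only; corrected GFP may legitimately be ~0 or slightly negative under
#' noise).
#'
#' @param well One well as a data frame (`time_h`, `od`, `gfp`, plus
#'   metadata columns).
#' @param background_wells Promoterless control wells: a list of well data
#'   frames, or one long data frame with a `well_id` column.
#' @param od_blank Optional scalar (or vector matching the time grid) media
#'   OD blank.
#' @param od_floor Positive floor applied to corrected OD.
#' @return The well with corrected `gfp` (and `od`, when a blank is given).
#' @export
subtract_background <- function(well, background_wells, od_blank = NULL,
                                od_floor = 1e-6) {
  stopifnot(is.data.frame(well),
            all(c("time_h", "od", "gfp") %in% names(well)))
  bg <- .as_well_list(background_wells)
  if (length(bg) == 0L) stop("background well set is empty")
  t_out <- well$time_h
  bg_gfp <- vapply(bg, function(b) {
    if (isTRUE(all.equal(b$time_h, t_out))) return(b$gfp)
    g <- stats::approx(b$time_h, b$gfp, xout = t_out, rule = 1)$y
    if (any(is.na(g)))
      stop("background wells do not cover the well's time grid; ",
           "cannot interpolate")
    g
  }, numeric(length(t_out)))
  well$gfp <- well$gfp - rowMeans(bg_gfp)
  if (!is.null(od_blank)) {
    well$od <- pmax(well$od - od_blank, od_floor)
  }
  well
}

.as_well_list <- function(x) {
  if (is.data.frame(x)) {
    if ("well_id" %in% names(x)) return(split(x, x$well_id))
    return(list(x))
  }
  stopifnot(is.list(x), all(vapply(x, is.data.frame, logical(1))))
  x
}

#' Promoter activity of one well
#'
#' Estimates `PA = (dGFP/dt)/OD` averaged over a time window.  The GFP
#' accumulation rate at each interior time point is the ordinary
#' least-squares slope over a centered sliding sub-window
#' (`2*half_width + 1` samples; 40 min at 8-min sampling with the default
#' `half_width = 2`), which is robust to a few percent of multiplicative
#' measurement noise where two-point differences are not.  Each local slope
#' is divided by the OD at the sub-window center; points whose OD falls
#' below `od_floor` are excluded, and the result is the mean over window
#' points with a standard error from the within-window scatter.
#'
#' @param well Background-corrected well data frame (`time_h`, `od`,
#'   `gfp`); time must be strictly increasing.
#' @param window Length-2 numeric, the averaging window in hours
#'   (default 5-7 h post-inoculation, 1-2 generations into exponential
#'   phase).
#' @param half_width Half-width (in samples) of the sliding regression
#'   sub-window.
#' @param od_floor OD values below this floor are treated as unusable.
#' @return A list of class `"promoter_activity"`: `activity`, `se`,
#'   `n_points`, `window`, and the per-point series `time`, `pa` (useful
#'   for inspecting within-window drift).
#' @export
promoter_activity <- function(well, window = c(5, 7), half_width = 2L,
                              od_floor = 1e-3) {
  stopifnot(is.data.frame(well),
            all(c("time_h", "od", "gfp") %in% names(well)))
  t <- well$time_h; od <- well$od; gfp <- well$gfp
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing length-2 interval")
  if (window[1] < min(t) || window[2] > max(t))
    stop("window lies outside the measured time range")
  h <- as.integer(half_width)
  n <- length(t)
  if (n < 2L * h + 2L) stop("too few samples for the derivative sub-window")

  centers <- (h + 1L):(n - h)
  dt <- diff(t)
  slope <- if (max(dt) - min(dt) < 1e-8 * mean(dt)) {
    # uniform grid: the OLS slope is a fixed linear filter
    kern <- (-h):h
    denom <- sum(kern^2) * mean(dt)
    # embed() rows run newest-to-oldest, so flip the kernel
    as.numeric(stats::embed(gfp, 2L * h + 1L) %*% rev(kern)) / denom
  } else {
    vapply(centers, function(i) {
      ii <- (i - h):(i + h)
      tt <- t[ii] - t[i]
      sum(tt * (gfp[ii] - mean(gfp[ii]))) / sum(tt^2)
    }, numeric(1))
  }

  in_win <- t[centers] >= window[1] & t[centers] <= window[2]
  if (sum(in_win) < 4L)
    stop("fewer than 4 samples fall inside the window")
  usable <- in_win & od[centers] >= od_floor
  if (!any(usable))
    stop("OD below floor throughout the window")
  pa <- slope[usable] / od[centers[usable]]
  m <- length(pa)
  structure(list(activity = mean(pa),
                 se = if (m > 1) stats::sd(pa) / sqrt(m) else NA_real_,
                 n_points = m, window = window,
                 time = t[centers[usable]], pa = pa),
            class = "promoter_activity")
}

#' @export
print.promoter_activity <- function(x, ...) {
  cat(sprintf("Promoter activity %.4g ± %.2g (s.e., %d points, window %g-%g h)\n",
              x$activity, x$se, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Build an input function from replicate wells
#'
#' Computes per-well promoter activities for one strain and aggregates them
#' per concentration: the activity is the mean across replicates and the
#' standard error is the standard error of that mean (falling back to the
#' single well's within-window s.e. when a concentration has one
#' replicate).  Concentration order is preserved; no concentration is
#' silently dropped.
#'
#' @param wells Background-corrected wells of one genotype: a list of well
#'   data frames or a long data frame with `well_id`.
#' @param window,half_width,od_floor Passed to [promoter_activity()].
#' @return A data frame (`arabinose_mM`, `activity`, `activity_se`,
#'   `n_wells`) sorted by concentration.
#' @export
build_input_function <- function(wells, window = c(5, 7), half_width = 2L,
                                 od_floor = 1e-3) {
  wl <- .as_well_list(wells)
  if (length(wl) == 0L) stop("no wells supplied")
  per_well <- lapply(wl, function(w) {
    pa <- promoter_activity(w, window = window, half_width = half_width,
                            od_floor = od_floor)
    data.frame(arabinose_mM = w$arabinose_mM[1], activity = pa$activity,
               se = pa$se)
  })
  tab <- do.call(rbind, per_well)
  agg <- lapply(split(tab, tab$arabinose_mM), function(g) {
    k <- nrow(g)
    se <- if (k > 1) stats::sd(g$activity) / sqrt(k) else g$se[1]
    data.frame(arabinose_mM = g$arabinose_mM[1],
               activity = mean(g$activity), activity_se = se, n_wells = k)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$arabinose_mM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract per-genotype input functions from a plate
#'
#' Convenience wrapper over the full activity pipeline: splits a long plate
#' table by genotype, subtracts the promoterless background from every
#' reporter well, and builds one input function per reporter genotype.
#'
#' @param plate Long plate data frame (see [generate_experiment()] /
#'   [read_plate_csv()]).
#' @param window,half_width,od_floor Passed to [promoter_activity()].
#' @param background_genotype Genotype name of the background wells.
#' @return A data frame with columns `genotype`, `arabinose_mM`,
#'   `activity`, `activity_se`, `n_wells`.
#' @export
extract_input_functions <- function(plate, window = c(5, 7),
                                    half_width = 2L, od_floor = 1e-3,
                                    background_genotype = "promoterless") {
  stopifnot(is.data.frame(plate), "genotype" %in% names(plate))
  bg <- plate[plate$genotype == background_genotype, , drop = FALSE]
  if (nrow(bg) == 0L)
    stop("plate contains no '", background_genotype, "' background wells")
  bg_wells <- split(bg, bg$well_id)

  # The same control-well mean is subtracted from every reporter well, so
  # its noise is a plate-wide additive offset on all activities.  Its s.d.
  # is estimated from the spread of the control wells' own residual
  # activities: each control well corrected by the k-well mean has
  # PA deviation e_j with sd(e_j) ~ sigma_well sqrt((k-1)/k), and the mean
  # of k wells errs with sigma_well/sqrt(k) = sd(e_j)/sqrt(k-1).
  bg_se <- NA_real_
  if (length(bg_wells) > 1L) {
    e <- tryCatch(vapply(bg_wells, function(wb) {
      cw <- subtract_background(wb, bg_wells)
      promoter_activity(cw, window = window, half_width = half_width,
                        od_floor = 0)$activity
    }, numeric(1)), error = function(e) NULL)
    if (!is.null(e)) bg_se <- stats::sd(e) / sqrt(length(e) - 1L)
  }
  reporters <- setdiff(unique(plate$genotype), background_genotype)
  out <- lapply(reporters, function(g) {
    wells <- split(plate[plate$genotype == g, , drop = FALSE],
                   plate$well_id[plate$genotype == g])
    corrected <- lapply(wells, subtract_background,
                        background_wells = bg_wells)
    fn <- build_input_function(corrected, window = window,
                               half_width = half_width, od_floor = od_floor)
    cbind(genotype = g, fn)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "background_se") <- bg_se
  res
}

#' Read and write input-function CSVs
#'
#' Columns `genotype`, `arabinose_mM`, `activity`, `activity_se`.
#'
#' @param inputfn Input-function data frame.
#' @param path File path.
#' @return `read_inputfn_csv()` returns the data frame.
#' @export
write_inputfn_csv <- function(inputfn, path) {
  need <- c("genotype", "arabinose_mM", "activity", "activity_se")
  if (!all(need %in% names(inputfn)))
    stop("input function table is missing columns: ",
         paste(setdiff(need, names(inputfn)), collapse = ", "))
  utils::write.csv(inputfn[, intersect(c(need, "n_wells"), names(inputfn))],
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_inputfn_csv
#' @export
read_inputfn_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
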