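# Plate-reader analytics: calibration, initial rates, Michaelis-Menten via
# Lineweaver-Burk, conversion, encapsulation efficiency, turbidity matrices,
# replicate outlier exclusion and line-scan normalization.

# simple-regression statistics computed directly so that exact synthetic data
# (zero residual) do not trip summary.lm()'s perfect-fit warning
.ols <- function(x, y) {
  n <- length(x)
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  if (sxx == 0) stop("degenerate regression: constant predictor")
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - ym)^2)
  sigma2 <- if (n > 2) ss_res / (n - 2) else 0
  se_slope <- sqrt(sigma2 / sxx)
  se_intercept <- sqrt(sigma2 * (1 / n + xm^2 / sxx))
  cov_ab <- -sigma2 * xm / sxx
  list(intercept = intercept, slope = slope,
       se_intercept = se_intercept, se_slope = se_slope,
       cov = matrix(c(se_intercept^2, cov_ab, cov_ab, se_slope^2), 2, 2),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Single-pass relative outlier exclusion
#'
#' The mean of ALL values is computed once; a value is excluded when its
#' relative deviation from that mean exceeds the threshold (25% for kinetics
#' data, 30% for calibration curves). The rule is single-pass: the mean is
#' never recomputed after exclusions.
#'
#' @param values Numeric replicate vector (>= 2 values).
#' @param mode `"kinetics"` (25%) or `"calibration"` (30%), or supply
#'   `threshold` directly.
#' @param threshold Relative deviation threshold overriding `mode`.
#' @return List with `retained`, `excluded`, `excluded_idx`, `mean`,
#'   `threshold`.
#' @export
exclude_outliers <- function(values, mode = c("kinetics", "calibration"),
                             threshold = NULL) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (is.null(threshold)) {
    mode <- match.arg(mode)
    threshold <- switch(mode, kinetics = 0.25, calibration = 0.30)
  }
  m <- mean(values)
  if (m == 0) stop("mean of values is 0; relative deviation undefined")
  dev <- abs(values - m) / abs(m)
  out <- dev > threshold
  list(retained = values[!out], excluded = values[out],
       excluded_idx = which(out), mean = m, threshold = threshold)
}

#' Fit a linear fluorescence-to-concentration calibration curve
#'
#' Blank-subtracted replicate signals are filtered per concentration level by
#' the 30% outlier rule, averaged, and fitted by ordinary least squares with
#' an intercept; only the slope is used downstream (signals are divided by
#' it).
#'
#' @param concentrations Concentration levels in mM (>= 3).
#' @param signals Numeric vector (one signal per level) or a list/matrix of
#'   replicates per level (matrix: one column per level).
#' @param blank Blank signal subtracted from every measurement (default 0).
#' @return Object of class `calibration_curve`: `slope` (AU/mM),
#'   `intercept`, `r_squared`, `level_means`, `excluded` (per-level report).
#' @export
fit_calibration <- function(concentrations, signals, blank = 0) {
  if (length(concentrations) < 3L) stop("need >= 3 concentration levels")
  reps <- if (is.matrix(signals)) {
    lapply(seq_len(ncol(signals)), function(j) signals[, j])
  } else if (is.list(signals)) signals else as.list(signals)
  if (length(reps) != length(concentrations))
    stop("signals must provide one entry (or column) per concentration level")
  excluded <- vector("list", length(reps))
  means <- numeric(length(reps))
  for (k in seq_along(reps)) {
    v <- reps[[k]] - blank
    if (length(v) >= 2L) {
      ex <- exclude_outliers(v, "calibration")
      excluded[[k]] <- ex$excluded
      v <- ex$retained
    } else excluded[[k]] <- numeric(0)
    if (!length(v)) { means[k] <- NA_real_; next }
    means[k] <- mean(v)
  }
  keep <- !is.na(means)
  if (sum(keep) < 3L)
    stop("fewer than 3 retained calibration levels after exclusion")
  fit <- .ols(concentrations[keep], means[keep])
  structure(list(slope = fit$slope,
                 intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 level_means = means, concentrations = concentrations,
                 excluded = excluded),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> slope %.4g AU/mM, intercept %.4g, r^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Initial rate from a kinetic time course
#'
#' The control trace is subtracted pointwise, an ordinary least-squares line
#' is fitted to the samples acquired up to `window` minutes, and the slope is
#' divided by the calibration-curve slope to convert AU/min to mM/min. The
#' standard error is propagated from the linear fit.
#'
#' @param time Sample times in minutes.
#' @param signal Fluorescence signal (AU).
#' @param control Control (substrate-free) trace subtracted pointwise; a
#'   scalar 0 disables the correction.
#' @param calibration A [fit_calibration()] result (slope in AU/mM).
#' @param window Fit window upper bound in minutes (default 2.5).
#' @return Object of class `initial_rate`: `v0` (mM/min), `se`,
#'   `raw_slope` (AU/min), `window`, `n`.
#' @export
initial_rate <- function(time, signal, control = 0, calibration,
                         window = 2.5) {
  stopifnot(inherits(calibration, "calibration_curve"))
  if (calibration$slope == 0) stop("calibration slope is zero")
  if (length(control) == 1L) control <- rep(control, length(signal))
  if (length(control) != length(signal))
    stop("control trace length must match the signal")
  if (window > max(time) - min(time) + 1e-9)
    stop("fit window exceeds the data span")
  corr <- signal - control
  keep <- time <= min(time) + window
  if (sum(keep) < 4L) stop("need >= 4 samples within the fit window")
  fit <- .ols(time[keep], corr[keep])
  structure(list(v0 = fit$slope / calibration$slope,
                 se = fit$se_slope / abs(calibration$slope),
                 raw_slope = fit$slope, window = window, n = sum(keep)),
            class = "initial_rate")
}

#' Michaelis-Menten parameters via the Lineweaver-Burk plot
#'
#' Ordinary least squares of 1/V0 on 1/S: V_max = 1/intercept,
#' K_m = slope * V_max, k_cat = V_max / catalyst concentration. Standard
#' errors are propagated from the regression by the delta method. The
#' double-reciprocal fit matches the source protocol; see
#' [fit_michaelis_menten_direct()] for the nonlinear alternative.
#'
#' @param substrate Substrate concentrations in mM (> 0, >= 3 levels).
#' @param v0 Initial rates in mM/min (> 0), one per level.
#' @param catalyst_conc Catalyst concentration in mM (> 0; default 3, the
#'   assay's peptide concentration).
#' @return Object of class `mm_fit`: `v_max`, `k_m`, `k_cat` (1/min),
#'   `se_v_max`, `se_k_m`, `lb_intercept`, `lb_slope`.
#' @export
michaelis_menten_parameters <- function(substrate, v0, catalyst_conc = 3) {
  if (length(substrate) < 3L) stop("need >= 3 substrate levels")
  if (any(substrate <= 0) || any(v0 <= 0))
    stop("substrate and v0 must be strictly positive")
  if (catalyst_conc <= 0) stop("catalyst_conc must be > 0")
  xi <- 1 / substrate
  yi <- 1 / v0
  fit <- .ols(xi, yi)
  b0 <- fit$intercept   # 1/V_max
  b1 <- fit$slope       # K_m/V_max
  if (b0 <= 0)
    stop("Lineweaver-Burk intercept <= 0 implies an unphysical V_max")
  vc <- fit$cov
  v_max <- 1 / b0
  k_m <- b1 / b0
  # delta method: V_max = 1/b0, K_m = b1/b0
  se_v_max <- sqrt(vc[1, 1]) / b0^2
  g <- c(-b1 / b0^2, 1 / b0)
  se_k_m <- sqrt(drop(t(g) %*% vc %*% g))
  structure(list(v_max = v_max, k_m = k_m,
                 k_cat = v_max / catalyst_conc,
                 se_v_max = se_v_max, se_k_m = se_k_m,
                 se_k_cat = se_v_max / catalyst_conc,
                 lb_intercept = b0, lb_slope = b1,
                 catalyst_conc = catalyst_conc),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> V_max %.4g mM/min, K_m %.4g mM, k_cat %.4g 1/min\n",
              x$v_max, x$k_m, x$k_cat))
  invisible(x)
}

#' Direct nonlinear Michaelis-Menten fit (labeled alternative)
#'
#' Nonlinear least squares of V0 = V_max * S / (K_m + S). Provided as a
#' statistically preferable cross-check; [michaelis_menten_parameters()]
#' (Lineweaver-Burk) remains the default analysis route.
#'
#' @inheritParams michaelis_menten_parameters
#' @return List with `v_max`, `k_m`, `k_cat`.
#' @export
fit_michaelis_menten_direct <- function(substrate, v0, catalyst_conc = 3) {
  if (length(substrate) < 3L) stop("need >= 3 substrate levels")
  start <- list(v_max = max(v0) * 1.2, k_m = stats::median(substrate))
  fit <- minpack.lm::nlsLM(v0 ~ v_max * substrate / (k_m + substrate),
                           start = start,
                           lower = c(v_max = 1e-12, k_m = 1e-12))
  cf <- stats::coef(fit)
  list(v_max = unname(cf["v_max"]), k_m = unname(cf["k_m"]),
       k_cat = unname(cf["v_max"]) / catalyst_conc)
}

#' Percent substrate conversion
#'
#' 100 * product concentration / substrate concentration; negative products
#' (possible after blank subtraction) are clamped to 0 and flagged.
#'
#' @param product_conc Product concentration in mM.
#' @param substrate_conc Total substrate in mM (default 0.7, the assay's
#'   working concentration).
#' @return Numeric percent vector with attribute `clamped` (logical vector).
#' @export
percent_conversion <- function(product_conc, substrate_conc = 0.7) {
  if (any(substrate_conc <= 0)) stop("substrate_conc must be > 0")
  clamped <- product_conc < 0
  p <- pmax(product_conc, 0)
  structure(100 * p / substrate_conc, clamped = clamped)
}

#' Encapsulation efficiency from total and supernatant concentrations
#'
#' EE = (C_T - C_sup) / C_T, reported as fraction and percent. A supernatant
#' concentration above the total yields a negative EE which is flagged, not
#' clipped.
#'
#' @param c_total Total concentration C_T in mM (> 0).
#' @param c_supernatant Supernatant concentration C_sup in mM.
#' @return List with `fraction`, `percent`, `flag_negative`.
#' @export
percent_ee <- function(c_total, c_supernatant) {
  if (any(c_total <= 0)) stop("c_total must be > 0")
  frac <- (c_total - c_supernatant) / c_total
  list(fraction = frac, percent = 100 * frac, flag_negative = frac < 0)
}

#' Turbidity phase-diagram matrix
#'
#' Replicate absorbances are averaged per condition, the buffer blank is
#' subtracted, and negative values are set to 0. Missing condition cells stay
#' missing.
#'
#' @param data `data.frame` with columns `conc_a`, `conc_b`, `absorbance`
#'   (replicate rows per condition).
#' @param blank Buffer background absorbance (AU).
#' @return Numeric matrix indexed by the two peptide concentrations (rows =
#'   `conc_a`, columns = `conc_b`).
#' @export
turbidity_matrix <- function(data, blank = 0) {
  need <- c("conc_a", "conc_b", "absorbance")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  la <- sort(unique(data$conc_a))
  lb <- sort(unique(data$conc_b))
  m <- matrix(NA_real_, length(la), length(lb),
              dimnames = list(as.character(la), as.character(lb)))
  agg <- stats::aggregate(absorbance ~ conc_a + conc_b, data = data, FUN = mean)
  for (r in seq_len(nrow(agg))) {
    m[as.character(agg$conc_a[r]), as.character(agg$conc_b[r])] <-
      max(agg$absorbance[r] - blank, 0)
  }
  m
}

#' Min-max normalization of a line-scan intensity profile
#'
#' Affine map (I - I_min) / (I_max - I_min) onto [0, 1]; the endpoints are
#' hit exactly. Constant profiles are an error.
#'
#' @param profile Numeric intensity vector.
#' @return Normalized vector in [0, 1].
#' @export
minmax_normalize <- function(profile) {
  rng <- range(profile)
  if (rng[1] == rng[2]) stop("constant profile: min-max undefined")
  (profile - rng[1]) / (rng[2] - rng[1])
}
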