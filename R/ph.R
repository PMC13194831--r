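# Ratiometric pH determination from two-channel emission data.
#
# The calibration model is a four-parameter logistic in base 10,
#
#   R(pH) = R_acid + (R_base - R_acid) / (1 + 10^(k * (pH50 - pH))),
#
# chosen because it admits the closed-form inversion
#
#   pH = pH50 - (1/k) * log10((R_base - R_acid) / (R - R_acid) - 1),
#
# so measured emission ratios map to pH by solving the calibration equation
# exactly rather than numerically.

#' Fit a ratiometric pH calibration (4-parameter logistic)
#'
#' @param ph Buffer pH values (>= 4 distinct levels spanning the transition).
#' @param ratio Measured emission ratios (e.g. I580/I640), one per pH (or
#'   replicate-averaged upstream).
#' @param condition Optional condition tag stored with the fit (e.g. the
#'   Zn2+ level; calibrations are fitted per condition, never pooled).
#' @return Object of class `ph_calibration`: `r_acid`, `r_base`, `ph50`,
#'   `k`, `residuals`, `condition`.
#' @export
fit_ph_calibration <- function(ph, ratio, condition = NA_character_) {
  if (length(ph) != length(ratio)) stop("ph and ratio lengths differ")
  if (length(unique(ph)) < 4L) stop("need >= 4 distinct pH levels")
  ord <- order(ph)
  rs <- ratio[ord]
  rho <- stats::cor(ph, ratio, method = "spearman")
  if (is.na(rho) || abs(rho) < 0.5)
    stop("calibration data are not monotone in pH (spearman rho = ",
         signif(rho, 3), "); cannot fit a logistic")
  r_lo <- rs[1]; r_hi <- rs[length(rs)]
  mid_ratio <- (r_lo + r_hi) / 2
  ph50_0 <- stats::approx(rs, ph[ord], xout = mid_ratio, ties = mean)$y
  if (is.na(ph50_0)) ph50_0 <- stats::median(ph)
  span <- abs(r_hi - r_lo)
  start <- list(r_acid = r_lo, r_base = r_hi, ph50 = ph50_0, k = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ r_acid + (r_base - r_acid) / (1 + 10^(k * (ph50 - ph))),
      data = data.frame(ph = ph, ratio = ratio),
      start = start,
      lower = c(r_acid = -Inf, r_base = -Inf, ph50 = min(ph) - 5, k = 1e-4),
      upper = c(r_acid = Inf, r_base = Inf, ph50 = max(ph) + 5, k = 100),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("pH calibration fit did not converge (starts: r_acid=",
           signif(r_lo, 4), ", r_base=", signif(r_hi, 4), ", ph50=",
           signif(ph50_0, 4), ", k=1): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(r_acid = unname(cf["r_acid"]),
                 r_base = unname(cf["r_base"]),
                 ph50 = unname(cf["ph50"]), k = unname(cf["k"]),
                 residuals = stats::resid(fit),
                 condition = condition),
            class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("<ph_calibration> R_acid %.4g, R_base %.4g, pH50 %.3f, k %.3f%s\n",
              x$r_acid, x$r_base, x$ph50, x$k,
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  invisible(x)
}

#' Predicted emission ratio at a given pH
#' @param cal A [fit_ph_calibration()] result (or any list with `r_acid`,
#'   `r_base`, `ph50`, `k`).
#' @param ph pH values.
#' @return Predicted ratios.
#' @export
predict_ratio <- function(cal, ph) {
  .logistic_ratio(ph, cal$r_acid, cal$r_base, cal$ph50, cal$k)
}

#' Invert an emission ratio to pH (closed form)
#'
#' Exact inversion of the logistic calibration; ratios at or beyond the
#' asymptotes (`r_acid`, `r_base`) are out of range and raise an error —
#' the calibration is never extrapolated silently.
#'
#' @param ratio Emission ratios to invert.
#' @param cal A [fit_ph_calibration()] result.
#' @return pH values.
#' @export
ratio_to_ph <- function(ratio, cal) {
  lo <- min(cal$r_acid, cal$r_base)
  hi <- max(cal$r_acid, cal$r_base)
  bad <- ratio <= lo | ratio >= hi
  if (any(bad))
    stop("ratio(s) ", paste(signif(ratio[bad], 5), collapse = ", "),
         " outside the open asymptote interval (", signif(lo, 5), ", ",
         signif(hi, 5), "); cannot invert")
  cal$ph50 - (1 / cal$k) *
    log10((cal$r_base - cal$r_acid) / (ratio - cal$r_acid) - 1)
}

#' Per-phase pH summary from ROI ratio tables
#'
#' Dilute-phase (background) ROIs within one image are averaged to a single
#' ratio BEFORE inversion — one pH per image — while dense-phase ROIs are
#' inverted individually. Aggregates (mean, SD, n) are reported per phase.
#'
#' @param rois `data.frame` with columns `image_id`, `phase`
#'   (`"dense"`/`"dilute"`), `I580`, `I640` and optionally `condition`.
#' @param calibrations A single `ph_calibration` or a named list keyed by
#'   condition.
#' @return List with `per_observation` (data.frame of inverted pH values)
#'   and `summary` (per-phase mean, sd, n).
#' @export
phase_ph_summary <- function(rois, calibrations) {
  need <- c("image_id", "phase", "I580", "I640")
  if (!all(need %in% names(rois)))
    stop("rois needs columns: ", paste(need, collapse = ", "))
  if (any(rois$I640 <= 0)) stop("I640 must be positive")
  if (is.null(rois$condition)) rois$condition <- "default"
  single <- inherits(calibrations, "ph_calibration")
  get_cal <- function(cond) {
    if (single) return(calibrations)
    cal <- calibrations[[cond]]
    if (is.null(cal)) stop("no calibration for condition '", cond, "'")
    cal
  }
  rois$ratio <- rois$I580 / rois$I640
  obs <- list()
  for (cond in unique(rois$condition)) {
    cal <- get_cal(cond)
    sub <- rois[rois$condition == cond, , drop = FALSE]
    dense <- sub[sub$phase == "dense", , drop = FALSE]
    if (nrow(dense)) {
      obs[[length(obs) + 1L]] <- data.frame(
        condition = cond, phase = "dense", image_id = dense$image_id,
        ratio = dense$ratio, ph = ratio_to_ph(dense$ratio, cal))
    }
    dilute <- sub[sub$phase == "dilute", , drop = FALSE]
    if (nrow(dilute)) {
      per_img <- tapply(dilute$ratio, dilute$image_id, mean)
      obs[[length(obs) + 1L]] <- data.frame(
        condition = cond, phase = "dilute", image_id = names(per_img),
        ratio = as.numeric(per_img),
        ph = ratio_to_ph(as.numeric(per_img), cal))
    }
  }
  per_obs <- do.call(rbind, obs)
  summ <- stats::aggregate(ph ~ condition + phase, data = per_obs,
                           FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                               n = length(v)))
  summ <- cbind(summ[, c("condition", "phase")], as.data.frame(summ$ph))
  summ$sd[summ$n == 1] <- 0
  list(per_observation = per_obs, summary = summ)
}
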