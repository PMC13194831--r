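# FRAP trace correction, normalization and exponential recovery fitting.
#
# Double normalization: the bleached-ROI intensity R1 is background-subtracted
# and corrected for acquisition photofading via the reference ROI R2,
#
#   I_corr(t) = (R1(t) - R3(t)) * (R2_pre - R3_pre) / (R2(t) - R3(t)),
#
# then min-max scaled so the post-bleach minimum is 0% and the pre-bleach
# mean is 100%. The recovery model fitted to the normalized trace is
# y(x) = a - b * c^x with x in seconds from the bleach; the half time is
# t_1/2 = log_c(0.5 * a / b) and the plateau a is the recovery percentage
# (mobile fraction).

#' Assemble a FRAP trace
#'
#' @param time Sample times in seconds (strictly increasing).
#' @param R1 Bleached-ROI intensity (AU).
#' @param R2 Reference-ROI intensity (AU).
#' @param R3 Background intensity (AU).
#' @param bleach_index Index of the first post-bleach sample (>= 2).
#' @param prebleach_window Indices used for pre-bleach means (default all
#'   samples before the bleach).
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(time, R1, R2, R3,
                       bleach_index, prebleach_window = NULL) {
  n <- length(time)
  if (length(R1) != n || length(R2) != n || length(R3) != n)
    stop("time, R1, R2, R3 must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (bleach_index < 2L || bleach_index > n)
    stop("bleach_index must lie in [2, length(time)]")
  if (is.null(prebleach_window)) prebleach_window <- seq_len(bleach_index - 1L)
  if (any(prebleach_window >= bleach_index) || any(prebleach_window < 1L))
    stop("prebleach_window must be a subset of [1, bleach_index)")
  structure(list(time = time, R1 = R1, R2 = R2, R3 = R3,
                 bleach_index = as.integer(bleach_index),
                 prebleach_window = as.integer(prebleach_window)),
            class = "frap_trace")
}

#' Correct and normalize a FRAP trace (double normalization)
#'
#' @param trace A [frap_trace()] object.
#' @return Object of class `corrected_trace`: `time`, `I_corrected`,
#'   `I_normalized` (percent), `I_min`, `I_pre`, `bleach_index`.
#' @export
correct_and_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  denom <- trace$R2 - trace$R3
  bad <- which(denom == 0 | sign(denom) != sign(denom[1]))
  if (length(bad))
    stop("R2 - R3 crosses zero at sample(s) ", paste(bad, collapse = ", "))
  pre <- trace$prebleach_window
  r2_pre <- mean(trace$R2[pre])
  r3_pre <- mean(trace$R3[pre])
  i_corr <- (trace$R1 - trace$R3) * (r2_pre - r3_pre) / denom
  post <- seq(trace$bleach_index, length(trace$time))
  i_min <- min(i_corr[post])
  i_pre <- mean(i_corr[pre])
  if (i_pre == i_min)
    stop("degenerate trace: pre-bleach mean equals the post-bleach minimum")
  structure(list(time = trace$time,
                 I_corrected = i_corr,
                 I_normalized = 100 * (i_corr - i_min) / (i_pre - i_min),
                 I_min = i_min, I_pre = i_pre,
                 R2_pre = r2_pre, R3_pre = r3_pre,
                 bleach_index = trace$bleach_index),
            class = "corrected_trace")
}

#' Half time of the fitted recovery model
#'
#' t_1/2 = log_c(0.5 * a / b); defined only when 0.5 * a / b lies in (0, 1).
#'
#' @param a,b,c Fitted model parameters.
#' @return Half time in the model's time unit, or `NA` when undefined.
#' @export
recovery_half_time <- function(a, b, c) {
  q <- unname(0.5 * a / b)
  if (q <= 0 || q >= 1) return(NA_real_)
  log(q) / log(unname(c))
}

#' Fit the exponential recovery model to a normalized FRAP trace
#'
#' Bounded nonlinear least squares of y = a - b * c^x on the post-bleach
#' samples (x measured in seconds from the first post-bleach sample),
#' optionally truncated at an evaluation horizon. Initialization: a0 from the
#' tail mean, b0 = a0 - y(0), c0 from a log-linear regression of (a0 - y).
#'
#' @param corrected A [correct_and_normalize()] result.
#' @param horizon Evaluation horizon in seconds from the bleach (default
#'   `Inf`, the full trace).
#' @return Object of class `recovery_fit`: `a`, `b`, `c`, `t_half`,
#'   `recovery_percent` (= a), `sigma`, `cov`, `horizon`, `n`,
#'   `t_half_defined`.
#' @export
fit_recovery <- function(corrected, horizon = Inf) {
  stopifnot(inherits(corrected, "corrected_trace"))
  post <- seq(corrected$bleach_index, length(corrected$time))
  x <- corrected$time[post] - corrected$time[post[1]]
  y <- corrected$I_normalized[post]
  keep <- x <= horizon
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L)
    stop("need at least 5 post-bleach samples within the horizon")
  ntail <- max(3L, ceiling(0.1 * length(y)))
  a0 <- mean(utils::tail(y, ntail))
  if (a0 <= 0) a0 <- max(y[y > 0], 1)
  b0 <- max(a0 - y[1], 1e-3)
  resid0 <- a0 - y
  pos <- resid0 > 0
  c0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(resid0[pos]) ~ x[pos]))[2]
    min(max(exp(sl), 1e-4), 1 - 1e-4)
  } else 0.9
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a - b * c^x, data = dat,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = 1e-8, b = 1e-8, c = 1e-8),
                      upper = c(a = 200, b = Inf, c = 1 - 1e-10),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("recovery fit did not converge (starts a0=", signif(a0, 4),
           ", b0=", signif(b0, 4), ", c0=", signif(c0, 4), "): ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  th <- recovery_half_time(cf["a"], cf["b"], cf["c"])
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]),
                 t_half = th, t_half_defined = !is.na(th),
                 recovery_percent = unname(cf["a"]),
                 sigma = stats::sigma(fit), cov = stats::vcov(fit),
                 horizon = horizon, n = length(x)),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> a=%.2f%% b=%.2f c=%.5f t1/2=%s s (n=%d)\n",
              x$a, x$b, x$c,
              if (x$t_half_defined) sprintf("%.2f", x$t_half) else "undefined",
              x$n))
  invisible(x)
}

#' Summarize recovery fits per condition
#'
#' Per-droplet values are preserved; the aggregate reports mean and SD of the
#' half time and recovery percentage. With a single fit the SD is reported as
#' 0 and flagged.
#'
#' @param fits List of [fit_recovery()] results.
#' @param grid_interval Optional interval (s) for an averaged model curve on a
#'   common time grid (default `NULL`, skip).
#' @param grid_horizon Horizon (s) of the averaged curve (default the
#'   smallest fitted horizon, capped at 180 s when all horizons are
#'   infinite).
#' @return List with `per_fit` (data.frame), `mean_t_half`, `sd_t_half`,
#'   `mean_recovery`, `sd_recovery`, `n`, `single_fit` flag and optionally
#'   `mean_curve`.
#' @export
summarize_frap <- function(fits, grid_interval = NULL, grid_horizon = NULL) {
  if (!length(fits)) stop("need at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "recovery_fit")))
  per <- data.frame(
    t_half = vapply(fits, function(f) f$t_half, numeric(1)),
    recovery_percent = vapply(fits, function(f) f$recovery_percent, numeric(1)),
    a = vapply(fits, function(f) f$a, numeric(1)),
    b = vapply(fits, function(f) f$b, numeric(1)),
    c = vapply(fits, function(f) f$c, numeric(1)))
  single <- nrow(per) == 1L
  out <- list(per_fit = per,
              mean_t_half = mean(per$t_half, na.rm = TRUE),
              sd_t_half = if (single) 0 else stats::sd(per$t_half, na.rm = TRUE),
              mean_recovery = mean(per$recovery_percent),
              sd_recovery = if (single) 0 else stats::sd(per$recovery_percent),
              n = nrow(per), single_fit = single)
  if (!is.null(grid_interval)) {
    if (is.null(grid_horizon)) {
      hz <- vapply(fits, function(f) f$horizon, numeric(1))
      grid_horizon <- if (all(is.infinite(hz))) 180 else min(hz[is.finite(hz)])
    }
    grid <- seq(0, grid_horizon, by = grid_interval)
    curves <- vapply(fits, function(f) f$a - f$b * f$c^grid,
                     numeric(length(grid)))
    out$mean_curve <- data.frame(time = grid,
                                 mean = rowMeans(curves),
                                 sd = apply(curves, 1, stats::sd))
  }
  out
}
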