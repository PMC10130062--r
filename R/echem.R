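# Cyclic-voltammetry analytics: peak picking on a two-segment sweep and the
# Randles-Sevcik scan-rate analysis that yields the diffusion coefficient of
# a freely diffusing redox couple.

#' Analyze a cyclic voltammogram
#'
#' Splits the trace into forward/reverse sweep segments, optionally smooths
#' each with a Savitzky-Golay filter, and reports anodic/cathodic peak
#' potentials and currents, the half-wave potential and the peak separation.
#' Potentials are converted to SHE through `reference_offset`.
#'
#' @param data data frame with columns `potential_V` and `current_A` (one full
#'   cycle, monotone sweep segments).
#' @param reference_offset volts added to convert the potential axis to SHE
#'   (0.206 V for Ag/AgCl 3 M NaCl; default 0).
#' @param smooth_window odd Savitzky-Golay window length in points (0 or 1
#'   disables smoothing).
#' @param baseline "none" or "linear" (subtract a line through the segment
#'   endpoints before peak picking).
#' @return list (class `mm_cv`): `E_pa`, `E_pc`, `i_pa`, `i_pc`, `E_half`,
#'   `delta_Ep` (all vs SHE where applicable) and `flags` (e.g. "no peaks").
#' @export
analyze_voltammogram <- function(data, reference_offset = 0, smooth_window = 0,
                                 baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  E <- data$potential_V; I <- data$current_A
  if (is.null(E) || is.null(I)) abort("need columns potential_V and current_A")
  dE <- diff(E)
  turn <- which(diff(sign(dE[dE != 0])) != 0)
  segs <- if (length(turn)) {
    brk <- which(dE != 0)[turn[1]] + 1
    list(seq_len(brk), seq(brk, length(E)))
  } else list(seq_along(E))
  pick <- function(idx, direction) {
    e <- E[idx]; i <- I[idx]
    if (baseline == "linear") {
      i <- i - (i[1] + (i[length(i)] - i[1]) * (e - e[1]) / (e[length(e)] - e[1]))
    }
    if (smooth_window > 2) {
      w <- min(smooth_window, length(i) - (1 - length(i) %% 2))
      if (w %% 2 == 0) w <- w - 1
      if (w >= 5) i <- signal::sgolayfilt(i, p = 3, n = w)
    }
    k <- if (direction > 0) which.max(i) else which.min(i)
    # a peak must be interior and rise above the segment noise floor
    amp <- abs(i[k] - stats::median(i))
    if (k <= 2 || k >= length(i) - 1 || amp < 10 * .Machine$double.eps) {
      return(NULL)
    }
    list(E = e[k], i = I[idx][k])
  }
  flags <- character(0)
  anodic <- cathodic <- NULL
  for (sg in segs) {
    up <- mean(diff(E[sg])) > 0
    p <- pick(sg, if (up) 1 else -1)
    if (is.null(p)) next
    if (up) anodic <- p else cathodic <- p
  }
  if (is.null(anodic) && is.null(cathodic)) flags <- c(flags, "no peaks")
  E_pa <- if (!is.null(anodic)) anodic$E + reference_offset else NA_real_
  E_pc <- if (!is.null(cathodic)) cathodic$E + reference_offset else NA_real_
  out <- list(
    E_pa = E_pa, E_pc = E_pc,
    i_pa = if (!is.null(anodic)) anodic$i else NA_real_,
    i_pc = if (!is.null(cathodic)) cathodic$i else NA_real_,
    E_half = if (!is.null(anodic) && !is.null(cathodic)) (E_pa + E_pc) / 2
             else NA_real_,
    delta_Ep = if (!is.null(anodic) && !is.null(cathodic)) E_pa - E_pc
               else NA_real_,
    flags = flags)
  class(out) <- "mm_cv"
  out
}

#' @export
print.mm_cv <- function(x, ...) {
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  cat(sprintf("E_pa %.4f V, E_pc %.4f V, E_half %.4f V, dEp %.0f mV (vs SHE)\n",
              x$E_pa, x$E_pc, x$E_half, 1000 * x$delta_Ep))
  invisible(x)
}

#' Randles-Sevcik fit of peak currents vs scan rate
#'
#' Fits `i_p = 0.4463 n F A C sqrt(n F v D / (R T))` by least squares of
#' `|i_p|` on `sqrt(v)` (zero intercept) and converts the slope to the
#' diffusion coefficient.
#'
#' @param peaks data frame with columns `scan_rate` (V/s) and `i_p` (A;
#'   consistent sign within the branch).
#' @param n electrons transferred.
#' @param area electrode area, cm².
#' @param conc bulk concentration, mol/cm³.
#' @param temperature K (default 298.15).
#' @return object of class `mm_fit`: `params` (D, cm²/s; slope), `stderr`,
#'   `residual_rms`, `n_points`, `data`, `model`.
#' @export
randles_sevcik_fit <- function(peaks, n = 1, area, conc, temperature = 298.15) {
  if (nrow(peaks) < 3) abort("need at least 3 scan rates")
  v <- peaks$scan_rate; ip <- abs(peaks$i_p)
  if (any(v <= 0)) abort("scan rates must be positive")
  fit <- lm(ip ~ 0 + sqrt(v))
  slope <- unname(coef(fit)[1])
  # noise-free synthetic peaks are legitimate input; lm warns on perfect fits
  se_slope <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[1]))
  if (slope <= 0) {
    return(new_mm_fit(params = c(D = NA_real_, slope = slope),
                      stderr = c(D = NA_real_, slope = se_slope),
                      residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                      n_points = nrow(peaks), data = as_tibble(peaks),
                      model = "randles_sevcik", flags = "non-positive slope"))
  }
  k <- 0.4463 * n * .FARADAY * area * conc * sqrt(n * .FARADAY / (.RGAS * temperature))
  D <- (slope / k)^2
  se_D <- 2 * D * se_slope / slope
  new_mm_fit(params = c(D = D, slope = slope),
             stderr = c(D = se_D, slope = se_slope),
             residual_rms = sqrt(mean(stats::residuals(fit)^2)),
             n_points = nrow(peaks), data = as_tibble(peaks),
             model = "randles_sevcik", flags = character(0))
}

new_mm_fit <- function(params, stderr, residual_rms, n_points, data, model,
                       flags = character(0), fitted = NULL) {
  structure(list(params = params, stderr = stderr, residual_rms = residual_rms,
                 n_points = n_points, data = data, model = model, flags = flags,
                 fitted = fitted),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  for (nm in names(x$params)) {
    cat(sprintf("  %-12s %.6g", nm, x$params[[nm]]))
    if (nm %in% names(x$stderr) && is.finite(x$stderr[[nm]])) {
      cat(sprintf(" ± %.2g", x$stderr[[nm]]))
    }
    cat("\n")
  }
  cat(sprintf("  residual rms %.3g over %d points\n", x$residual_rms, x$n_points))
  invisible(x)
}
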