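# 1:1 binding isotherm (exact quadratic, valid in the tight-binding regime
# where ligand depletion matters), extinction-coefficient bookkeeping, and
# Beer-Lambert concentration conversion.

#' Complex concentration under exact 1:1 binding
#'
#' `[PL] = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2`.
#'
#' @param ligand_total,protein_total molar totals.
#' @param kd dissociation constant, M (0 allowed: stoichiometric limit).
#' @return complex concentration, M.
#' @export
binding_complex <- function(ligand_total, protein_total, kd) {
  s <- protein_total + ligand_total + kd
  (s - sqrt(pmax(s^2 - 4 * protein_total * ligand_total, 0))) / 2
}

#' Fit a 1:1 binding isotherm to a spectrophotometric titration
#'
#' Signal model: `A = eps_complex * [PL] * pathlength + baseline` with `[PL]`
#' from the exact quadratic 1:1 model. Fitted by bounded Levenberg-Marquardt
#' least squares over (Kd, eps_complex, baseline). When the optimizer pushes
#' Kd to its lower bound (0) the estimate is reported as an upper limit
#' (`kd_is_upper_limit`), the tight-binding regime where the titration only
#' bounds Kd from above.
#'
#' @param data data frame with columns `ligand_total_M` (non-decreasing) and
#'   `absorbance`.
#' @param protein_total protein concentration, M.
#' @param pathlength cm (default 1).
#' @return `mm_fit` with params `kd` (M), `eps_complex` (M^-1 cm^-1),
#'   `baseline`; flag "kd upper limit" when at the bound. `fitted` holds the
#'   model curve.
#' @export
fit_binding_isotherm <- function(data, protein_total, pathlength = 1) {
  L <- data$ligand_total_M; A <- data$absorbance
  if (is.null(L) || is.null(A)) abort("need columns ligand_total_M and absorbance")
  if (protein_total <= 0) abort("protein_total must be positive")
  if (length(L) < 5) abort("need at least 5 titration points")
  if (any(diff(L) < 0)) abort("ligand_total_M must be non-decreasing")
  # fit in units of the protein concentration so every parameter is O(1)
  # (micromolar-scale Kd values otherwise underflow the numeric Jacobian);
  # Levenberg-Marquardt with a box constraint keeping Kd non-negative
  amp0 <- max(max(A) - min(A), 1e-6)
  l <- L / protein_total
  model <- function(p) p["amp"] * binding_complex(l, 1, p["kds"]) + p["b0"]
  fit <- minpack.lm::nls.lm(
    par = c(kds = 0.1, amp = amp0, b0 = min(A)),
    lower = c(kds = 0, amp = 0, b0 = -Inf),
    fn = function(p) A - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  n <- length(L); npar <- 3
  se <- tryCatch({
    s2 <- fit$deviance / max(n - npar, 1)
    out <- sqrt(diag(solve(fit$hessian)) * s2)
    setNames(out, names(est))
  }, error = function(e) setNames(rep(NA_real_, 3), names(est)))
  kd <- unname(est["kds"]) * protein_total
  eps <- unname(est["amp"]) / (protein_total * pathlength)
  at_bound <- est["kds"] <= 1e-6
  flags <- if (at_bound) "kd upper limit" else character(0)
  fitted_curve <- tibble(ligand_total_M = L, absorbance = model(est))
  new_mm_fit(
    params = c(kd = kd, eps_complex = eps, baseline = unname(est["b0"])),
    stderr = c(kd = unname(se["kds"]) * protein_total,
               eps_complex = unname(se["amp"]) / (protein_total * pathlength),
               baseline = unname(se["b0"])),
    residual_rms = sqrt(fit$deviance / length(L)),
    n_points = length(L),
    data = tibble(L = L, A = A), model = "binding_isotherm_1to1",
    flags = flags, fitted = fitted_curve)
}

#' Equivalence-point breakpoint of a stoichiometric titration
#'
#' For Kd -> 0 data the signal rises linearly and plateaus at exactly one
#' ligand equivalent; the breakpoint is located as the intersection of the
#' rising and plateau line fits.
#'
#' @param data titration table as in [fit_binding_isotherm()].
#' @param protein_total protein concentration, M.
#' @return breakpoint in ligand equivalents.
#' @export
titration_breakpoint <- function(data, protein_total) {
  eq <- data$ligand_total_M / protein_total
  A <- data$absorbance
  lo <- eq <= 0.5
  hi <- eq >= 1.5
  if (sum(lo) < 2 || sum(hi) < 2) abort("need points well below and above 1 eq")
  f1 <- lm(A ~ eq, data = data.frame(A = A[lo], eq = eq[lo]))
  f2 <- lm(A ~ eq, data = data.frame(A = A[hi], eq = eq[hi]))
  b <- coef(f1); p <- coef(f2)
  unname((p[1] - b[1]) / (b[2] - p[2]))
}

# residue extinction contributions at 280 nm (M^-1 cm^-1)
.EPS280 <- c(TRP = 5500, TYR = 1490, CYSTINE = 125)

#' Protein extinction coefficient at 280 nm
#'
#' `eps280 = 5500 nTrp + 1490 nTyr + 125 nCystine`. Accepts 1-letter codes;
#' "X" denotes Aib (2-aminoisobutyric acid), which does not absorb.
#'
#' @param sequence 1-letter amino-acid string.
#' @param n_cystine number of disulfide bridges (default 0; free thiols do not
#'   contribute).
#' @return eps280 in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(sequence, n_cystine = 0) {
  codes <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(codes, names(.AA3))
  if (length(bad)) {
    abort(paste0("unknown residue code(s): ", paste(unique(bad), collapse = ", ")))
  }
  unname(.EPS280["TRP"] * sum(codes == "W") + .EPS280["TYR"] * sum(codes == "Y") +
           .EPS280["CYSTINE"] * n_cystine)
}

#' Beer-Lambert concentration
#'
#' @param absorbance measured absorbance (dimensionless).
#' @param epsilon molar absorptivity in mM^-1 cm^-1.
#' @param pathlength cm.
#' @return concentration in µM.
#' @export
beer_lambert_concentration <- function(absorbance, epsilon, pathlength = 1) {
  if (any(epsilon <= 0)) abort("epsilon must be positive")
  1000 * absorbance / (epsilon * pathlength)
}
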