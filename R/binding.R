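# Multiphasic binding-isotherm model and fitting for MST-style titrations:
# exact 1:1 ligand-depletion isotherm, amplitude-weighted sums of
# independent binding phases, multi-start least-squares fitting with
# kd-ordering enforced by log-gap parameterization, BIC phase-count
# selection, and a Hill-type self-association model.

#' Exact 1:1 ligand-depletion binding isotherm
#'
#' Fraction of labeled species bound at total titrant concentration `P`,
#' total labeled concentration `L` and dissociation constant `kd`:
#' `theta = ((P + L + kd) - sqrt((P + L + kd)^2 - 4 P L)) / (2 L)`.
#' This is the exact solution of the 1:1 equilibrium and remains valid when
#' `kd` is comparable to `L`, where the hyperbolic approximation
#' `P / (P + kd)` (its `L -> 0` limit) fails.
#'
#' @param P titrant (protein) concentration(s), molar.
#' @param kd dissociation constant, molar (> 0).
#' @param L labeled-species concentration, molar.
#' @return fraction bound in `[0, 1]`, same length as `P`.
#' @export
isotherm <- function(P, kd, L) {
  stopifnot(kd > 0, all(P >= 0), L >= 0)
  if (L == 0) return(P / (P + kd))
  s <- P + L + kd
  disc <- pmax(s^2 - 4 * P * L, 0)
  # conjugate form 2P / (s + sqrt(disc)) avoids the cancellation of
  # (s - sqrt(disc)) when L << kd
  ifelse(s == 0, 0, 2 * P / (s + sqrt(disc)))
}

#' Construct a multiphasic binding model
#'
#' A baseline plus independent binding phases summed by amplitude; phases
#' are kept sorted by `kd`.
#'
#' @param baseline signal at zero titrant.
#' @param kd per-phase dissociation constants (molar).
#' @param amplitude per-phase signal amplitudes.
#' @param labeled_conc labeled-species concentration (molar).
#' @return an object of class `binding_model`.
#' @export
binding_model <- function(baseline, kd, amplitude, labeled_conc) {
  stopifnot(length(kd) == length(amplitude), all(kd > 0), labeled_conc > 0)
  o <- order(kd)
  structure(list(baseline = baseline,
                 phases = data.frame(kd = kd[o], amplitude = amplitude[o]),
                 labeled_conc = labeled_conc),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("binding_model:", nrow(x$phases), "phase(s), baseline",
      signif(x$baseline, 4), "\n")
  for (j in seq_len(nrow(x$phases)))
    cat(sprintf("  phase %d: Kd = %s M, amplitude = %s\n", j,
                signif(x$phases$kd[j], 4), signif(x$phases$amplitude[j], 4)))
  invisible(x)
}

#' Predict signal from a multiphasic binding model
#'
#' `signal(P) = baseline + sum_j amplitude_j * isotherm(P, kd_j, L)` —
#' binding events are assumed independent, so their contributions add.
#'
#' @param model a [binding_model()].
#' @param protein_concs titrant concentrations (molar).
#' @return numeric signal vector.
#' @export
predict_binding <- function(model, protein_concs) {
  sig <- rep(model$baseline, length(protein_concs))
  for (j in seq_len(nrow(model$phases)))
    sig <- sig + model$phases$amplitude[j] *
      isotherm(protein_concs, model$phases$kd[j], model$labeled_conc)
  sig
}

# ordered-kd parameterization: theta = (baseline, l1, u_2..u_n, a_1..a_n)
# with log kd_1 = l1 and log kd_j = log kd_{j-1} + exp(u_j) (strict order).
theta_to_model <- function(theta, n_phases, L) {
  baseline <- theta[1]
  logkd <- cumsum(c(theta[2],
                    if (n_phases > 1) exp(theta[3:(n_phases + 1)])))
  amps <- theta[(n_phases + 2):(2 * n_phases + 1)]
  binding_model(baseline, exp(logkd), amps, L)
}

model_to_theta <- function(kd, amplitude, baseline) {
  logkd <- log(sort(kd))
  c(baseline, logkd[1],
    if (length(kd) > 1) log(diff(logkd)),
    amplitude)
}

#' Fit a multiphasic binding model to a titration curve
#'
#' Least squares over (baseline, log kd's, amplitudes) with the kd ordering
#' enforced by parameterizing log-gaps, using Levenberg--Marquardt with
#' multiple starts drawn from a log-spaced kd grid spanning the titration
#' range. The labeled concentration is fixed (known experimentally).
#'
#' @param curve data frame with `conc` (molar) and `signal` (and optionally
#'   `replicate`); e.g. from [simulate_titration()].
#' @param n_phases number of binding phases to fit.
#' @param labeled_conc labeled-species concentration (molar); defaults to
#'   the curve's `labeled_conc` attribute.
#' @param n_starts number of multi-start initializations.
#' @return list of class `fit_result`: `model`, `rss`, `n_points`, `bic`,
#'   `converged`.
#' @export
fit_multiphase <- function(curve, n_phases, labeled_conc = NULL,
                           n_starts = 8L) {
  if (is.null(labeled_conc)) labeled_conc <- attr(curve, "labeled_conc")
  stopifnot(!is.null(labeled_conc), n_phases >= 1)
  P <- curve$conc
  y <- curve$signal
  k <- 2L * n_phases + 1L
  if (length(y) < 2L * k)
    stop("need at least ", 2L * k, " data points for ", n_phases,
         " phase(s)")
  resid_fn <- function(theta) {
    m <- theta_to_model(theta, n_phases, labeled_conc)
    predict_binding(m, P) - y
  }
  lo <- log(min(P[P > 0]) / 10)
  hi <- log(max(P) * 10)
  amp0 <- (max(y) - min(y)) / n_phases
  best <- NULL
  for (s in seq_len(n_starts)) {
    # starting kds evenly spread over the titration range in log space,
    # shifted lattice per start
    shift <- (s - 1) / n_starts - 0.5
    frac <- (seq_len(n_phases) - 0.5) / n_phases + shift / n_phases
    kd0 <- exp(lo + (hi - lo) * pmin(pmax(frac, 0.01), 0.99))
    kd0 <- sort(kd0) * (1 + 1e-6 * seq_len(n_phases))  # strict order
    th0 <- model_to_theta(kd0, rep(amp0, n_phases), min(y))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best)) stop("all fit starts failed")
  n_pts <- length(y)
  bic <- n_pts * log(best$rss / n_pts) + k * log(n_pts)
  structure(list(model = theta_to_model(best$par, n_phases, labeled_conc),
                 rss = best$rss, n_points = n_pts, bic = bic,
                 converged = best$info %in% 1:3),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: rss =", signif(x$rss, 4), " BIC =", signif(x$bic, 5),
      " converged =", x$converged, "\n")
  print(x$model)
  invisible(x)
}

#' Select the number of binding phases by BIC
#'
#' Fits models with 1 to `max_phases` phases and picks the fit minimizing
#' `BIC = n log(rss / n) + k log(n)` with `k = 2 n_phases + 1`.
#'
#' @param curve titration data frame (see [fit_multiphase()]).
#' @param max_phases maximum phase count to consider.
#' @param ... passed to [fit_multiphase()].
#' @return list with `best_n`, `best_fit`, and `fits` (one per phase
#'   count; `NULL` where the data could not support the model size).
#' @export
select_phase_count <- function(curve, max_phases, ...) {
  fits <- vector("list", max_phases)
  for (n in seq_len(max_phases))
    fits[[n]] <- tryCatch(fit_multiphase(curve, n, ...),
                          error = function(e) NULL)
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                 numeric(1))
  best_n <- which.min(bics)
  list(best_n = best_n, best_fit = fits[[best_n]], fits = fits,
       bic = bics)
}

#' Fit a Hill-type self-association curve
#'
#' Fits `S(C) = s0 + delta_s * C^h / (kd_app^h + C^h)`; the Hill
#' coefficient is fixed at 1 unless `fit_hill = TRUE`.
#'
#' @param curve data frame with `conc` and `signal`.
#' @param fit_hill estimate the Hill coefficient as a free parameter.
#' @param n_starts multi-start initializations on a log-kd grid.
#' @return a `fit_result` whose `model` is a list with `kd_app`, `hill`,
#'   `s0`, `delta_s`.
#' @export
fit_self_association <- function(curve, fit_hill = FALSE, n_starts = 8L) {
  C <- curve$conc
  y <- curve$signal
  stopifnot(length(y) >= 8)
  resid_fn <- function(th) {
    kd <- exp(th[1]); s0 <- th[2]; ds <- th[3]
    h <- if (fit_hill) 1 + exp(th[4]) else 1
    s0 + ds * C^h / (kd^h + C^h) - y
  }
  grid <- seq(log(min(C[C > 0]) / 10), log(max(C) * 10),
              length.out = n_starts)
  best <- NULL
  for (g in grid) {
    th0 <- c(g, min(y), max(y) - min(y), if (fit_hill) log(1e-6))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best)) stop("self-association fit failed")
  n_pts <- length(y)
  kpar <- 3L + as.integer(fit_hill)
  model <- list(kd_app = exp(best$par[1]), s0 = best$par[2],
                delta_s = best$par[3],
                hill = if (fit_hill) 1 + exp(best$par[4]) else 1)
  structure(list(model = model, rss = best$rss, n_points = n_pts,
                 bic = n_pts * log(best$rss / n_pts) + kpar * log(n_pts),
                 converged = best$info %in% 1:3),
            class = "fit_result")
}

unit_to_molar <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

parse_conc <- function(x, unit) {
  if (!unit %in% names(unit_to_molar))
    stop("unknown concentration unit: ", unit)
  x * unit_to_molar[[unit]]
}

#' Ratio of a concentration to a dissociation constant
#'
#' Converts both quantities to molar and returns their fold ratio; used to
#' relate an in-situ protein concentration to a measured Kd (e.g. how far
#' above the weakest binding event the protein sits in the native
#' secretion).
#'
#' @param conc,kd numeric values.
#' @param conc_unit,kd_unit units among `M`, `mM`, `uM`, `nM`, `pM`.
#' @return fold ratio (dimensionless).
#' @export
concentration_ratio <- function(conc, kd, conc_unit = "uM",
                                kd_unit = "uM") {
  parse_conc(conc, conc_unit) / parse_conc(kd, kd_unit)
}

# average (monoisotopic-free) residue masses, Da; protein MW = sum + water
aa_residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param seq amino-acid sequence (one-letter codes).
#' @return mass in Dalton.
#' @export
protein_mass <- function(seq) {
  aa <- strsplit(toupper(gsub("[^A-Za-z]", "", seq)), "")[[1]]
  unknown <- setdiff(aa, names(aa_residue_mass))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  sum(aa_residue_mass[aa]) + 18.0153
}

#' Convert a mass concentration to molarity
#'
#' @param mg_per_ml mass concentration in mg/mL.
#' @param monomer_mass_da monomer mass in Dalton (e.g. from
#'   [protein_mass()]).
#' @return molar concentration (mol/L).
#' @export
mass_to_molar <- function(mg_per_ml, monomer_mass_da) {
  stopifnot(mg_per_ml >= 0, monomer_mass_da > 0)
  mg_per_ml / monomer_mass_da  # (g/L) / (g/mol) = mol/L
}
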