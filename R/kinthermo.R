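# SPR-side analysis: K_D from rate constants, Langmuir 1:1 global
# sensorgram fitting, van't Hoff and Eyring temperature regressions,
# delta-delta energetics and enthalpy-entropy compensation.
#
# Sign conventions (binding direction, 1 M standard state):
#   ln K_D = dH/(R T) - dS/R       so   dG = R T ln K_D = dH - T dS < 0
#   for tight binders; activation parameters follow
#   k_on = (kB T / h) exp(-(dHa - T dSa)/(R T)).

#' K_D from the rate constants
#'
#' @param k_on association rate constant, 1/(M s).
#' @param k_off dissociation rate constant, 1/s.
#' @return K_D = k_off / k_on in M. Vectorized.
#' @export
kd_from_rates <- function(k_on, k_off) {
  if (any(k_on <= 0) || any(k_off <= 0)) stop("rate constants must be positive")
  k_off / k_on
}

#' Standard binding free energy from K_D
#'
#' @param kd dissociation constant, M (1 M standard state).
#' @param T absolute temperature, K (default 298.15).
#' @return dG = R T ln(K_D), kcal/mol (negative for K_D < 1 M).
#' @export
gibbs_from_kd <- function(kd, T = ab_constants$T_ref) {
  if (any(kd <= 0) || any(T <= 0)) stop("kd and T must be positive")
  ab_constants$R_kcal * T * log(kd)
}

#' Read a kinetic record table
#'
#' Delimited text with columns `variant, T_K, kon, koff` and optional
#' `KD` (M) and `NaCl_mM`.
#'
#' @param path file path.
#' @return data frame of kinetic records.
#' @export
read_kinetic_table <- function(path) {
  kt <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant", "T_K", "kon", "koff")
  if (!all(need %in% names(kt)))
    stop("kinetic table must have columns: ", paste(need, collapse = ", "))
  if (any(kt$kon <= 0 | kt$koff <= 0 | kt$T_K <= 0))
    stop("rates and temperatures must be positive")
  kt
}

#' Flag K_D values inconsistent with their rate constants
#'
#' @param kon,koff rate constants.
#' @param kd reported K_D values (M); NA entries are never flagged.
#' @param tol relative tolerance on |K_D k_on - k_off| / k_off
#'   (default 0.1).
#' @return logical vector, TRUE where the reported K_D disagrees with
#'   k_off/k_on beyond the tolerance.
#' @export
flag_kd_inconsistency <- function(kon, koff, kd, tol = 0.1) {
  ifelse(is.na(kd), FALSE, abs(kd * kon - koff) / koff > tol)
}

#' van't Hoff analysis of a temperature series
#'
#' OLS of ln K_D on 1/T: slope = dH/R, intercept = -dS/R (binding
#' convention; see module header).
#'
#' @param T temperatures, K (>= 3 distinct values).
#' @param kd dissociation constants, M.
#' @return list of class `thermo_params`: `dH`, `dS` (kcal/mol,
#'   kcal/mol/K), `mTdS` and `dG` at `T_ref`, fit diagnostics
#'   (`se_dH`, `se_dS`, `r2`, `n`).
#' @export
vant_hoff_fit <- function(T, kd) {
  if (length(T) < 3 || length(unique(T)) < 3)
    stop("need >= 3 distinct temperatures")
  if (any(kd <= 0)) stop("K_D must be positive")
  fit <- stats::lm(log(kd) ~ I(1 / T))
  sm <- suppressWarnings(summary(fit))
  R <- ab_constants$R_kcal
  dH <- unname(stats::coef(fit)[2]) * R
  dS <- -unname(stats::coef(fit)[1]) * R
  Tr <- ab_constants$T_ref
  structure(list(dH = dH, dS = dS, mTdS = -Tr * dS, dG = dH - Tr * dS,
                 T_ref = Tr,
                 se_dH = sm$coefficients[2, 2] * R,
                 se_dS = sm$coefficients[1, 2] * R,
                 r2 = sm$r.squared, n = length(T)),
            class = "thermo_params")
}

#' Eyring analysis of association rate constants
#'
#' OLS of ln(k_on h / (kB T)) on 1/T: slope = -dHa/R, intercept = dSa/R.
#'
#' @param T temperatures, K (>= 3 distinct values).
#' @param kon association rate constants, 1/(M s).
#' @return list of class `activation_params`: `dH`, `dS`, `mTdS`, `dG`
#'   at `T_ref` (the activation quantities), plus diagnostics.
#' @export
eyring_fit <- function(T, kon) {
  if (length(T) < 3 || length(unique(T)) < 3)
    stop("need >= 3 distinct temperatures")
  if (any(kon <= 0)) stop("k_on must be positive")
  y <- log(kon * ab_constants$h / (ab_constants$kB * T))
  fit <- stats::lm(y ~ I(1 / T))
  sm <- suppressWarnings(summary(fit))
  R <- ab_constants$R_kcal
  dH <- -unname(stats::coef(fit)[2]) * R
  dS <- unname(stats::coef(fit)[1]) * R
  Tr <- ab_constants$T_ref
  structure(list(dH = dH, dS = dS, mTdS = -Tr * dS, dG = dH - Tr * dS,
                 T_ref = Tr,
                 se_dH = sm$coefficients[2, 2] * R,
                 se_dS = sm$coefficients[1, 2] * R,
                 r2 = sm$r.squared, n = length(T)),
            class = "activation_params")
}

#' Delta-delta energetics table relative to a reference variant
#'
#' Accepts either a named list of `thermo_params`/`activation_params`
#' fits, or a data frame with columns `variant`, `dH` and one of `mTdS`
#' (kcal/mol at temperature `T`) or `dS` (kcal/mol/K) -- the layout of a
#' published thermodynamics table. Differences are mutein minus
#' reference; the identity dG = dH + (-T dS) holds exactly by
#' construction.
#'
#' @param params fits or component data frame (see above).
#' @param reference reference variant name (default "WT").
#' @param T temperature for the -T dS and dG columns, K.
#' @param kd optional named vector of K_D values (M or any common unit);
#'   adds `fold` = K_D(ref)/K_D(variant) and `improved` = fold > 1.
#' @return data frame: variant, dH, mTdS, dG, ddH, mTddS, ddG
#'   (+ fold, improved).
#' @export
delta_table <- function(params, reference = "WT", T = ab_constants$T_ref,
                        kd = NULL) {
  if (is.data.frame(params)) {
    df <- params
    if (!"mTdS" %in% names(df)) {
      if (!"dS" %in% names(df)) stop("need column mTdS or dS")
      df$mTdS <- -T * df$dS
    }
    df <- df[, c("variant", "dH", "mTdS")]
  } else {
    df <- do.call(rbind, lapply(names(params), function(v) {
      p <- params[[v]]
      data.frame(variant = v, dH = p$dH, mTdS = -T * p$dS)
    }))
  }
  if (!reference %in% df$variant) stop("reference variant '", reference,
                                       "' not present")
  df$dG <- df$dH + df$mTdS
  ref <- df[df$variant == reference, ]
  df$ddH <- df$dH - ref$dH
  df$mTddS <- df$mTdS - ref$mTdS
  df$ddG <- df$ddH + df$mTddS
  if (!is.null(kd)) {
    if (!reference %in% names(kd)) stop("reference K_D missing")
    df$fold <- unname(kd[reference] / kd[df$variant])
    df$improved <- df$fold > 1
  }
  rownames(df) <- NULL
  df
}

#' Enthalpy-entropy compensation summary
#'
#' OLS of -T ddS on ddH over the non-reference variants, plus the
#' per-variant conversion efficiency ddG/ddH (the fraction of the
#' enthalpy advantage surviving compensation).
#'
#' @param deltas a [delta_table()] result.
#' @param reference reference variant name.
#' @return list: slope, intercept, r2, efficiencies (data frame).
#' @export
compensation_summary <- function(deltas, reference = "WT") {
  d <- deltas[deltas$variant != reference, , drop = FALSE]
  if (nrow(d) < 2) stop("need >= 2 non-reference variants")
  if (length(unique(d$ddH)) < 2) stop("degenerate (all-equal) ddH inputs")
  fit <- stats::lm(mTddS ~ ddH, data = d)
  eff <- ifelse(d$ddH == 0, NA_real_, d$ddG / d$ddH)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       efficiencies = data.frame(variant = d$variant, efficiency = eff))
}

# Langmuir 1:1 response model for one concentration
langmuir_response <- function(t, conc, kon, koff, rmax, t_assoc_end) {
  kobs <- kon * conc + koff
  req <- rmax * conc / (conc + koff / kon)
  r_end <- req * (1 - exp(-kobs * t_assoc_end))
  ifelse(t <= t_assoc_end,
         req * (1 - exp(-kobs * t)),
         r_end * exp(-koff * (t - t_assoc_end)))
}

#' Global Langmuir 1:1 fit of a sensorgram set
#'
#' Association R(t) = R_eq (1 - e^{-(kon C + koff) t}) with
#' R_eq = R_max C/(C + koff/kon); dissociation decays exponentially from
#' the association end point. k_on, k_off and R_max are shared across all
#' concentrations and fitted jointly by Levenberg-Marquardt least squares
#' (on log-scale rates, so positivity is structural).
#'
#' @param data data frame with columns `t` (s), `RU`, `conc` (M) and
#'   `t_assoc_end` (s, per concentration; constant within a trace).
#' @param start optional named list (kon, koff, rmax) of starting values.
#' @return list of class `sensorgram_fit`: kon, koff, rmax, kd, standard
#'   errors, residual sd and the fit object.
#' @export
fit_sensorgram <- function(data, start = NULL) {
  need <- c("t", "RU", "conc", "t_assoc_end")
  if (!all(need %in% names(data)))
    stop("sensorgram data must have columns: ", paste(need, collapse = ", "))
  if (length(unique(data$conc)) < 2)
    stop("need sensorgrams at >= 2 analyte concentrations")
  if (all(data$RU == 0)) stop("all-zero response; nothing to fit")
  if (is.null(start)) {
    start <- list(kon = 1e5, koff = 1e-3, rmax = max(data$RU) * 1.2)
    if (start$rmax <= 0) start$rmax <- 1
  }
  par0 <- c(lkon = log(start$kon), lkoff = log(start$koff), rmax = start$rmax)
  resid_fn <- function(p) {
    pred <- langmuir_response(data$t, data$conc, exp(p[["lkon"]]),
                              exp(p[["lkoff"]]), p[["rmax"]],
                              data$t_assoc_end)
    data$RU - pred
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9))
    stop("sensorgram fit did not converge: ", fit$message,
         " (last iterate kon=", exp(fit$par[["lkon"]]), ")")
  p <- fit$par
  cv <- tryCatch(diag(solve(fit$hessian)) * fit$deviance /
                   (length(fit$fvec) - 3), error = function(e) rep(NA_real_, 3))
  se_log <- suppressWarnings(sqrt(abs(cv)))
  structure(list(kon = exp(p[["lkon"]]), koff = exp(p[["lkoff"]]),
                 rmax = p[["rmax"]],
                 kd = exp(p[["lkoff"]] - p[["lkon"]]),
                 se_kon = exp(p[["lkon"]]) * se_log[1],
                 se_koff = exp(p[["lkoff"]]) * se_log[2],
                 se_rmax = se_log[3],
                 sigma = sqrt(fit$deviance / (length(fit$fvec) - 3)),
                 fit = fit),
            class = "sensorgram_fit")
}
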