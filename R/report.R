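# End-to-end characterization of a mutein panel from kinetic records and
# thermodynamic component tables, in the layout of the published 11K2
# scFv / MCP-1 study tables: K_D with fold-changes and improved flags,
# equilibrium and activation delta-delta tables, compensation summary.

#' Characterize a mutein panel
#'
#' From a kinetic record table at a single temperature: recomputes
#' K_D = k_off/k_on for every variant, flags rows whose reported K_D is
#' inconsistent with the rates, computes fold-improvement
#' K_D(ref)/K_D(variant) (from the reported K_D when available, else the
#' recomputed one) and the improved flag. Optional equilibrium and
#' activation component tables (variant, dH, mTdS) yield delta-delta
#' tables and an enthalpy-entropy compensation summary.
#'
#' @param kinetics data frame with columns `variant, kon, koff` and
#'   optional `KD` (M).
#' @param thermo optional equilibrium components (variant, dH, mTdS).
#' @param activation optional activation components (variant, dH, mTdS).
#' @param reference reference variant (default "WT").
#' @param T temperature for derived quantities, K.
#' @param kd_tol relative tolerance for the K_D consistency flag.
#' @return list of class `characterization`: `kinetics` (augmented
#'   table), `thermo_deltas`, `activation_deltas`, `compensation`.
#' @export
run_characterize <- function(kinetics, thermo = NULL, activation = NULL,
                             reference = "WT", T = ab_constants$T_ref,
                             kd_tol = 0.1) {
  if (nrow(kinetics) == 0) stop("empty kinetic table")
  need <- c("variant", "kon", "koff")
  if (!all(need %in% names(kinetics)))
    stop("kinetics must have columns: ", paste(need, collapse = ", "))
  if (!reference %in% kinetics$variant)
    stop("reference variant '", reference, "' not in kinetic table")
  kt <- kinetics
  kt$KD_rates <- kd_from_rates(kt$kon, kt$koff)
  if (is.null(kt$KD)) kt$KD <- NA_real_
  kt$kd_inconsistent <- flag_kd_inconsistency(kt$kon, kt$koff, kt$KD, kd_tol)
  kt$KD_used <- ifelse(is.na(kt$KD), kt$KD_rates, kt$KD)
  ref_kd <- kt$KD_used[kt$variant == reference][1]
  kt$fold <- ref_kd / kt$KD_used
  kt$improved <- kt$variant != reference & kt$fold > 1
  kt$dG <- gibbs_from_kd(kt$KD_used, T)

  kd_named <- stats::setNames(kt$KD_used, kt$variant)
  thermo_deltas <- if (!is.null(thermo))
    delta_table(thermo, reference, T,
                kd = kd_named[intersect(thermo$variant, names(kd_named))])
  activation_deltas <- if (!is.null(activation))
    delta_table(activation, reference, T)
  compensation <- if (!is.null(thermo_deltas) &&
                      sum(thermo_deltas$variant != reference) >= 2)
    compensation_summary(thermo_deltas, reference)
  structure(list(kinetics = kt, thermo_deltas = thermo_deltas,
                 activation_deltas = activation_deltas,
                 compensation = compensation, reference = reference, T = T),
            class = "characterization")
}

#' @export
print.characterization <- function(x, ...) {
  kt <- x$kinetics
  cat(sprintf("<characterization> %d variants (reference %s): %d improved, %d K_D-inconsistent\n",
              nrow(kt), x$reference, sum(kt$improved), sum(kt$kd_inconsistent)))
  # display rounding follows the field's table conventions:
  # 2 significant figures for K_D in nM, one decimal for kcal/mol
  show <- data.frame(variant = kt$variant,
                     KD_nM = signif(kt$KD_used * 1e9, 2),
                     fold = signif(kt$fold, 2),
                     improved = ifelse(kt$variant == x$reference, "-",
                                       ifelse(kt$improved, "YES", "NO")),
                     dG_kcal = round(kt$dG, 1),
                     flag = ifelse(kt$kd_inconsistent, "KD!=koff/kon", ""))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write characterization outputs
#'
#' Emits `kinetics.tsv`, `thermo_deltas.tsv`, `activation_deltas.tsv`
#' and `compensation.tsv` (where available) under `out_dir`, full
#' precision.
#'
#' @param ch a `characterization`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_characterization <- function(ch, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(ch$kinetics, "kinetics.tsv")
  if (!is.null(ch$thermo_deltas)) wt(ch$thermo_deltas, "thermo_deltas.tsv")
  if (!is.null(ch$activation_deltas))
    wt(ch$activation_deltas, "activation_deltas.tsv")
  if (!is.null(ch$compensation)) {
    wt(data.frame(slope = ch$compensation$slope,
                  intercept = ch$compensation$intercept,
                  r2 = ch$compensation$r2), "compensation.tsv")
    wt(ch$compensation$efficiencies, "efficiencies.tsv")
  }
  invisible(out_dir)
}

#' Bundled published measurements of the 11K2 scFv / MCP-1 panel
#'
#' Convenience loaders for the bundled literature tables: the 25 C
#' kinetic parameters of wild-type 11K2 scFv and twelve single-muteins
#' binding the chemokine MCP-1, and the van't Hoff / Eyring component
#' tables (dH and -T dS at 25 C) for the five improved muteins.
#'
#' @param which one of "kinetics", "thermo", "activation".
#' @return data frame.
#' @export
load_published_tables <- function(which = c("kinetics", "thermo", "activation")) {
  which <- match.arg(which)
  f <- switch(which,
              kinetics = "kinetics_11k2_25C.tsv",
              thermo = "thermo_equilibrium_11k2.tsv",
              activation = "activation_association_11k2.tsv")
  utils::read.table(system.file("extdata", f, package = "abmature"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
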