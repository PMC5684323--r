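# Closed-form assay computations: efficiency-based qPCR abundance with
# reference-gene and vehicle-control normalization, 2^-ddCt fold enrichment,
# and SPR percent-binding normalization.

#' mRNA abundance from a qPCR Ct value
#'
#' Converts cycle-threshold values to relative abundance using the actual
#' per-target PCR efficiency: `abundance = E^(-Ct)`. Strictly decreasing in
#' Ct.
#'
#' @param ct Ct values (cycles, > 0).
#' @param efficiency Per-cycle amplification factor `E` in `(1, 2]`
#'   (default 2, perfect doubling).
#' @return Relative abundance values.
#' @export
ct_abundance <- function(ct, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2))
    stop("efficiency must lie in (1, 2]")
  efficiency^(-ct)
}

#' Fold change of a target mRNA versus vehicle control
#'
#' Per sample, target abundance (`E^(-Ct)`) is normalized to the reference
#' gene, then to the mean of the vehicle-control samples, yielding fold change
#' versus control.
#'
#' @param tab `data.frame` with columns `sample_id`, `target`, `ct`, `group`.
#' @param target Target transcript to quantify.
#' @param reference Reference gene (default `"GAPDH"`).
#' @param control Control group label (default `"DMSO"`).
#' @param efficiency Named vector of per-target efficiencies; unnamed scalar
#'   applies to all targets (default 2).
#' @return `data.frame`: `sample_id`, `group`, `rel_abundance`, `fold_change`.
#' @export
qpcr_fold_change <- function(tab, target, reference = "GAPDH",
                             control = "DMSO", efficiency = 2) {
  eff_of <- function(tgt) {
    if (is.null(names(efficiency))) efficiency[1L]
    else if (tgt %in% names(efficiency)) efficiency[[tgt]]
    else 2
  }
  tt <- tab[tab$target == target, ]
  rr <- tab[tab$target == reference, ]
  if (!nrow(tt) || !nrow(rr))
    stop("target or reference rows missing from the Ct table")
  m <- merge(tt[, c("sample_id", "group", "ct")],
             rr[, c("sample_id", "ct")],
             by = "sample_id", suffixes = c("_t", "_r"))
  rel <- ct_abundance(m$ct_t, eff_of(target)) /
    ct_abundance(m$ct_r, eff_of(reference))
  ctrl <- mean(rel[m$group == control])
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("no usable control-group samples for group '", control, "'")
  data.frame(sample_id = m$sample_id, group = m$group,
             rel_abundance = rel, fold_change = rel / ctrl,
             stringsAsFactors = FALSE)
}

#' Fold enrichment by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_a - Ct_ref_a) - (Ct_target_b - Ct_ref_b)` and
#' `fold = 2^(-ddCt)`; condition *a* is the numerator (e.g. active ligand)
#' and *b* the comparator.
#'
#' @param ct_target_a,ct_ref_a Target and reference Ct in condition a.
#' @param ct_target_b,ct_ref_b Target and reference Ct in condition b.
#' @return Fold enrichment of condition a over b.
#' @export
ddct_fold <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  ddct <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-ddct)
}

#' SPR percent binding at full-occupancy normalization
#'
#' The theoretical maximal response for 1:1 stoichiometry is
#' `Rmax = immobilized * (analyte_mw / ligand_mw) * stoichiometry`; the signal
#' is expressed as `100 * signal / Rmax`, so 100% corresponds to full
#' occupancy of one binding site.
#'
#' @param signal Measured response (RU).
#' @param analyte_mw Analyte molecular mass (Da).
#' @param ligand_mw Immobilized ligand (RNA) molecular mass (Da).
#' @param immobilized Immobilized ligand surface density (RU).
#' @param stoichiometry Binding sites per ligand (default 1).
#' @return Percent binding.
#' @export
spr_percent_binding <- function(signal, analyte_mw, ligand_mw, immobilized,
                                stoichiometry = 1) {
  rmax <- immobilized * (analyte_mw / ligand_mw) * stoichiometry
  if (any(rmax <= 0)) stop("Rmax must be positive")
  100 * signal / rmax
}
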