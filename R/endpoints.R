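#' Macrophage infiltration ratio
#'
#' Per-animal ratio of liver-area-normalized macrophage density at the
#' endpoint timepoint (15 dpf) to the baseline timepoint (9 or 12 dpf,
#' depending on the experiment). Densities are assumed already normalized
#' to liver area upstream, which makes the ratio invariant to any common
#' rescaling of both densities.
#'
#' @param density_15dpf Endpoint area-normalized density (>= 0, vectorized).
#' @param density_baseline Baseline area-normalized density (> 0).
#' @return Dimensionless ratio(s).
#' @export
#' @examples
#' infiltration_ratio(5, 2)  # 2.5
infiltration_ratio <- function(density_15dpf, density_baseline) {
  if (any(!is.finite(density_baseline)) || any(density_baseline <= 0)) {
    .stopf("infiltration_ratio: baseline density must be > 0 (fish with zero baseline are excluded upstream)")
  }
  if (any(density_15dpf < 0)) {
    .stopf("infiltration_ratio: endpoint density must be >= 0")
  }
  density_15dpf / density_baseline
}

#' Efficiency-corrected delta-delta-Ct fold change
#'
#' Relative expression by the efficiency-corrected comparative-Ct method:
#' `dCt = Ct_target - Ct_reference` within each group, `ddCt = dCt_treated
#' - dCt_control`, fold change `= efficiency^(-ddCt)`. With a calibrated
#' per-cycle amplification factor of 1.94 (about 94% efficiency) the fold
#' change is `1.94^(-ddCt)`; at a perfect factor of 2 this reduces to the
#' classic `2^(-ddCt)`.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference gene
#'   in the treated group (cycles).
#' @param ct_target_control,ct_ref_control Same for the control group.
#' @param efficiency Per-cycle amplification factor in `(1, 2]`
#'   (default 1.94).
#' @return Fold change (dimensionless, vectorized).
#' @export
#' @examples
#' ddct_fold_change(24, 18, 23, 18)                   # 1.94^-1
#' ddct_fold_change(24, 18, 23, 18, efficiency = 2)   # 0.5
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control,
                             efficiency = 1.94) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) .stopf("ddct_fold_change: non-finite Ct value")
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    .stopf("ddct_fold_change: efficiency must be in (1, 2]")
  }
  dct_treated <- ct_target_treated - ct_ref_treated
  dct_control <- ct_target_control - ct_ref_control
  efficiency^(-(dct_treated - dct_control))
}

#' Per-cycle amplification factor to percent efficiency
#'
#' Converts a per-cycle amplification factor (1 < factor <= 2) to percent
#' amplification efficiency: `(factor - 1) * 100`. A factor of 1.94 is 94%
#' efficiency; 2 is the theoretical 100%.
#'
#' @param per_cycle_factor Amplification factor in `(1, 2]`.
#' @return Efficiency in percent.
#' @export
#' @examples
#' percent_efficiency(1.94)  # 94
percent_efficiency <- function(per_cycle_factor) {
  if (any(per_cycle_factor <= 1) || any(per_cycle_factor > 2)) {
    .stopf("percent_efficiency: per-cycle factor must be in (1, 2]")
  }
  (per_cycle_factor - 1) * 100
}

#' Convert a fish cohort table to dose-response records
#'
#' Computes one infiltration ratio per fish and emits the long-schema
#' record table consumed by the surface-fitting stage (`endpoint =
#' "macrophage_ratio"`, biological replicate = batch, one technical
#' replicate per fish). Fish with zero baseline density are excluded — the
#' ratio is undefined — and the exclusion count is reported via a message
#' and the `"n_excluded"` attribute. Cohorts mixing baseline timepoints
#' (9 and 12 dpf) are refused unless `allow_mixed_baseline = TRUE`, in
#' which case the baseline label is carried along.
#'
#' @param cohort Data frame with agent dose columns plus `fish_id`,
#'   `context`, `batch`, `baseline_dpf`, `density_baseline`,
#'   `density_15dpf`.
#' @param panel An [agent_panel()].
#' @param allow_mixed_baseline Permit mixed 9/12 dpf baselines.
#' @return Long-schema data frame of `macrophage_ratio` records with
#'   attribute `n_excluded`.
#' @export
ratio_table_to_responses <- function(cohort, panel,
                                     allow_mixed_baseline = FALSE) {
  if (nrow(cohort) == 0L) {
    out <- data.frame()
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  req <- c(panel_names(panel), "fish_id", "context", "batch",
           "baseline_dpf", "density_baseline", "density_15dpf")
  missing <- setdiff(req, names(cohort))
  if (length(missing)) {
    .stopf("cohort table missing column(s): %s",
           paste(missing, collapse = ", "))
  }
  if (!all(cohort$baseline_dpf %in% c(9L, 12L))) {
    .stopf("baseline_dpf must be 9 or 12")
  }
  if (length(unique(cohort$baseline_dpf)) > 1L && !allow_mixed_baseline) {
    .stopf(paste0("cohort mixes baseline timepoints (9 and 12 dpf); one ",
                  "fitted model uses a single baseline. Set ",
                  "allow_mixed_baseline = TRUE to keep both, labeled."))
  }
  keep <- cohort$density_baseline > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf(
      "ratio_table_to_responses: excluded %d fish with zero baseline density",
      n_excluded))
  }
  cohort <- cohort[keep, , drop = FALSE]
  out <- cohort[panel_names(panel)]
  out$endpoint <- "macrophage_ratio"
  out$value <- infiltration_ratio(cohort$density_15dpf,
                                  cohort$density_baseline)
  out$context <- cohort$context
  out$subject <- as.character(cohort$fish_id)
  out$bio_rep <- as.integer(cohort$batch)
  out$tech_rep <- 1L
  out$timepoint_dpf <- 15L
  if (allow_mixed_baseline) out$baseline_dpf <- cohort$baseline_dpf
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
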