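#' Extrapolate a PBPK model to another species
#'
#' Compound-specific parameters (physicochemistry, Km, vmax per
#' intracellular volume, clearances in ml/h/kg) are retained; the
#' physiology is replaced and the partition coefficients are recomputed
#' against the target organ compositions. Absolute clearances rescale
#' implicitly through the target body weight, and absolute process
#' velocities through the target organ volumes.
#'
#' @param model a [pbpk_model()].
#' @param target_physiology the target `physiology` object.
#' @return a `pbpk_model` on the target physiology.
#' @export
extrapolate_species <- function(model, target_physiology) {
  validate_physiology(target_physiology)
  for (p in model$active_processes)
    if (!p$organ %in% target_physiology$organ)
      stop_config("organ '%s' (process %s) missing from target physiology",
                  p$organ, p$enzyme_or_transporter)
  pbpk_model(compounds = model$compounds,
             physiology = target_physiology,
             partition_method = model$partition_method,
             active_processes = model$active_processes,
             clearances = model$clearances,
             endothelial_permeability_overrides =
               model$endothelial_permeability_overrides)
}

#' Oral bioavailability from paired simulations
#'
#' F is the dose-normalized ratio of the oral to the intravenous venous
#' plasma AUC over the given window (default 0-24 h).
#'
#' @param model a [pbpk_model()].
#' @param oral_regimen,iv_regimen [dosing_regimen()] objects.
#' @param window integration window `[t0, t1]` in h.
#' @param ... passed to [simulate_pk()].
#' @return bioavailability fraction.
#' @export
compute_bioavailability <- function(model, oral_regimen, iv_regimen,
                                    window = c(0, 24), ...) {
  assert_that(oral_regimen$route == "oral", "oral_regimen must be oral")
  assert_that(iv_regimen$route %in% c("iv_bolus", "iv_infusion"),
              "iv_regimen must be intravenous")
  t_end <- window[2]
  sim_po <- simulate_pk(model, oral_regimen, t_end = t_end, ...)
  sim_iv <- simulate_pk(model, iv_regimen, t_end = t_end, ...)
  auc_po <- compute_auc(get_profile(sim_po), window)
  auc_iv <- compute_auc(get_profile(sim_iv), window)
  if (auc_iv <= 0)
    stop_config("IV AUC is zero; bioavailability undefined")
  (auc_po / sum(oral_regimen$dose)) / (auc_iv / sum(iv_regimen$dose))
}
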