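#' Active metabolic and transport processes
#'
#' An active process is a saturable (Michaelis-Menten) reaction located in
#' one organ's intracellular space: either a metabolic conversion producing
#' a declared metabolite, or an influx/efflux transport across the cell
#' membrane. `vmax` is referenced to the organ's intracellular volume and
#' scaled by a per-organ relative expression factor.
#'
#' @param kind `"metabolism"` or `"transport"`.
#' @param organ organ label the process lives in.
#' @param enzyme_or_transporter label, e.g. `"CYP3A4"`.
#' @param Km Michaelis constant, µmol/L, > 0.
#' @param vmax maximal velocity, µmol/L/h referenced to intracellular
#'   volume, >= 0.
#' @param compound_id substrate compound id.
#' @param product_id metabolite compound id (metabolism only).
#' @param direction `"influx"` or `"efflux"` (transport only).
#' @param relative_expression per-organ scaling factor >= 0.
#' @return an object of class `active_process`.
#' @export
active_process <- function(kind = c("metabolism", "transport"), organ,
                           enzyme_or_transporter, Km, vmax, compound_id,
                           product_id = NULL, direction = NULL,
                           relative_expression = 1) {
  kind <- match.arg(kind)
  assert_that(is_scalar_number(Km) && Km > 0, "Km must be > 0")
  assert_that(is_scalar_number(vmax) && vmax >= 0, "vmax must be >= 0")
  assert_that(relative_expression >= 0, "relative_expression must be >= 0")
  if (kind == "metabolism")
    assert_that(!is.null(product_id), "metabolism requires a product_id")
  if (kind == "transport") {
    assert_that(!is.null(direction) && direction %in% c("influx", "efflux"),
                "transport requires direction 'influx' or 'efflux'")
    product_id <- NULL
  }
  structure(list(kind = kind, organ = organ,
                 enzyme_or_transporter = enzyme_or_transporter,
                 Km = Km, vmax = vmax, compound_id = compound_id,
                 product_id = product_id, direction = direction,
                 relative_expression = relative_expression),
            class = "active_process")
}

#' Clearance specification for one compound
#'
#' Linear plasma clearances: renal (either an absolute ml/h/kg value or a
#' unitless multiplier of the glomerular filtration rate applied to the
#' unbound plasma concentration), biliary and hepatic, all referenced to
#' body weight. Renal clearance samples the kidney plasma concentration and
#' routes to urine; biliary samples the liver plasma concentration and
#' routes to bile; hepatic plasma clearance is an unspecific first-pass
#' elimination at the liver tracked as cleared mass.
#'
#' @param renal_plasma_clearance ml/h/kg (absolute mode) or GFR multiplier
#'   (GFR-fraction mode), >= 0.
#' @param renal_mode `"absolute"` or `"gfr_fraction"`.
#' @param biliary_clearance ml/h/kg, >= 0.
#' @param hepatic_plasma_clearance ml/h/kg, >= 0.
#' @return an object of class `clearance_spec`.
#' @export
clearance_spec <- function(renal_plasma_clearance = 0,
                           renal_mode = c("absolute", "gfr_fraction"),
                           biliary_clearance = 0,
                           hepatic_plasma_clearance = 0) {
  renal_mode <- match.arg(renal_mode)
  assert_that(renal_plasma_clearance >= 0 && biliary_clearance >= 0 &&
                hepatic_plasma_clearance >= 0,
              "clearances must be >= 0")
  structure(list(renal_plasma_clearance = renal_plasma_clearance,
                 renal_mode = renal_mode,
                 biliary_clearance = biliary_clearance,
                 hepatic_plasma_clearance = hepatic_plasma_clearance),
            class = "clearance_spec")
}

#' Dosing regimen
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"oral"`.
#' @param dose dose in mg, > 0 (per administration).
#' @param dose_times administration times in h, strictly increasing, >= 0.
#' @param infusion_duration infusion length in h (iv_infusion only).
#' @param intestinal_permeability intestinal permeability in cm/s (oral
#'   only); converted to a first-order absorption rate via the effective
#'   gut surface area.
#' @return an object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(route = c("iv_bolus", "iv_infusion", "oral"),
                           dose, dose_times = 0, infusion_duration = NULL,
                           intestinal_permeability = NULL) {
  route <- match.arg(route)
  assert_that(all(dose > 0), "dose must be > 0")
  assert_that(all(dose_times >= 0) && !is.unsorted(dose_times, strictly = TRUE),
              "dose_times must be >= 0 and strictly increasing")
  if (route == "iv_infusion")
    assert_that(!is.null(infusion_duration) && infusion_duration > 0,
                "iv_infusion requires infusion_duration > 0")
  if (route == "oral")
    assert_that(!is.null(intestinal_permeability) &&
                  intestinal_permeability >= 0,
                "oral route requires intestinal_permeability >= 0")
  structure(list(route = route, dose = dose, dose_times = dose_times,
                 infusion_duration = infusion_duration,
                 intestinal_permeability = intestinal_permeability),
            class = "dosing_regimen")
}

#' Whole-body PBPK model
#'
#' Assembles compounds, physiology, partition coefficients, active
#' processes and clearances into a simulatable model. Partition
#' coefficients are computed from the registered method unless supplied
#' explicitly. All internal units are h, µmol, µmol/L; doses in mg are
#' converted at intake via the molecular weight.
#'
#' @param compounds list of [compound_properties()] (parent first,
#'   metabolites after).
#' @param physiology a `physiology` object.
#' @param partition_coefficients optional named list (per compound id) of
#'   named Kp vectors (per organ); computed via `partition_method` when
#'   absent.
#' @param partition_method label passed to
#'   [compute_partition_coefficients()].
#' @param active_processes list of [active_process()] objects.
#' @param clearances named list (per compound id) of [clearance_spec()]
#'   objects.
#' @param endothelial_permeability_overrides optional named list (per
#'   compound id) of named vectors organ -> permeability cm/s, restricting
#'   plasma/interstitial exchange in those organs (by default exchange is
#'   unlimited).
#' @return an object of class `pbpk_model`.
#' @export
pbpk_model <- function(compounds, physiology,
                       partition_coefficients = NULL,
                       partition_method = "composition",
                       active_processes = list(),
                       clearances = list(),
                       endothelial_permeability_overrides = list()) {
  if (inherits(compounds, "compound_properties")) compounds <- list(compounds)
  ids <- vapply(compounds, `[[`, "", "id")
  assert_that(!anyDuplicated(ids), "duplicate compound ids")
  names(compounds) <- ids
  for (p in active_processes) {
    assert_that(p$compound_id %in% ids,
                "process substrate '%s' is not a declared compound",
                p$compound_id)
    assert_that(p$organ %in% physiology$organ,
                "process organ '%s' absent from physiology", p$organ)
    if (p$kind == "metabolism")
      assert_that(p$product_id %in% ids,
                  "metabolite '%s' is not a declared compound", p$product_id)
  }
  for (cid in names(clearances))
    assert_that(cid %in% ids, "clearance for undeclared compound '%s'", cid)
  if (is.null(partition_coefficients)) {
    partition_coefficients <- lapply(compounds, function(cp)
      compute_partition_coefficients(cp, physiology, partition_method))
  }
  for (cid in names(partition_coefficients)) {
    kp <- partition_coefficients[[cid]]
    assert_that(all(kp > 0), "Kp must be > 0 for compound '%s'", cid)
    assert_that(all(physiology$organ %in% names(kp)),
                "Kp for '%s' misses organs", cid)
  }
  structure(list(compounds = compounds, physiology = physiology,
                 partition_coefficients = partition_coefficients,
                 partition_method = partition_method,
                 active_processes = active_processes,
                 clearances = clearances,
                 endothelial_permeability_overrides =
                   endothelial_permeability_overrides),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model: %d compound(s) [%s], %s physiology (%d organs), %d active process(es)>\n",
              length(x$compounds), paste(names(x$compounds), collapse = ", "),
              attr(x$physiology, "species"), nrow(x$physiology),
              length(x$active_processes)))
  invisible(x)
}

#' One-compartment reference model
#'
#' A well-stirred single-volume model with a linear plasma clearance routed
#' to urine, for closed-form checks: an IV bolus gives
#' C(t) = (dose/V) exp(-CL/V t).
#'
#' @param volume_l compartment volume, L.
#' @param clearance_l_h linear clearance, L/h.
#' @param molecular_weight compound MW, g/mol.
#' @param id compound label.
#' @return a `pbpk_model`.
#' @export
one_compartment_model <- function(volume_l, clearance_l_h,
                                  molecular_weight = 100, id = "drug") {
  phys <- one_compartment_physiology(volume_l)
  cmp <- compound_properties(id, molecular_weight, logP = 0,
                             fraction_unbound = 1,
                             compound_type = "neutral")
  # express CL (L/h) as ml/h/kg against the physiology's nominal body weight
  cl <- clearance_spec(renal_plasma_clearance =
                         clearance_l_h * 1000 / attr(phys, "body_weight_kg"))
  m <- pbpk_model(list(cmp), phys,
                  clearances = stats::setNames(list(cl), id))
  m
}
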