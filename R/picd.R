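#' In vitro exposure description
#'
#' One assay condition: a constant medium concentration held for a given
#' duration, with responses measured at a subset of 2, 8, 24 h.
#'
#' @param compound_id compound label.
#' @param concentration assay medium concentration, µmol/L, > 0.
#' @param duration exposure duration, h, > 0.
#' @param timepoints_measured measured timepoints, subset of `c(2, 8, 24)`,
#'   all within the duration.
#' @return an object of class `in_vitro_exposure`.
#' @export
in_vitro_exposure <- function(compound_id, concentration, duration = 24,
                              timepoints_measured = c(2, 8, 24)) {
  assert_that(concentration > 0, "concentration must be > 0")
  assert_that(duration > 0, "duration must be > 0")
  assert_that(length(timepoints_measured) > 0 &&
                all(timepoints_measured %in% c(2, 8, 24)) &&
                all(timepoints_measured <= duration),
              "timepoints must be a non-empty subset of {2, 8, 24} h within the duration")
  structure(list(compound_id = compound_id, concentration = concentration,
                 duration = duration,
                 timepoints_measured = sort(timepoints_measured)),
            class = "in_vitro_exposure")
}

#' In vitro exposure AUC
#'
#' Under the constant-medium assumption the assay exposure integral is
#' concentration times duration.
#'
#' @param exposure an [in_vitro_exposure()].
#' @return AUC in µmol·h/L.
#' @export
in_vitro_auc <- function(exposure) {
  exposure$concentration * exposure$duration
}

# liver-interstitial AUC of `model` at IV bolus dose `dose_mg` over the
# exposure window
.liver_auc_at_dose <- function(model, dose_mg, duration, unbound, ...) {
  reg <- dosing_regimen("iv_bolus", dose = dose_mg, dose_times = 0)
  sim <- simulate_pk(model, reg, t_end = duration, ...)
  prof <- get_profile(sim, compartment = "liver",
                      subcompartment = "interstitial")
  auc <- compute_auc(prof, c(0, duration))
  if (unbound)
    auc <- auc * model$compounds[[sim$dose_compound]]$fraction_unbound
  auc
}

#' Find the in vivo dose matching an in vitro exposure
#'
#' The core of PICD: identify the intravenous dose whose simulated
#' liver-interstitial AUC over the exposure window equals the in vitro
#' exposure AUC. The search first probes dose linearity (two simulations);
#' if the system is linear the dose follows by scaling, otherwise a
#' bracketed bisection runs to the requested relative AUC tolerance. Total
#' (bound plus unbound) interstitial concentration is matched by default;
#' set `unbound = TRUE` to match unbound exposure.
#'
#' @param model a [pbpk_model()].
#' @param exposure an [in_vitro_exposure()].
#' @param dose_bracket initial dose bracket `[lo, hi]` in mg;
#'   auto-expanded up to `max_expand` doublings.
#' @param tolerance relative AUC mismatch at convergence (default 1e-6).
#' @param unbound match unbound instead of total interstitial AUC.
#' @param method `"auto"` (linearity shortcut, then bisection) or
#'   `"bisection"`.
#' @param max_expand maximum bracket doublings.
#' @param ... passed to [simulate_pk()].
#' @return the matching dose in mg, with attribute `auc_relative_error`.
#' @export
find_equivalent_dose <- function(model, exposure,
                                 dose_bracket = c(0.01, 100),
                                 tolerance = 1e-6, unbound = FALSE,
                                 method = c("auto", "bisection"),
                                 max_expand = 60, ...) {
  method <- match.arg(method)
  target <- in_vitro_auc(exposure)
  dur <- exposure$duration
  f <- function(d) .liver_auc_at_dose(model, d, dur, unbound, ...)
  if (method == "auto") {
    d_probe <- sqrt(prod(dose_bracket))
    a1 <- f(d_probe)
    a2 <- f(2 * d_probe)
    if (a1 > 0 && abs(a2 - 2 * a1) <= 1e-9 * (2 * a1)) {
      d_star <- d_probe * target / a1
      err <- abs(f(d_star) - target) / target
      if (err < tolerance)
        return(structure(d_star, auc_relative_error = err))
    }
  }
  lo <- dose_bracket[1]; hi <- dose_bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  n_exp <- 0
  while (f_lo > target && n_exp < max_expand) {
    lo <- lo / 2; f_lo <- f(lo); n_exp <- n_exp + 1
  }
  while (f_hi < target && n_exp < max_expand) {
    hi <- hi * 2; f_hi <- f(hi); n_exp <- n_exp + 1
  }
  if (f_lo > target || f_hi < target)
    stop_config("target AUC %.4g not bracketable in [%.4g, %.4g] mg after expansion",
                target, lo, hi)
  if (f_hi < f_lo)
    warning("liver AUC not monotone increasing in dose; proceeding with bisection",
            call. = FALSE)
  err <- Inf; mid <- NA_real_
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    err <- abs(fm - target) / target
    if (err < tolerance) break
    if (fm < target) lo <- mid else hi <- mid
  }
  structure(mid, auc_relative_error = err)
}

#' Build a time-dependent dose-response map
#'
#' For each assay concentration level, the AUC-equivalent in vivo dose is
#' identified and paired with that level's measured responses, yielding
#' per-timepoint dose-response anchor curves with an implicit (dose 0,
#' response 0) anchor. For oral administration the IV-equivalent dose is
#' divided by the bioavailability to express anchors as oral doses.
#'
#' @param model a [pbpk_model()].
#' @param exposures list of [in_vitro_exposure()] objects, one per assay
#'   concentration level (named by level, e.g. low/mid/high).
#' @param responses data.frame with columns `entity`, `level`, `time_h`,
#'   `response` (absolute log2 fold change, >= 0).
#' @param route `"iv"` or `"oral"`.
#' @param bioavailability fraction used for oral dose correction.
#' @param ... passed to [find_equivalent_dose()].
#' @return an object of class `dose_response_map`.
#' @export
build_dose_response_map <- function(model, exposures, responses,
                                    route = c("iv", "oral"),
                                    bioavailability = 1, ...) {
  route <- match.arg(route)
  assert_that(all(c("entity", "level", "time_h", "response") %in%
                    names(responses)),
              "responses must have entity, level, time_h, response columns")
  assert_that(all(responses$response >= 0),
              "responses must be non-negative (absolute log2FC scale)")
  if (is.null(names(exposures)))
    names(exposures) <- paste0("level", seq_along(exposures))
  lvl <- names(exposures)
  assert_that(all(responses$level %in% lvl),
              "response levels must match exposure names")
  doses <- vapply(exposures, function(e)
    as.numeric(find_equivalent_dose(model, e, ...)), 0)
  if (route == "oral") {
    assert_that(bioavailability > 0 && bioavailability <= 1,
                "bioavailability must be in (0, 1]")
    doses <- doses / bioavailability
  }
  ord <- order(doses)
  if (any(diff(doses[ord]) <= 1e-9 * max(doses)))
    stop_config("duplicate equivalent doses for distinct concentrations")
  anchors <- data.frame(level = lvl[ord], dose_mg = doses[ord],
                        stringsAsFactors = FALSE)
  structure(list(compound_id = exposures[[1]]$compound_id,
                 anchors = anchors, responses = responses,
                 route = route, bioavailability = bioavailability,
                 timepoints = sort(unique(responses$time_h))),
            class = "dose_response_map")
}

#' @export
print.dose_response_map <- function(x, ...) {
  cat(sprintf("<dose_response_map %s (%s): anchors %s mg at %s; timepoints %s h>\n",
              x$compound_id, x$route,
              paste(signif(x$anchors$dose_mg, 4), collapse = ", "),
              paste(x$anchors$level, collapse = "/"),
              paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' Predict the in vivo response at a dose
#'
#' Responses are linearly interpolated (on the natural dose scale) between
#' the bracketing dose anchors, with the implicit (0, 0) anchor below the
#' first positive anchor. Doses above the highest anchor are clamped to the
#' highest anchor's response with a warning. When no 2 h responses were
#' measured, the 2 h value is linearly interpolated in time between
#' (0 h, 0) and the 8 h value, i.e. (2/8) of the 8 h response.
#'
#' @param map a [build_dose_response_map()] result.
#' @param dose dose in mg (same route as the map), >= 0.
#' @param dose_label label, e.g. `"therapeutic"` or `"toxic"`.
#' @param log_dose interpolate on the log-dose scale instead (anchors and
#'   dose must then be positive).
#' @return an object of class `contextualized_response` holding a
#'   data.frame `response` with columns `entity`, `time_h`, `response`.
#' @export
contextualize_response <- function(map, dose, dose_label = "dose",
                                   log_dose = FALSE) {
  assert_that(inherits(map, "dose_response_map"), "map must be a dose_response_map")
  assert_that(nrow(map$anchors) > 0, "empty dose-response map")
  assert_that(dose >= 0, "dose must be >= 0")
  d_anch <- c(0, map$anchors$dose_mg)
  clamped <- dose > max(d_anch)
  if (clamped) {
    warning(sprintf("dose %.4g mg above highest anchor %.4g mg; response clamped",
                    dose, max(d_anch)), call. = FALSE)
  }
  d_eval <- min(dose, max(d_anch))
  tx <- function(d) if (log_dose) log(pmax(d, 1e-12)) else d
  out <- list()
  tps <- map$timepoints
  for (tp in tps) {
    sub <- map$responses[map$responses$time_h == tp, , drop = FALSE]
    wide <- stats::reshape(sub[, c("entity", "level", "response")],
                           direction = "wide", idvar = "entity",
                           timevar = "level")
    ent <- wide$entity
    R <- as.matrix(wide[, paste0("response.", map$anchors$level),
                        drop = FALSE])
    R <- cbind(0, R)  # the (0, 0) anchor
    da <- tx(d_anch)
    j <- findInterval(tx(d_eval), da, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(da) - 1L)
    w <- if (da[j + 1] > da[j])
      (tx(d_eval) - da[j]) / (da[j + 1] - da[j]) else 0
    vals <- (1 - w) * R[, j] + w * R[, j + 1]
    out[[as.character(tp)]] <- data.frame(entity = ent, time_h = tp,
                                          response = unname(vals),
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!2 %in% tps && 8 %in% tps) {
    r8 <- res[res$time_h == 8, , drop = FALSE]
    r2 <- transform(r8, time_h = 2, response = response * 2 / 8)
    res <- rbind(r2, res)
  }
  rownames(res) <- NULL
  res <- res[order(res$time_h, res$entity), , drop = FALSE]
  structure(list(compound_id = map$compound_id, dose_label = dose_label,
                 dose = dose, clamped = clamped, response = res),
            class = "contextualized_response")
}

#' @export
print.contextualized_response <- function(x, ...) {
  cat(sprintf("<contextualized_response %s [%s, %.4g mg]: %d entities x %d timepoints%s>\n",
              x$compound_id, x$dose_label, x$dose,
              length(unique(x$response$entity)),
              length(unique(x$response$time_h)),
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}
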