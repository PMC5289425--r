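# Parameter estimation for PBPK models.

# Resolve a free-parameter label to a getter/setter on the model.
# Supported labels:
#   clearance.<compound>.<renal|biliary|hepatic>   (ml/h/kg)
#   process.<k>.<vmax|Km>                          (k = index or enzyme label)
.param_accessor <- function(model, label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  if (parts[1] == "clearance" && length(parts) == 3) {
    cid <- parts[2]
    field <- c(renal = "renal_plasma_clearance",
               biliary = "biliary_clearance",
               hepatic = "hepatic_plasma_clearance")[[parts[3]]]
    if (is.null(field) || !cid %in% names(model$compounds))
      stop_config("cannot resolve parameter '%s'", label)
    list(
      get = function(m) {
        cs <- m$clearances[[cid]]
        if (is.null(cs)) 0 else cs[[field]]
      },
      set = function(m, v) {
        cs <- m$clearances[[cid]] %||% clearance_spec()
        cs[[field]] <- v
        m$clearances[[cid]] <- cs
        m
      })
  } else if (parts[1] == "process" && length(parts) == 3) {
    k <- suppressWarnings(as.integer(parts[2]))
    if (is.na(k)) {
      lbl <- vapply(model$active_processes, `[[`, "",
                    "enzyme_or_transporter")
      k <- match(parts[2], lbl)
    }
    if (is.na(k) || k > length(model$active_processes))
      stop_config("cannot resolve parameter '%s'", label)
    field <- match.arg(parts[3], c("vmax", "Km"))
    list(
      get = function(m) m$active_processes[[k]][[field]],
      set = function(m, v) {
        m$active_processes[[k]][[field]] <- v
        m
      })
  } else stop_config("cannot resolve parameter '%s'", label)
}

set_model_params <- function(model, values) {
  for (lbl in names(values))
    model <- .param_accessor(model, lbl)$set(model, values[[lbl]])
  model
}

#' Goodness of fit between simulated and observed profiles
#'
#' The simulated profile is linearly interpolated to the observed times.
#' The root-mean-square deviation is normalized by the mean of the observed
#' values; the coefficient of determination comes from the linear
#' regression of observed on predicted values.
#'
#' @param simulated,observed `pk_profile` objects (or lists with `times`
#'   and `values`); observed times must lie within the simulated support.
#' @return list with `normalized_RMSD`, `R_squared`, `RMSD` and the paired
#'   `predicted` values.
#' @export
goodness_of_fit <- function(simulated, observed) {
  assert_that(length(observed$times) >= 3,
              "goodness of fit needs at least 3 observation points")
  pred <- stats::approx(simulated$times, simulated$values,
                        xout = observed$times)$y
  assert_that(!anyNA(pred),
              "observed times outside the simulated support")
  obs <- observed$values
  rmsd <- sqrt(mean((obs - pred)^2))
  # R^2 of the simple linear regression of observed on predicted equals
  # the squared Pearson correlation
  r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(obs, pred)^2
  list(normalized_RMSD = rmsd / mean(obs),
       RMSD = rmsd,
       R_squared = r2,
       predicted = pred)
}

#' Fit free PBPK parameters to observed concentration data
#'
#' Least-squares estimation (Levenberg-Marquardt, `minpack.lm::nls.lm`)
#' of selected model parameters against an observed concentration-time
#' profile. Parameters are addressed by label:
#' `clearance.<compound>.<renal|biliary|hepatic>` (ml/h/kg) and
#' `process.<index-or-enzyme>.<vmax|Km>`. The optimization is deterministic
#' for fixed starting values.
#'
#' @param model a [pbpk_model()].
#' @param observed a `pk_profile` (or list with `times`/`values`) of
#'   observed venous plasma concentrations (µmol/L).
#' @param regimen the [dosing_regimen()] under which the data were
#'   collected.
#' @param start named numeric vector of starting values; the names are the
#'   free-parameter labels. May be empty, in which case only goodness of
#'   fit is computed.
#' @param lower,upper parameter bounds (recycled); must be finite for a
#'   bounded search.
#' @param compartment,subcompartment which simulated profile to match.
#' @param t_end simulation horizon, h (default: past the last observation).
#' @param rtol,atol solver tolerances used during fitting.
#' @param log_residuals minimize on the log-concentration scale
#'   (proportional-error model, appropriate for multiplicative assay
#'   noise) instead of the absolute scale.
#' @return an object of class `pbpk_fit`.
#' @export
fit_pbpk <- function(model, observed, regimen, start = numeric(0),
                     lower = 0, upper = Inf,
                     compartment = "venous_plasma",
                     subcompartment = "plasma",
                     t_end = NULL, rtol = 1e-6, atol = 1e-8,
                     log_residuals = FALSE) {
  t_end <- t_end %||% (max(observed$times) * 1.05)
  labels <- names(start)
  assert_that(length(observed$times) >= length(start),
              "need at least as many observations as free parameters")
  sim_at <- function(values) {
    m <- set_model_params(model, stats::setNames(as.list(values), labels))
    sim <- simulate_pk(m, regimen, t_end = t_end, rtol = rtol, atol = atol,
                       n_grid = 121L)
    get_profile(sim, compartment = compartment,
                subcompartment = subcompartment)
  }
  if (length(start) == 0L) {
    prof <- sim_at(numeric(0))
    gof <- goodness_of_fit(prof, observed)
    return(structure(list(coefficients = numeric(0),
                          residuals = observed$values - gof$predicted,
                          gof = gof, model = model, observed = observed,
                          regimen = regimen, convergence = NA,
                          flat_parameters = character(0)),
                     class = "pbpk_fit"))
  }
  lower <- rep_len(lower, length(start))
  upper <- rep_len(upper, length(start))
  resid_fun <- function(p) {
    prof <- sim_at(p)
    pred <- stats::approx(prof$times, prof$values,
                          xout = observed$times)$y
    if (log_residuals)
      log(pmax(observed$values, 1e-12)) - log(pmax(pred, 1e-12))
    else observed$values - pred
  }
  # epsfcn reflects the ODE-solver noise floor in the residuals so the
  # finite-difference Jacobian steps stay above it
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-10,
                              epsfcn = max(rtol, 1e-10)))
  est <- stats::setNames(as.numeric(fit$par), labels)
  # flag parameters with a locally flat objective (non-identifiable)
  scale_r <- sqrt(mean(observed$values^2))
  flat <- character(0)
  r0 <- resid_fun(est)
  for (i in seq_along(est)) {
    p2 <- est
    p2[i] <- p2[i] * 1.01 + 1e-9
    if (max(abs(resid_fun(p2) - r0)) < 1e-9 * max(scale_r, 1e-12))
      flat <- c(flat, labels[i])
  }
  if (length(flat))
    warning(sprintf("objective locally flat in: %s (non-identifiable?)",
                    paste(flat, collapse = ", ")), call. = FALSE)
  fitted_model <- set_model_params(model, as.list(est))
  prof <- sim_at(est)
  gof <- goodness_of_fit(prof, observed)
  structure(list(coefficients = est, residuals = r0, gof = gof,
                 model = fitted_model, observed = observed,
                 regimen = regimen, convergence = fit$info,
                 message = fit$message, flat_parameters = flat),
            class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat("<pbpk_fit>\n")
  if (length(x$coefficients)) {
    cat("  estimates:\n")
    for (nm in names(x$coefficients))
      cat(sprintf("    %-30s %.6g\n", nm, x$coefficients[[nm]]))
  } else cat("  (no free parameters; goodness of fit only)\n")
  cat(sprintf("  normalized RMSD %.4g, R^2 %.4f\n",
              x$gof$normalized_RMSD, x$gof$R_squared))
  invisible(x)
}

#' @export
summary.pbpk_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 gof = object$gof,
                 n_obs = length(object$observed$times),
                 convergence = object$convergence,
                 flat_parameters = object$flat_parameters),
            class = "summary.pbpk_fit")
}

#' @export
print.summary.pbpk_fit <- function(x, ...) {
  cat("PBPK fit summary\n")
  cat(sprintf("  observations: %d\n", x$n_obs))
  if (length(x$coefficients))
    print(x$coefficients)
  cat(sprintf("  normalized RMSD: %.4g\n  R^2: %.4f\n",
              x$gof$normalized_RMSD, x$gof$R_squared))
  if (length(x$flat_parameters))
    cat("  flat (non-identifiable) parameters:",
        paste(x$flat_parameters, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pbpk_fit <- function(object, ...) object$coefficients

#' @export
residuals.pbpk_fit <- function(object, ...) object$residuals

#' @export
fitted.pbpk_fit <- function(object, ...)
  object$observed$values - object$residuals

#' Predict concentrations from a fitted PBPK model
#'
#' Re-simulates the fitted model and returns concentrations at the
#' requested times.
#'
#' @param object a `pbpk_fit`.
#' @param times times in h (default: the observed times).
#' @param ... passed to [simulate_pk()].
#' @return numeric vector of concentrations, µmol/L.
#' @export
predict.pbpk_fit <- function(object, times = object$observed$times, ...) {
  sim <- simulate_pk(object$model, object$regimen,
                     t_end = max(times) * 1.05, ...)
  prof <- get_profile(sim)
  stats::approx(prof$times, prof$values, xout = times)$y
}

#' @export
plot.pbpk_fit <- function(x, ...) {
  sim <- simulate_pk(x$model, x$regimen,
                     t_end = max(x$observed$times) * 1.05)
  prof <- get_profile(sim)
  plot(prof$times, prof$values, type = "l",
       xlab = "time [h]", ylab = "venous plasma conc [µmol/L]", ...)
  graphics::points(x$observed$times, x$observed$values, pch = 19)
  invisible(x)
}
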