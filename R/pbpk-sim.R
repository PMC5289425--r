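# Whole-body PBPK simulation engine.
#
# Internal unit system: time h, amounts µmol, concentrations µmol/L. Doses
# in mg are converted at intake via the molecular weight. Each organ is a
# well-stirred compartment; blood leaving an organ carries the organ
# plasma concentration C_organ / Kp. Sub-compartment concentrations are
# derived algebraically (plasma = interstitial = C/Kp by default, i.e.
# unlimited endothelial exchange; intracellular holds the remainder),
# except where an endothelial permeability override splits the organ into
# vascular and extravascular states with permeability-limited exchange.
# Saturable processes sample the organ plasma concentration (well-stirred
# convention) with vmax referenced to the intracellular volume.

# fixture constants for oral absorption and endothelial exchange
.GUT_LUMEN_SA_CM2 <- 7000    # effective absorptive surface area
.GUT_LUMEN_VOL_L  <- 1       # lumen fluid volume
.ENDOTHELIAL_SA_CM2_PER_L <- 7000  # capillary surface area per L organ

mg_to_umol <- function(mg, mw) mg / mw * 1000

.sim_layout <- function(model) {
  phys <- model$physiology
  orgs <- phys$organ
  single_pool <- identical(orgs, "venous_blood")
  if (!single_pool) {
    needed <- c("venous_blood", "arterial_blood", "lung")
    if (!all(needed %in% orgs))
      stop_config("physiology must contain %s (or be a single venous pool)",
                  paste(needed, collapse = ", "))
  }
  cids <- names(model$compounds)
  over <- lapply(cids, function(cid) {
    ov <- model$endothelial_permeability_overrides[[cid]]
    if (is.null(ov)) character(0) else intersect(names(ov), orgs)
  })
  names(over) <- cids
  state_names <- unlist(lapply(cids, function(cid) {
    c(paste0(cid, "|org|", orgs),
      if (length(over[[cid]])) paste0(cid, "|ext|", over[[cid]]),
      paste0(cid, "|", c("lumen", "urine", "bile", "cleared")))
  }))
  list(orgs = orgs, single_pool = single_pool, cids = cids,
       over = over, state_names = state_names)
}

#' Simulate a PBPK model under a dosing regimen
#'
#' Integrates the whole-body system with a stiff solver (lsoda, relative
#' tolerance 1e-8, absolute 1e-10 by default) and returns concentration
#' profiles for every compound and organ plus cumulative urine, bile and
#' unspecific hepatic-cleared amounts. The dose is administered to
#' `dose_compound` (the first declared compound by default).
#'
#' @param model a [pbpk_model()].
#' @param regimen a [dosing_regimen()].
#' @param t_end simulation end, h; must exceed the last dose time.
#' @param rtol,atol solver tolerances.
#' @param n_grid number of output points (default at least 200 per 24 h).
#' @param dose_compound compound id receiving the dose.
#' @return an object of class `pbpk_simulation`.
#' @export
simulate_pk <- function(model, regimen, t_end = 24, rtol = 1e-8,
                        atol = 1e-10, n_grid = NULL, dose_compound = NULL) {
  assert_that(inherits(model, "pbpk_model"), "model must be a pbpk_model")
  assert_that(inherits(regimen, "dosing_regimen"),
              "regimen must be a dosing_regimen")
  assert_that(t_end > max(regimen$dose_times),
              "t_end must exceed the last dose time")
  lay <- .sim_layout(model)
  phys <- model$physiology
  orgs <- lay$orgs
  n_org <- length(orgs)
  V <- phys$volume_l
  Q <- phys$flow_l_h
  names(V) <- names(Q) <- orgs
  bw <- attr(phys, "body_weight_kg")
  gfr <- attr(phys, "gfr_l_h")
  cids <- lay$cids
  dose_compound <- dose_compound %||% cids[1]
  assert_that(dose_compound %in% cids,
              "dose_compound '%s' not declared", dose_compound)

  i_ven <- match("venous_blood", orgs)
  i_art <- match("arterial_blood", orgs)
  i_lung <- match("lung", orgs)
  i_liv <- match("liver", orgs)
  i_kid <- match("kidney", orgs)
  i_gut <- match("gut", orgs)
  spl <- which(orgs %in% splanchnic_organs())
  direct <- setdiff(seq_len(n_org),
                    c(i_ven, i_art, i_lung, i_liv, spl))
  direct <- direct[!is.na(direct)]
  q_co <- if (!lay$single_pool) Q[i_lung] else 0
  q_liv_out <- if (!is.na(i_liv)) Q[i_liv] + sum(Q[spl]) else 0

  # per-compound constants
  n_c <- length(cids)
  mw <- vapply(model$compounds, `[[`, 0, "molecular_weight")
  fu <- vapply(model$compounds, `[[`, 0, "fraction_unbound")
  kp <- lapply(cids, function(cid) {
    k <- model$partition_coefficients[[cid]][orgs]
    k[orgs %in% blood_pools()] <- 1  # pools hold plasma directly
    k
  })
  names(kp) <- cids
  cl_abs <- lapply(cids, function(cid) {
    cs <- model$clearances[[cid]]
    if (is.null(cs)) cs <- clearance_spec()
    renal <- if (cs$renal_mode == "gfr_fraction")
      cs$renal_plasma_clearance * gfr * fu[[cid]]
    else cs$renal_plasma_clearance * bw / 1000
    c(renal = renal,
      biliary = cs$biliary_clearance * bw / 1000,
      hepatic = cs$hepatic_plasma_clearance * bw / 1000)
  })
  names(cl_abs) <- cids

  # override-organ geometry: vascular and extravascular volumes and the
  # extravascular/plasma equilibrium ratio consistent with the organ Kp
  over_geom <- lapply(cids, function(cid) {
    ovo <- lay$over[[cid]]
    if (!length(ovo)) return(NULL)
    j <- match(ovo, orgs)
    v_vas <- V[j] * (phys$f_plasma[j] + phys$f_rbc[j])
    v_ext <- V[j] * (phys$f_interstitial[j] + phys$f_intracellular[j])
    kp_ext <- pmax((kp[[cid]][j] * V[j] - v_vas) / v_ext, 1e-6)
    ps <- model$endothelial_permeability_overrides[[cid]][ovo] * 3600 *
      .ENDOTHELIAL_SA_CM2_PER_L * V[j] / 1000  # cm/s -> L/h
    list(organs = ovo, j = j, v_vas = v_vas, v_ext = v_ext,
         kp_ext = kp_ext, ps = ps)
  })
  names(over_geom) <- cids

  # process constants
  procs <- lapply(model$active_processes, function(p) {
    j <- match(p$organ, orgs)
    vmax_abs <- p$vmax * V[j] * phys$f_intracellular[j] * p$relative_expression
    list(kind = p$kind, j = j, Km = p$Km, vmax_abs = vmax_abs,
         sub = p$compound_id, prod = p$product_id, dir = p$direction)
  })

  # oral absorption rate constant and solubility cap
  ka <- 0; sol_cap <- Inf
  if (regimen$route == "oral") {
    ka <- regimen$intestinal_permeability * 3600 * .GUT_LUMEN_SA_CM2 /
      (.GUT_LUMEN_VOL_L * 1000)  # cm/s * cm2 / cm3 * 3600 -> 1/h
    sol <- model$compounds[[dose_compound]]$water_solubility
    sol_cap <- sol / mw[[dose_compound]] * 1000 * .GUT_LUMEN_VOL_L  # µmol
  }
  dose_umol <- mg_to_umol(regimen$dose, mw[[dose_compound]])
  if (length(dose_umol) == 1L && length(regimen$dose_times) > 1L)
    dose_umol <- rep(dose_umol, length(regimen$dose_times))

  sn <- lay$state_names
  ns <- length(sn)
  y0 <- stats::setNames(numeric(ns), sn)
  org_idx <- lapply(cids, function(cid)
    match(paste0(cid, "|org|", orgs), sn))
  names(org_idx) <- cids
  misc_idx <- lapply(cids, function(cid)
    stats::setNames(match(paste0(cid, "|", c("lumen", "urine", "bile",
                                             "cleared")), sn),
                    c("lumen", "urine", "bile", "cleared")))
  names(misc_idx) <- cids
  ext_idx <- lapply(cids, function(cid) {
    ovo <- lay$over[[cid]]
    if (length(ovo)) match(paste0(cid, "|ext|", ovo), sn) else integer(0)
  })
  names(ext_idx) <- cids

  infusion_rate <- function(t) {
    if (regimen$route != "iv_infusion") return(0)
    on <- t >= regimen$dose_times &
      t < regimen$dose_times + regimen$infusion_duration
    sum(dose_umol[on] / regimen$infusion_duration)
  }

  rhs <- function(t, y, parms) {
    dy <- numeric(ns)
    for (ci in seq_len(n_c)) {
      cid <- cids[ci]
      oi <- org_idx[[cid]]
      A <- y[oi]
      kpc <- kp[[cid]]
      og <- over_geom[[cid]]
      # exit/plasma concentration per organ
      cp <- (A / V) / kpc
      if (!is.null(og)) cp[og$j] <- A[og$j] / og$v_vas
      if (lay$single_pool) {
        d <- numeric(n_org)
      } else {
        c_art <- cp[i_art]
        d <- Q * (c_art - cp)          # generic tissue perfusion
        d[i_lung] <- q_co * (cp[i_ven] - cp[i_lung])
        d[i_art] <- q_co * cp[i_lung] - q_co * c_art
        if (!is.na(i_liv))
          d[i_liv] <- Q[i_liv] * c_art + sum(Q[spl] * cp[spl]) -
            q_liv_out * cp[i_liv]
        d[i_ven] <- sum(Q[direct] * cp[direct]) +
          (if (!is.na(i_liv)) q_liv_out * cp[i_liv] else 0) -
          q_co * cp[i_ven]
      }
      # endothelial-override exchange
      if (!is.null(og)) {
        Ae <- y[ext_idx[[cid]]]
        ce <- Ae / og$v_ext
        flux <- og$ps * (cp[og$j] - ce / og$kp_ext)
        d[og$j] <- d[og$j] - flux
        dy[ext_idx[[cid]]] <- flux
      }
      # clearances
      clc <- cl_abs[[cid]]
      j_ren <- if (!is.na(i_kid)) i_kid else i_ven
      j_hep <- if (!is.na(i_liv)) i_liv else i_ven
      r_ren <- clc[["renal"]] * cp[j_ren]
      r_bil <- clc[["biliary"]] * cp[j_hep]
      r_hep <- clc[["hepatic"]] * cp[j_hep]
      d[j_ren] <- d[j_ren] - r_ren
      d[j_hep] <- d[j_hep] - r_bil - r_hep
      mi <- misc_idx[[cid]]
      dy[mi[["urine"]]] <- r_ren
      dy[mi[["bile"]]] <- r_bil
      dy[mi[["cleared"]]] <- r_hep
      dy[oi] <- dy[oi] + d
    }
    # saturable processes (cross-compound mass movement)
    for (p in procs) {
      oi <- org_idx[[p$sub]]
      og <- over_geom[[p$sub]]
      s <- if (!is.null(og) && p$j %in% og$j) {
        k <- match(p$j, og$j)
        (y[ext_idx[[p$sub]]][k] / og$v_ext[k]) / og$kp_ext[k]
      } else (y[oi[p$j]] / V[p$j]) / kp[[p$sub]][p$j]
      s <- max(s, 0)
      r <- p$vmax_abs * s / (p$Km + s)
      take <- if (!is.null(og) && p$j %in% og$j)
        ext_idx[[p$sub]][match(p$j, og$j)] else oi[p$j]
      if (p$kind == "metabolism") {
        dy[take] <- dy[take] - r
        dy[org_idx[[p$prod]][p$j]] <- dy[org_idx[[p$prod]][p$j]] + r
      } else if (p$dir == "influx") {
        pool <- if (lay$single_pool) i_ven else i_art
        s_in <- max((y[oi[pool]] / V[pool]) / kp[[p$sub]][pool], 0)
        r <- p$vmax_abs * s_in / (p$Km + s_in)
        dy[oi[pool]] <- dy[oi[pool]] - r
        dy[take] <- dy[take] + r
      } else {  # efflux
        dy[take] <- dy[take] - r
        dy[oi[i_ven]] <- dy[oi[i_ven]] + r
      }
    }
    # oral absorption from the gut lumen
    if (regimen$route == "oral") {
      il <- misc_idx[[dose_compound]][["lumen"]]
      absorbable <- min(max(y[il], 0), sol_cap)
      r_abs <- ka * absorbable
      dy[il] <- dy[il] - r_abs
      target <- if (!is.na(i_gut)) i_gut else if (!is.na(i_liv)) i_liv
                else i_ven
      ti <- org_idx[[dose_compound]][target]
      dy[ti] <- dy[ti] + r_abs
    }
    # iv infusion
    r_inf <- infusion_rate(t)
    if (r_inf > 0) {
      vi <- org_idx[[dose_compound]][i_ven]
      dy[vi] <- dy[vi] + r_inf
    }
    list(dy)
  }

  # bolus and oral doses: t = 0 doses seed the initial state, later doses
  # are discrete solver events
  ev <- NULL
  if (regimen$route %in% c("iv_bolus", "oral")) {
    var <- if (regimen$route == "iv_bolus")
      paste0(dose_compound, "|org|venous_blood")
    else paste0(dose_compound, "|lumen")
    at0 <- regimen$dose_times == 0
    if (any(at0)) y0[var] <- y0[var] + sum(dose_umol[at0])
    if (any(!at0))
      ev <- data.frame(var = var, time = regimen$dose_times[!at0],
                       value = dose_umol[!at0], method = "add",
                       stringsAsFactors = FALSE)
  }

  n_grid <- n_grid %||% max(201L, ceiling(200 * t_end / 24) + 1L)
  times <- c(seq(0, t_end, length.out = n_grid),
             regimen$dose_times,
             if (regimen$route == "iv_infusion")
               regimen$dose_times + regimen$infusion_duration)
  # log-spaced refinement after each dose so the fast distribution
  # transient is resolved and trapezoidal AUCs stay accurate
  for (td in regimen$dose_times) {
    span <- t_end - td
    if (span > 1e-3)
      times <- c(times, td + 10^seq(-4, log10(span),
                                    length.out = max(80L, n_grid %/% 2L)))
  }
  times <- sort(unique(times))
  times <- times[times <= t_end]

  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = if (!is.null(ev)) list(data = ev),
                      maxsteps = 50000)
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
    stop_config("ODE integration failed (istate %d)",
                attr(out, "istate")[1])
  states <- out[, -1, drop = FALSE]
  neg <- min(states)
  tol_neg <- max(atol * 100, 1e-6 * max(abs(states)))
  if (neg < -tol_neg)
    stop_config("negative state beyond tolerance (min %.3g)", neg)
  states[states < 0] <- 0

  administered <- vapply(out[, 1], function(t) {
    if (regimen$route == "iv_infusion") {
      done <- pmin(pmax(t - regimen$dose_times, 0),
                   regimen$infusion_duration)
      sum(dose_umol * done / regimen$infusion_duration)
    } else {
      # the solver reports the state at an event time before applying the
      # event, so later doses count strictly after their dose time
      sum(dose_umol[regimen$dose_times < t | regimen$dose_times == 0])
    }
  }, 0)

  structure(list(model = model, regimen = regimen,
                 dose_compound = dose_compound,
                 times = out[, 1], states = states,
                 state_names = sn, layout = lay,
                 kp = kp, administered_umol = administered),
            class = "pbpk_simulation")
}

#' @export
print.pbpk_simulation <- function(x, ...) {
  cat(sprintf("<pbpk_simulation: %s %s, %d compounds, t 0-%.3g h, %d output points>\n",
              x$regimen$route, paste(format(x$regimen$dose), collapse = "+"),
              length(x$layout$cids), max(x$times), length(x$times)))
  invisible(x)
}

.state_col <- function(sim, name) {
  j <- match(name, sim$state_names)
  if (is.na(j)) stop_config("no state '%s' in simulation", name)
  sim$states[, j]
}

#' Extract a concentration-time profile from a simulation
#'
#' Compartments: `"venous_plasma"`, `"urine"`, `"bile"`, `"cleared"`,
#' `"gut_lumen"` (amounts, µmol), or an `(organ, subcompartment)` pair with
#' subcompartment one of `"plasma"`, `"interstitial"`, `"intracellular"`,
#' `"total"` (concentrations, µmol/L).
#'
#' @param sim a `pbpk_simulation`.
#' @param compound compound id (default: the dosed compound).
#' @param compartment compartment label, see Details.
#' @param subcompartment sub-compartment label when `compartment` is an
#'   organ.
#' @return an object of class `pk_profile` with fields `compound_id`,
#'   `compartment`, `times` (h) and `values`.
#' @export
get_profile <- function(sim, compound = NULL,
                        compartment = "venous_plasma",
                        subcompartment = "plasma") {
  compound <- compound %||% sim$dose_compound
  phys <- sim$model$physiology
  orgs <- sim$layout$orgs
  lbl <- compartment
  if (compartment == "venous_plasma") {
    vals <- .state_col(sim, paste0(compound, "|org|venous_blood")) /
      phys$volume_l[match("venous_blood", orgs)]
  } else if (compartment %in% c("urine", "bile", "cleared")) {
    vals <- .state_col(sim, paste0(compound, "|", compartment))
  } else if (compartment == "gut_lumen") {
    vals <- .state_col(sim, paste0(compound, "|lumen"))
  } else if (compartment %in% orgs) {
    j <- match(compartment, orgs)
    ovo <- sim$layout$over[[compound]]
    if (compartment %in% ovo) {
      v_vas <- phys$volume_l[j] * (phys$f_plasma[j] + phys$f_rbc[j])
      v_ext <- phys$volume_l[j] * (phys$f_interstitial[j] +
                                     phys$f_intracellular[j])
      a_vas <- .state_col(sim, paste0(compound, "|org|", compartment))
      a_ext <- .state_col(sim, paste0(compound, "|ext|", compartment))
      vals <- switch(subcompartment,
        plasma = a_vas / v_vas,
        interstitial = ,
        intracellular = a_ext / v_ext,
        total = (a_vas + a_ext) / phys$volume_l[j],
        stop_config("unknown subcompartment '%s'", subcompartment))
    } else {
      a <- .state_col(sim, paste0(compound, "|org|", compartment))
      c_tot <- a / phys$volume_l[j]
      cp <- c_tot / sim$kp[[compound]][j]
      vals <- switch(subcompartment,
        plasma = ,
        interstitial = cp,
        intracellular = {
          fc <- phys$f_intracellular[j]
          pmax((c_tot - cp * (1 - fc)) / max(fc, 1e-12), 0)
        },
        total = c_tot,
        stop_config("unknown subcompartment '%s'", subcompartment))
    }
    lbl <- paste0(compartment, ":", subcompartment)
  } else stop_config("unknown compartment '%s'", compartment)
  structure(list(compound_id = compound, compartment = lbl,
                 times = sim$times, values = unname(vals)),
            class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile %s @ %s: %d points, t %.3g-%.3g h, Cmax %.4g>\n",
              x$compound_id, x$compartment, length(x$times),
              min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.pbpk_simulation <- function(x, ...) {
  phys <- x$model$physiology
  rows <- list()
  for (cid in x$layout$cids) {
    for (org in x$layout$orgs) {
      for (sub in c("plasma", "interstitial", "intracellular")) {
        pr <- get_profile(x, cid, org, sub)
        rows[[length(rows) + 1L]] <-
          data.frame(compound = cid, organ = org, subcompartment = sub,
                     time_h = pr$times, value = pr$values,
                     stringsAsFactors = FALSE)
      }
    }
    for (amt in c("urine", "bile")) {
      pr <- get_profile(x, cid, amt)
      rows[[length(rows) + 1L]] <-
        data.frame(compound = cid, organ = amt, subcompartment = "amount",
                   time_h = pr$times, value = pr$values,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate method for PBPK models
#'
#' Thin wrapper around [simulate_pk()] so `pbpk_model` objects follow the
#' base `simulate()` generic.
#'
#' @param object a `pbpk_model`.
#' @param nsim ignored (the model is deterministic).
#' @param seed ignored.
#' @param regimen,t_end,... passed to [simulate_pk()].
#' @return a `pbpk_simulation`.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL, regimen,
                                t_end = 24, ...) {
  simulate_pk(object, regimen, t_end = t_end, ...)
}

#' Mass balance of a simulation
#'
#' At every output time the administered amount must equal body burden plus
#' excreted and cleared amounts, summed over all compounds (metabolic
#' conversion conserves µmol mole-for-mole).
#'
#' @param sim a `pbpk_simulation`.
#' @return list with per-time `relative_error` and its maximum
#'   `max_relative_error`.
#' @export
mass_balance <- function(sim) {
  total <- numeric(length(sim$times))
  for (cid in sim$layout$cids) {
    oi <- match(paste0(cid, "|org|", sim$layout$orgs), sim$state_names)
    total <- total + rowSums(sim$states[, oi, drop = FALSE])
    ei <- grep(paste0("^", cid, "\\|ext\\|"), sim$state_names)
    if (length(ei))
      total <- total + rowSums(sim$states[, ei, drop = FALSE])
    for (w in c("lumen", "urine", "bile", "cleared"))
      total <- total + .state_col(sim, paste0(cid, "|", w))
  }
  denom <- pmax(sim$administered_umol, .Machine$double.eps)
  rel <- abs(total - sim$administered_umol) / denom
  rel[sim$administered_umol == 0] <- abs(total[sim$administered_umol == 0])
  list(relative_error = rel, max_relative_error = max(rel))
}

#' Trapezoidal area under a concentration-time profile
#'
#' @param profile a `pk_profile` or a list/data.frame with `times` and
#'   `values`.
#' @param interval `[t0, t1]` in h, within the profile support; interval
#'   bounds not on the grid are linearly interpolated.
#' @return AUC in µmol·h/L (or µmol·h for amount profiles).
#' @export
compute_auc <- function(profile, interval = range(profile$times)) {
  t0 <- interval[1]; t1 <- interval[2]
  assert_that(t1 > t0, "interval end must exceed start")
  tt <- profile$times; vv <- profile$values
  assert_that(t0 >= min(tt) - 1e-12 && t1 <= max(tt) + 1e-12,
              "interval [%g, %g] outside profile support [%g, %g]",
              t0, t1, min(tt), max(tt))
  keep <- tt > t0 & tt < t1
  ts <- c(t0, tt[keep], t1)
  vs <- c(stats::approx(tt, vv, xout = t0)$y, vv[keep],
          stats::approx(tt, vv, xout = t1)$y)
  sum(diff(ts) * (utils::head(vs, -1) + utils::tail(vs, -1)) / 2)
}
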