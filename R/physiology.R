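#' Species physiology tables
#'
#' A physiology table describes the organism the PBPK model is built on:
#' one row per organ with its volume (L), its arterial blood inflow (L/h),
#' the sub-compartment volume fractions (plasma, red blood cells,
#' interstitial, intracellular; summing to 1 per organ) and the tissue
#' water/lipid composition used by the partition-coefficient calculation.
#' Whole-body scalars (body weight kg, hematocrit, glomerular filtration
#' rate L/h) travel as attributes.
#'
#' The circulation topology is fixed: venous blood passes through the lung
#' to the arterial pool; all other organs receive arterial blood and drain
#' to the venous pool, except the splanchnic organs (gut, spleen, pancreas,
#' stomach) which drain into the liver (portal flow). The liver row's
#' `flow_l_h` is the hepatic artery only; its outflow is artery plus portal.
#'
#' @param organs data.frame with columns `organ`, `volume_l`, `flow_l_h`,
#'   `f_plasma`, `f_rbc`, `f_interstitial`, `f_intracellular`, `f_water`,
#'   `f_lipid`.
#' @param species `"human"` or `"rat"` (free-text labels are allowed for toy
#'   physiologies).
#' @param body_weight_kg body weight in kg.
#' @param hematocrit red-cell volume fraction of blood.
#' @param gfr_l_h glomerular filtration rate in L/h.
#' @return an object of class `physiology`.
#' @export
physiology_table <- function(organs, species, body_weight_kg,
                             hematocrit = 0.45, gfr_l_h = 0) {
  needed <- c("organ", "volume_l", "flow_l_h", "f_plasma", "f_rbc",
              "f_interstitial", "f_intracellular", "f_water", "f_lipid")
  missing <- setdiff(needed, names(organs))
  if (length(missing))
    stop_config("physiology table lacks columns: %s",
                paste(missing, collapse = ", "))
  assert_that(!anyDuplicated(organs$organ), "duplicate organ labels")
  assert_that(all(organs$volume_l > 0), "all organ volumes must be > 0")
  assert_that(all(organs$flow_l_h >= 0), "organ blood flows must be >= 0")
  fr_sum <- with(organs, f_plasma + f_rbc + f_interstitial + f_intracellular)
  bad <- abs(fr_sum - 1) > 1e-9
  if (any(bad))
    stop_config("sub-compartment fractions do not sum to 1 for: %s",
                paste(organs$organ[bad], collapse = ", "))
  obj <- structure(organs,
                   species = species,
                   body_weight_kg = body_weight_kg,
                   hematocrit = hematocrit,
                   gfr_l_h = gfr_l_h,
                   class = c("physiology", "data.frame"))
  validate_physiology(obj)
  obj
}

# organs routed through the portal vein into the liver
splanchnic_organs <- function() c("gut", "spleen", "pancreas", "stomach")

# organs that are blood pools, not perfused tissue
blood_pools <- function() c("venous_blood", "arterial_blood")

#' Validate circulation consistency of a physiology table
#'
#' Checks that the sum of arterial tissue inflows equals the cardiac output
#' carried by the lung (when a lung is present), i.e. that what leaves the
#' arterial pool returns to the venous pool.
#'
#' @param phys a `physiology` object.
#' @return the object, invisibly; errors on inconsistency.
#' @export
validate_physiology <- function(phys) {
  tissue <- setdiff(phys$organ, c(blood_pools(), "lung"))
  q_out <- sum(phys$flow_l_h[phys$organ %in% tissue])
  if ("lung" %in% phys$organ) {
    q_lung <- phys$flow_l_h[phys$organ == "lung"]
    if (abs(q_lung - q_out) > 1e-9 * max(q_lung, 1))
      stop_config("cardiac output mismatch: lung carries %.6g L/h but tissues receive %.6g L/h",
                  q_lung, q_out)
  }
  invisible(phys)
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology: %s, %.3g kg, %d organs, GFR %.3g L/h, Hct %.2f>\n",
              attr(x, "species"), attr(x, "body_weight_kg"), nrow(x),
              attr(x, "gfr_l_h"), attr(x, "hematocrit")))
  print.data.frame(x, ...)
  invisible(x)
}

# Shared organ layout; volumes/flows differ per species. Sub-compartment
# fractions and water/lipid compositions are generic textbook values.
.organ_layout <- function() {
  data.frame(
    organ = c("lung", "brain", "heart", "kidney", "liver", "gut", "spleen",
              "pancreas", "stomach", "adipose", "muscle", "skin", "bone",
              "venous_blood", "arterial_blood"),
    f_plasma        = c(rep(0.04, 13), 0.55, 0.55),
    f_rbc           = c(rep(0.02, 13), 0.45, 0.45),
    f_interstitial  = c(0.30, 0.09, 0.14, 0.20, 0.16, 0.19, 0.21, 0.17,
                        0.19, 0.14, 0.13, 0.30, 0.10, 0, 0),
    f_intracellular = c(0.64, 0.85, 0.80, 0.74, 0.78, 0.75, 0.73, 0.77,
                        0.75, 0.80, 0.81, 0.64, 0.84, 0, 0),
    f_water = c(0.79, 0.77, 0.76, 0.78, 0.75, 0.75, 0.79, 0.66, 0.75,
                0.15, 0.76, 0.65, 0.45, 0.93, 0.93),
    f_lipid = c(0.02, 0.11, 0.04, 0.03, 0.05, 0.05, 0.02, 0.10, 0.05,
                0.80, 0.02, 0.10, 0.07, 0.004, 0.004),
    stringsAsFactors = FALSE)
}

#' Default whole-body physiologies
#'
#' Reference physiology tables for a 73 kg human and a 250 g rat: 15
#' compartments (13 perfused organs plus venous and arterial blood pools)
#' with representative organ volumes, regional blood flows, sub-compartment
#' fractions and tissue water/lipid compositions drawn from standard PBPK
#' physiology compilations. All values are overridable by constructing a
#' [physiology_table()] directly.
#'
#' @param species `"human"` or `"rat"`.
#' @return a `physiology` object.
#' @export
default_physiology <- function(species = c("human", "rat")) {
  species <- match.arg(species)
  lay <- .organ_layout()
  if (species == "human") {
    vol <- c(lung = 1.2, brain = 1.45, heart = 0.33, kidney = 0.31,
             liver = 1.8, gut = 1.1, spleen = 0.19, pancreas = 0.10,
             stomach = 0.15, adipose = 18, muscle = 29, skin = 3.4,
             bone = 10, venous_blood = 3.9, arterial_blood = 1.7)
    flw <- c(lung = 311, brain = 46, heart = 15, kidney = 66, liver = 19,
             gut = 54, spleen = 11, pancreas = 3, stomach = 3, adipose = 19,
             muscle = 45, skin = 19, bone = 11,
             venous_blood = 0, arterial_blood = 0)
    bw <- 73; gfr <- 7.5
  } else {
    co <- 4.8  # rat cardiac output, L/h
    frac <- c(lung = 1, brain = 0.148, heart = 0.048, kidney = 0.212,
              liver = 0.061, gut = 0.174, spleen = 0.035, pancreas = 0.010,
              stomach = 0.010, adipose = 0.061, muscle = 0.145,
              skin = 0.061, bone = 0.035,
              venous_blood = 0, arterial_blood = 0)
    flw <- frac * co
    vol <- c(lung = 0.0015, brain = 0.0017, heart = 0.0010, kidney = 0.0020,
             liver = 0.0092, gut = 0.0110, spleen = 0.0006,
             pancreas = 0.0013, stomach = 0.0011, adipose = 0.0250,
             muscle = 0.1220, skin = 0.0400, bone = 0.0150,
             venous_blood = 0.0115, arterial_blood = 0.0050)
    bw <- 0.25; gfr <- 0.08
  }
  lay$volume_l <- unname(vol[lay$organ])
  lay$flow_l_h <- unname(flw[lay$organ])
  physiology_table(lay, species = species, body_weight_kg = bw,
                   hematocrit = 0.45, gfr_l_h = gfr)
}

#' Reduced physiology for fast simulations
#'
#' A six-compartment physiology (lung, liver, gut, kidney, adipose plus the
#' two blood pools) preserving the default species' liver and kidney
#' volumes/flows, with the remaining tissues lumped into the adipose row.
#' Useful for quick dose searches and fitting studies where whole-body
#' detail is not needed.
#'
#' @param species `"human"` or `"rat"`.
#' @return a `physiology` object.
#' @export
reduced_physiology <- function(species = c("human", "rat")) {
  species <- match.arg(species)
  full <- default_physiology(species)
  keep <- c("lung", "liver", "gut", "kidney", "adipose",
            "venous_blood", "arterial_blood")
  ph <- full[full$organ %in% keep, , drop = FALSE]
  lumped <- setdiff(full$organ, c(keep, "lung"))
  extra_v <- sum(full$volume_l[full$organ %in% lumped])
  extra_q <- sum(full$flow_l_h[full$organ %in% setdiff(lumped, splanchnic_organs())])
  # splanchnic flow that no longer exists must leave cardiac output too
  lost_splanchnic <- sum(full$flow_l_h[full$organ %in%
                                         intersect(lumped, splanchnic_organs())])
  ph$volume_l[ph$organ == "adipose"] <-
    ph$volume_l[ph$organ == "adipose"] + extra_v
  ph$flow_l_h[ph$organ == "adipose"] <-
    ph$flow_l_h[ph$organ == "adipose"] + extra_q
  ph$flow_l_h[ph$organ == "lung"] <-
    ph$flow_l_h[ph$organ == "lung"] - lost_splanchnic
  rownames(ph) <- NULL
  physiology_table(as.data.frame(ph), species = species,
                   body_weight_kg = attr(full, "body_weight_kg"),
                   hematocrit = attr(full, "hematocrit"),
                   gfr_l_h = attr(full, "gfr_l_h"))
}

#' Degenerate single-compartment physiology
#'
#' Collapses the body to one well-stirred venous pool of the given volume.
#' Used for closed-form checks and simple fitting exercises: with a linear
#' clearance CL the model reduces to C(t) = (dose/V) exp(-CL/V * t).
#'
#' @param volume_l compartment volume in L.
#' @param body_weight_kg nominal body weight (used only for clearance
#'   scaling), default 73.
#' @return a `physiology` object with a single `venous_blood` organ.
#' @export
one_compartment_physiology <- function(volume_l, body_weight_kg = 73) {
  organs <- data.frame(organ = "venous_blood", volume_l = volume_l,
                       flow_l_h = 0, f_plasma = 1, f_rbc = 0,
                       f_interstitial = 0, f_intracellular = 0,
                       f_water = 0.93, f_lipid = 0.004,
                       stringsAsFactors = FALSE)
  physiology_table(organs, species = "one_compartment",
                   body_weight_kg = body_weight_kg, hematocrit = 0,
                   gfr_l_h = 0)
}

#' Read a physiology table from YAML or JSON
#'
#' The file must contain keys `species`, `body_weight_kg`, `hematocrit`,
#' `gfr_l_h` and an `organs` list of per-organ records matching the columns
#' of [physiology_table()].
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `physiology` object.
#' @export
read_physiology <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (k in c("species", "body_weight_kg", "organs"))
    if (is.null(raw[[k]])) stop_config("physiology file misses key '%s'", k)
  organs <- if (is.data.frame(raw$organs)) raw$organs else
    do.call(rbind, lapply(raw$organs, function(o) as.data.frame(o)))
  physiology_table(organs, species = raw$species,
                   body_weight_kg = raw$body_weight_kg,
                   hematocrit = raw$hematocrit %||% 0.45,
                   gfr_l_h = raw$gfr_l_h %||% 0)
}

#' Write a physiology table to YAML
#'
#' @param phys a `physiology` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(phys, path) {
  lst <- list(species = attr(phys, "species"),
              body_weight_kg = attr(phys, "body_weight_kg"),
              hematocrit = attr(phys, "hematocrit"),
              gfr_l_h = attr(phys, "gfr_l_h"),
              organs = lapply(seq_len(nrow(phys)), function(i)
                as.list(phys[i, , drop = FALSE])))
  yaml::write_yaml(lst, path)
  invisible(path)
}
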