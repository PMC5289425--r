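#' Organ/plasma partition coefficients
#'
#' Partition coefficients Kp give the equilibrium ratio of total tissue to
#' total plasma concentration per organ. The default calculation is a
#' tissue-composition method: the affinity of a compound for an organ is the
#' water fraction plus the lipid fraction weighted by the octanol/water
#' partition coefficient P = 10^logP, and the tissue/plasma ratio is scaled
#' by the plasma fraction unbound,
#'
#'   Kp(organ) = fu * (f_water(organ) + P * f_lipid(organ)) /
#'               (f_water(plasma) + P * f_lipid(plasma))
#'
#' with the plasma composition taken from the physiology's venous blood row.
#' This makes Kp = 1 for a logP 0, fu 1 compound in a water-only body,
#' monotone increasing in logP for lipid-rich organs such as adipose, and
#' proportional to fu. Alternative calculations can be registered under new
#' method labels.
#'
#' @param compound a [compound_properties()] object.
#' @param physiology a `physiology` object.
#' @param method registered calculation label; `"composition"` is shipped.
#' @return named numeric vector of Kp, one per organ (> 0).
#' @export
compute_partition_coefficients <- function(compound, physiology,
                                           method = "composition") {
  fun <- .kp_registry[[method]]
  if (is.null(fun))
    stop_config("unknown partition-coefficient method '%s' (registered: %s)",
                method, paste(names(.kp_registry), collapse = ", "))
  kp <- fun(compound, physiology)
  assert_that(all(kp > 0), "partition method '%s' produced non-positive Kp",
              method)
  kp
}

.kp_composition <- function(compound, physiology) {
  P <- 10^compound$logP
  fu <- compound$fraction_unbound
  ref <- if ("venous_blood" %in% physiology$organ)
    which(physiology$organ == "venous_blood")[1] else 1L
  denom <- physiology$f_water[ref] + P * physiology$f_lipid[ref]
  kp <- fu * (physiology$f_water + P * physiology$f_lipid) / denom
  names(kp) <- physiology$organ
  kp
}

.kp_registry <- new.env(parent = emptyenv())
assign("composition", .kp_composition, envir = .kp_registry)

#' Register a partition-coefficient calculation method
#'
#' @param name method label.
#' @param fun function of `(compound, physiology)` returning a named
#'   positive numeric vector of Kp per organ.
#' @return `name`, invisibly.
#' @export
register_partition_method <- function(name, fun) {
  assert_that(is.function(fun), "fun must be a function")
  assign(name, fun, envir = .kp_registry)
  invisible(name)
}
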