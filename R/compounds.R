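#' Compound physicochemistry
#'
#' A compound record holds the physicochemical properties the PBPK model
#' needs: molecular weight (g/mol), the octanol/water partition coefficient
#' logP, the fraction unbound in plasma fu, the acid/base character with its
#' pKa values, and water solubility (mg/L). Metabolites link to their parent
#' through `parent_id`.
#'
#' @param id short compound label.
#' @param molecular_weight molecular weight in g/mol, > 0.
#' @param logP octanol/water log partition coefficient (unitless).
#' @param fraction_unbound fraction unbound in plasma, in (0, 1].
#' @param compound_type one of `"acid"`, `"base"`, `"neutral"`,
#'   `"zwitterion"`.
#' @param pKa_values numeric vector of acid dissociation constants; must be
#'   empty for neutral compounds and hold at least two values for
#'   zwitterions.
#' @param water_solubility water solubility in mg/L, >= 0.
#' @param parent_id optional id of the parent drug for metabolites.
#' @return an object of class `compound_properties`.
#' @export
compound_properties <- function(id, molecular_weight, logP, fraction_unbound,
                                compound_type = c("neutral", "acid", "base",
                                                  "zwitterion"),
                                pKa_values = numeric(0),
                                water_solubility = Inf,
                                parent_id = NA_character_) {
  compound_type <- match.arg(compound_type)
  assert_that(is_scalar_number(molecular_weight) && molecular_weight > 0,
              "molecular_weight must be a positive number (got %s)",
              format(molecular_weight))
  assert_that(is_scalar_number(logP), "logP must be a finite number")
  assert_that(is_scalar_number(fraction_unbound) &&
                fraction_unbound > 0 && fraction_unbound <= 1,
              "fraction_unbound must lie in (0, 1]")
  assert_that(is.numeric(water_solubility) && water_solubility >= 0,
              "water_solubility must be >= 0")
  if (compound_type == "zwitterion")
    assert_that(length(pKa_values) >= 2L,
                "zwitterion '%s' requires at least two pKa values", id)
  if (compound_type == "neutral")
    assert_that(length(pKa_values) == 0L,
                "neutral compound '%s' must have no pKa values", id)
  structure(list(id = as.character(id),
                 molecular_weight = molecular_weight,
                 logP = logP,
                 fraction_unbound = fraction_unbound,
                 compound_type = compound_type,
                 pKa_values = as.numeric(pKa_values),
                 water_solubility = water_solubility,
                 parent_id = as.character(parent_id)),
            class = "compound_properties")
}

#' @export
print.compound_properties <- function(x, ...) {
  cat(sprintf("<compound %s>  MW %.2f g/mol  logP %.2f  fu %.4f  %s\n",
              x$id, x$molecular_weight, x$logP, x$fraction_unbound,
              x$compound_type))
  if (length(x$pKa_values))
    cat("  pKa:", paste(format(x$pKa_values), collapse = ", "), "\n")
  if (!is.na(x$parent_id)) cat("  metabolite of", x$parent_id, "\n")
  invisible(x)
}

#' Read a compound table from CSV
#'
#' Expected header: `id, parent_id, mw_g_mol, logp, fu, compound_type,
#' pka1, pka2, solubility_mg_l`. Empty `pka` cells mean "no such pKa".
#'
#' @param path CSV file path.
#' @return named list of [compound_properties()] objects.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "parent_id", "mw_g_mol", "logp", "fu", "compound_type",
              "pka1", "pka2", "solubility_mg_l")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_config("compound table %s lacks columns: %s", path,
                paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    pka <- c(df$pka1[i], df$pka2[i])
    pka <- suppressWarnings(as.numeric(pka))
    pka <- pka[is.finite(pka)]
    compound_properties(
      id = df$id[i],
      molecular_weight = df$mw_g_mol[i],
      logP = df$logp[i],
      fraction_unbound = df$fu[i],
      compound_type = df$compound_type[i],
      pKa_values = pka,
      water_solubility = df$solubility_mg_l[i],
      parent_id = if (is.na(df$parent_id[i]) || df$parent_id[i] == "")
        NA_character_ else df$parent_id[i])
  })
  names(out) <- df$id
  out
}

#' The shipped hepatotoxicant compound panel
#'
#' Loads the packaged physicochemistry table of the fifteen hepatotoxic
#' drugs and their major metabolites (acetaminophen, amiodarone,
#' azathioprine, cyclophosphamide, ciclosporin, diclofenac, erythromycin,
#' flutamide, haloperidol, isoniazid, phenobarbital, phenytoin, rifampicin,
#' simvastatin, valproic acid).
#'
#' @return named list of [compound_properties()] objects.
#' @export
hepatotoxicant_panel <- function() {
  path <- system.file("extdata", "compounds_hepatotoxicants.csv",
                      package = "picdtox", mustWork = TRUE)
  read_compound_table(path)
}
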