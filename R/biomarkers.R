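# Molecular biomarker identification and DDI prediction from toxic changes.
#
# Biomarker rules are evaluated per (process, timepoint) scope over a drug
# group: the unsubscripted grand mean and standard deviation are taken over
# all (gene, drug) toxic changes of that scope. A gene is a common
# biomarker for the whole group when its across-drug mean exceeds 1.5x the
# grand mean while its across-drug standard deviation stays below 0.5x the
# grand standard deviation (strict inequalities); it is an individual
# biomarker for a single drug when that drug's toxic change exceeds 7x the
# grand mean.

# iterate over (process, timepoint) scopes of a gene-level toxic-change
# table; fn(process, timepoint, sub) with sub = rows of that scope
.scope_apply <- function(toxic_changes, group, collection, processes, fn) {
  processes <- processes %||% names(collection$process_sets)
  tc <- toxic_changes[toxic_changes$drug %in% group, , drop = FALSE]
  out <- list()
  for (ps in processes) {
    members <- collection$process_sets[[ps]]
    sub_p <- tc[tc$entity %in% members, , drop = FALSE]
    for (tp in sort(unique(sub_p$time_h))) {
      sub <- sub_p[sub_p$time_h == tp, , drop = FALSE]
      res <- fn(ps, tp, sub)
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Identify common molecular biomarkers
#'
#' A gene is marked as a common biomarker of the drug group within a
#' (process, timepoint) scope when `mean_g > mean_mult * grand_mean` and
#' `sd_g < sd_mult * grand_sd`, with the across-drug gene statistics on
#' the left and the grand statistics over all (gene, drug) toxic changes
#' of the scope on the right (strict inequalities; defaults 1.5 and 0.5).
#'
#' @param toxic_changes gene-level `toxic_change_table` (columns `drug`,
#'   `entity`, `time_h`, `toxic_change`).
#' @param group the high-responsive drug group (>= 2 drugs).
#' @param collection a [gene_set_collection()] providing the process
#'   membership.
#' @param processes process names to scan (default: all in the
#'   collection; typically the selected perturbed processes).
#' @param mean_mult,sd_mult the two thresholds.
#' @return an object of class `biomarker_set` (kind `"common"`):
#'   data.frame with `gene`, `process`, `time_h`, `mean_toxic_change`,
#'   `sd_toxic_change`, `grand_mean`, `grand_sd`.
#' @export
identify_common_biomarkers <- function(toxic_changes, group, collection,
                                       processes = NULL,
                                       mean_mult = 1.5, sd_mult = 0.5) {
  assert_that(length(group) >= 2, "need >= 2 drugs in the group")
  res <- .scope_apply(toxic_changes, group, collection, processes,
    function(ps, tp, sub) {
      genes <- unique(sub$entity)
      if (length(genes) < 2) {
        warning(sprintf("scope (%s, %g h) has < 2 genes; skipped", ps, tp),
                call. = FALSE)
        return(NULL)
      }
      gm <- mean(sub$toxic_change)
      gs <- stats::sd(sub$toxic_change)
      mg <- tapply(sub$toxic_change, sub$entity, mean)
      sg <- tapply(sub$toxic_change, sub$entity, stats::sd)
      hit <- names(mg)[mg > mean_mult * gm & sg < sd_mult * gs]
      if (!length(hit)) return(NULL)
      data.frame(gene = hit, process = ps, time_h = tp,
                 mean_toxic_change = unname(mg[hit]),
                 sd_toxic_change = unname(sg[hit]),
                 grand_mean = gm, grand_sd = gs,
                 stringsAsFactors = FALSE)
    })
  if (is.null(res))
    res <- data.frame(gene = character(0), process = character(0),
                      time_h = numeric(0), mean_toxic_change = numeric(0),
                      sd_toxic_change = numeric(0), grand_mean = numeric(0),
                      grand_sd = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, kind = "common",
            thresholds = c(mean_mult = mean_mult, sd_mult = sd_mult),
            group = group,
            class = c("biomarker_set", "data.frame"))
}

#' Identify individual molecular biomarkers
#'
#' A gene is an individual biomarker for a single drug within a (process,
#' timepoint) scope when that drug's toxic change strictly exceeds
#' `multiplier` (default 7) times the scope's grand mean toxic change. A
#' gene may be an individual biomarker of several drugs.
#'
#' @inheritParams identify_common_biomarkers
#' @param multiplier the fold threshold over the grand mean.
#' @return an object of class `biomarker_set` (kind `"individual"`):
#'   data.frame with `gene`, `drug`, `process`, `time_h`, `toxic_change`,
#'   `grand_mean`.
#' @export
identify_individual_biomarkers <- function(toxic_changes, group, collection,
                                           processes = NULL,
                                           multiplier = 7) {
  res <- .scope_apply(toxic_changes, group, collection, processes,
    function(ps, tp, sub) {
      gm <- mean(sub$toxic_change)
      if (!is.finite(gm) || gm <= 0) {
        warning(sprintf("scope (%s, %g h) has non-positive grand mean; skipped",
                        ps, tp), call. = FALSE)
        return(NULL)
      }
      hit <- sub[sub$toxic_change > multiplier * gm, , drop = FALSE]
      if (!nrow(hit)) return(NULL)
      data.frame(gene = hit$entity, drug = hit$drug, process = ps,
                 time_h = tp, toxic_change = hit$toxic_change,
                 grand_mean = gm, stringsAsFactors = FALSE)
    })
  if (is.null(res))
    res <- data.frame(gene = character(0), drug = character(0),
                      process = character(0), time_h = numeric(0),
                      toxic_change = numeric(0), grand_mean = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, kind = "individual",
            thresholds = c(multiplier = multiplier), group = group,
            class = c("biomarker_set", "data.frame"))
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set (%s): %d entries, %d unique genes>\n",
              attr(x, "kind"), nrow(x), length(unique(x$gene))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Compare common-biomarker toxic changes between drug groups
#'
#' For every common biomarker, the toxic changes of the high-responsive
#' drugs are compared against the low-responsive drugs with a pooled
#' two-sample t-test, Benjamini-Hochberg adjusted across the biomarker
#' family; significance is flagged at adjusted p < 0.05.
#'
#' @param common a common `biomarker_set`.
#' @param toxic_changes gene-level `toxic_change_table` covering both
#'   groups.
#' @param low_group,high_group drug vectors (>= 2 each).
#' @param alpha significance level on the adjusted p, default 0.05.
#' @return the biomarker data.frame with `p_raw`, `p_adjusted` and
#'   `significant` columns appended (`NA` p where both groups are
#'   constant, with a warning).
#' @export
test_biomarker_sensitivity <- function(common, toxic_changes, low_group,
                                       high_group, alpha = 0.05) {
  assert_that(length(low_group) >= 2 && length(high_group) >= 2,
              "both groups need >= 2 drugs")
  p_raw <- vapply(seq_len(nrow(common)), function(i) {
    sub <- toxic_changes[toxic_changes$entity == common$gene[i] &
                           toxic_changes$time_h == common$time_h[i], ,
                         drop = FALSE]
    hi <- sub$toxic_change[sub$drug %in% high_group]
    lo <- sub$toxic_change[sub$drug %in% low_group]
    if (stats::sd(hi) == 0 && stats::sd(lo) == 0) {
      if (isTRUE(all.equal(mean(hi), mean(lo)))) return(1)
      warning(sprintf("biomarker %s: zero variance in both groups",
                      common$gene[i]), call. = FALSE)
      return(NA_real_)
    }
    stats::t.test(hi, lo, var.equal = TRUE)$p.value
  }, 0)
  out <- as.data.frame(common)
  out$p_raw <- p_raw
  out$p_adjusted <- stats::p.adjust(p_raw, method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

.canon_pairs <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Predict drug-drug interactions from shared individual biomarkers
#'
#' A potential DDI is assumed for every unordered drug pair sharing at
#' least one individual-biomarker gene. Shared biomarkers are ranked by
#' the absolute difference of the two drugs' toxic changes, ascending
#' (most similar toxic action first); per (drug, gene) the maximum toxic
#' change over its scopes is used. Each pair is annotated with whether any
#' shared biomarker belongs to the cytochrome P450 functional class.
#'
#' @param individual an individual `biomarker_set`.
#' @param drugs the drug group over which pairs are formed.
#' @param collection optional [gene_set_collection()] supplying functional
#'   classes for the CYP annotation.
#' @return data.frame of predicted pairs (`drug_a`, `drug_b`,
#'   `n_shared`, `shared_genes` (comma-joined, ranked), `has_cyp`), with
#'   attribute `ranked` holding the per-pair rank tables.
#' @export
predict_ddis <- function(individual, drugs, collection = NULL) {
  bm <- as.data.frame(individual)
  bm <- bm[bm$drug %in% drugs, , drop = FALSE]
  tc_max <- tapply(bm$toxic_change, paste(bm$drug, bm$gene, sep = "\r"),
                   max)
  gene_drugs <- split(bm$drug, bm$gene) |> lapply(unique)
  classes <- if (!is.null(collection)) collection$functional_classes
  pairs <- list(); ranked <- list()
  dd <- sort(unique(drugs))
  for (i in seq_along(dd)) for (j in seq_len(i - 1L)) {
    a <- dd[j]; b <- dd[i]
    shared <- names(gene_drugs)[vapply(gene_drugs, function(g)
      a %in% g && b %in% g, TRUE)]
    if (!length(shared)) next
    delta <- abs(tc_max[paste(a, shared, sep = "\r")] -
                   tc_max[paste(b, shared, sep = "\r")])
    ord <- order(delta, shared)  # ascending |difference|, ties by gene
    rk <- data.frame(gene = shared[ord], abs_difference = unname(delta[ord]),
                     stringsAsFactors = FALSE)
    has_cyp <- !is.null(classes) &&
      any(classes[shared] == "cytochrome P450", na.rm = TRUE)
    key <- paste(a, b, sep = " ~ ")
    ranked[[key]] <- rk
    pairs[[key]] <- data.frame(drug_a = a, drug_b = b,
                               n_shared = length(shared),
                               shared_genes = paste(rk$gene, collapse = ","),
                               has_cyp = has_cyp, stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(drug_a = character(0), drug_b = character(0),
               n_shared = integer(0), shared_genes = character(0),
               has_cyp = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ranked") <- ranked
  out
}

#' Evaluate DDI predictions against a reference
#'
#' Confusion counts over all unordered pairs of the drug group, and the
#' derived accuracy (TP+TN)/(TP+FP+TN+FN), sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP) and precision TP/(TP+FP). Ratios with a zero
#' denominator are reported as `NA` with a warning, never coerced to 0.
#'
#' @param predicted data.frame with `drug_a`, `drug_b` (or 2-column
#'   matrix) of predicted pairs.
#' @param reference data.frame with `drug_a`, `drug_b` of known DDI pairs;
#'   must be pairs of the group.
#' @param drugs the drug group.
#' @return an object of class `ddi_evaluation`.
#' @export
evaluate_ddi_predictions <- function(predicted, reference, drugs) {
  get_pairs <- function(x, what) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)))
      return(character(0))
    a <- x[[1]]; b <- x[[2]]
    if (!is.null(x$drug_a)) { a <- x$drug_a; b <- x$drug_b }
    assert_that(all(c(a, b) %in% drugs),
                "%s pairs contain drugs outside the group", what)
    assert_that(all(a != b), "%s pairs contain self-pairs", what)
    keys <- .canon_pairs(a, b)
    if (anyDuplicated(keys))
      stop_config("duplicate pairs in %s set", what)
    keys
  }
  pred <- get_pairs(predicted, "predicted")
  ref <- get_pairs(reference, "reference")
  dd <- sort(unique(drugs))
  all_pairs <- utils::combn(dd, 2)
  keys <- .canon_pairs(all_pairs[1, ], all_pairs[2, ])
  p <- keys %in% pred
  r <- keys %in% ref
  tp <- sum(p & r); fp <- sum(p & !r); fn <- sum(!p & r); tn <- sum(!p & !r)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 n_pairs = length(keys),
                 accuracy = ratio(tp + tn, tp + fp + tn + fn, "accuracy"),
                 sensitivity = ratio(tp, tp + fn, "sensitivity"),
                 specificity = ratio(tn, tn + fp, "specificity"),
                 precision = ratio(tp, tp + fp, "precision")),
            class = "ddi_evaluation")
}

#' @export
print.ddi_evaluation <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<ddi_evaluation: TP %d, FP %d, TN %d, FN %d (of %d pairs)>\n",
              x$TP, x$FP, x$TN, x$FN, x$n_pairs))
  cat(sprintf("  accuracy %s  sensitivity %s  specificity %s  precision %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$precision)))
  invisible(x)
}

#' Threshold robustness sweep for biomarker counts
#'
#' Re-identifies common and individual biomarkers with each threshold
#' perturbed by the given relative deltas (default plus/minus 5 percent)
#' and reports the percent change in biomarker counts versus the baseline
#' thresholds.
#'
#' @inheritParams identify_common_biomarkers
#' @param deltas relative perturbations, default `c(-0.05, 0.05)`.
#' @param multiplier baseline individual-biomarker multiplier.
#' @return data.frame with `threshold`, `baseline_value`, `delta`,
#'   `value`, `count`, `baseline_count`, `pct_change`.
#' @export
sweep_thresholds <- function(toxic_changes, group, collection,
                             processes = NULL, deltas = c(-0.05, 0.05),
                             mean_mult = 1.5, sd_mult = 0.5,
                             multiplier = 7) {
  n_common <- function(mm, sm)
    length(unique(identify_common_biomarkers(
      toxic_changes, group, collection, processes, mm, sm)$gene))
  n_indiv <- function(m) {
    bm <- identify_individual_biomarkers(toxic_changes, group, collection,
                                         processes, m)
    nrow(unique(as.data.frame(bm)[, c("gene", "drug")]))
  }
  base_c <- n_common(mean_mult, sd_mult)
  base_i <- n_indiv(multiplier)
  rows <- list()
  add <- function(threshold, base_val, delta, val, count, base_count) {
    rows[[length(rows) + 1L]] <<- data.frame(
      threshold = threshold, baseline_value = base_val, delta = delta,
      value = val, count = count, baseline_count = base_count,
      pct_change = if (base_count > 0)
        100 * (count - base_count) / base_count else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (d in deltas) {
    add("common_mean_mult", mean_mult, d, mean_mult * (1 + d),
        n_common(mean_mult * (1 + d), sd_mult), base_c)
    add("common_sd_mult", sd_mult, d, sd_mult * (1 + d),
        n_common(mean_mult, sd_mult * (1 + d)), base_c)
    add("individual_mult", multiplier, d, multiplier * (1 + d),
        n_indiv(multiplier * (1 + d)), base_i)
  }
  do.call(rbind, rows)
}
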