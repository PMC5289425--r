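#' Gene response level
#'
#' The response level of a gene is the absolute log2 fold change of its
#' expression versus control.
#'
#' @param log2fc signed log2 fold change(s).
#' @return `abs(log2fc)`.
#' @export
gene_response_level <- function(log2fc) {
  assert_that(all(is.finite(log2fc)), "log2fc must be finite")
  abs(log2fc)
}

#' Gene set collection
#'
#' Holds the named process gene sets (the toxicity lists standing for key
#' cellular processes), the functional class of each gene and the measured
#' universe. Set members outside the universe are dropped at load time and
#' counted.
#'
#' @param process_sets named list of character vectors.
#' @param functional_classes named character vector gene -> class label;
#'   allowed labels: kinase, transcription regulator, enzyme, transporter,
#'   growth factor, ligand-dependent nuclear receptor, peptidase,
#'   phosphatase, cytochrome P450, other.
#' @param universe character vector of all measured genes.
#' @return an object of class `gene_set_collection` with a `dropped`
#'   count attribute per set.
#' @export
gene_set_collection <- function(process_sets, functional_classes = NULL,
                                universe) {
  assert_that(!is.null(names(process_sets)) &&
                !anyDuplicated(names(process_sets)),
              "process sets must have unique names")
  allowed <- c("kinase", "transcription regulator", "enzyme", "transporter",
               "growth factor", "ligand-dependent nuclear receptor",
               "peptidase", "phosphatase", "cytochrome P450", "other")
  if (!is.null(functional_classes)) {
    bad <- setdiff(unique(functional_classes), allowed)
    assert_that(length(bad) == 0,
                "unknown functional class label(s): %s",
                paste(bad, collapse = ", "))
  }
  dropped <- vapply(process_sets, function(s)
    sum(!s %in% universe), 0L)
  if (any(dropped > 0))
    message(sprintf("dropped %d gene-set member(s) outside the universe",
                    sum(dropped)))
  process_sets <- lapply(process_sets, intersect, y = universe)
  structure(list(process_sets = process_sets,
                 functional_classes = functional_classes,
                 universe = universe),
            dropped = dropped,
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$process_sets)
  cat(sprintf("<gene_set_collection: %d sets (size %d-%d), universe %d genes%s>\n",
              length(x$process_sets), min(sizes), max(sizes),
              length(x$universe),
              if (!is.null(x$functional_classes)) ", with classes" else ""))
  invisible(x)
}

#' Aggregate gene responses to processes or functional classes
#'
#' The response of a process is the arithmetic mean response of its member
#' genes present in the data; genes absent from the data are excluded and
#' reported in the coverage attribute. With `by_class = TRUE` the mean is
#' additionally taken per functional class within each process.
#'
#' @param gene_responses data.frame with columns `gene`, `response`, and
#'   any grouping columns (e.g. `drug`, `time_h`) which are preserved.
#' @param collection a [gene_set_collection()].
#' @param by_class aggregate per (process, functional class) instead of per
#'   process.
#' @return data.frame with `entity` (process or "process|class"), the
#'   preserved grouping columns, and the mean `response`; attribute
#'   `coverage` reports per-process measured/total member counts.
#' @export
aggregate_response <- function(gene_responses, collection,
                               by_class = FALSE) {
  assert_that(all(c("gene", "response") %in% names(gene_responses)),
              "gene_responses needs 'gene' and 'response' columns")
  grp_cols <- setdiff(names(gene_responses), c("gene", "response"))
  measured <- unique(gene_responses$gene)
  out <- list()
  coverage <- list()
  for (ps in names(collection$process_sets)) {
    members <- collection$process_sets[[ps]]
    present <- intersect(members, measured)
    coverage[[ps]] <- c(measured = length(present),
                        total = length(members))
    if (!length(present)) {
      warning(sprintf("process '%s' has no measured member genes", ps),
              call. = FALSE)
      next
    }
    sub <- gene_responses[gene_responses$gene %in% present, , drop = FALSE]
    if (by_class) {
      cls <- collection$functional_classes[sub$gene]
      cls[is.na(cls)] <- "other"
      sub$entity <- paste(ps, cls, sep = "|")
    } else sub$entity <- ps
    agg <- stats::aggregate(sub$response,
                            by = c(list(entity = sub$entity),
                                   lapply(grp_cols, function(g) sub[[g]])),
                            FUN = mean)
    names(agg) <- c("entity", grp_cols, "response")
    out[[ps]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "coverage") <- do.call(rbind, coverage)
  res
}

#' Toxic change between toxic and therapeutic responses
#'
#' The toxic change of an entity at a timepoint is the predicted in vivo
#' response at the toxic dose minus the response at the therapeutic dose.
#' Values are not clamped; negative toxic changes are preserved and
#' counted in the `n_negative` attribute (on the study data all toxic
#' changes were positive, which is checked downstream as a report, not
#' enforced).
#'
#' @param therapeutic,toxic `contextualized_response` objects (or
#'   data.frames with `entity`, `time_h`, `response`) on the same index.
#' @return an object of class `toxic_change_table`: data.frame with
#'   `drug`, `entity`, `time_h`, `toxic_change`.
#' @export
compute_toxic_change <- function(therapeutic, toxic) {
  drug <- NA_character_
  if (inherits(therapeutic, "contextualized_response")) {
    drug <- therapeutic$compound_id
    therapeutic <- therapeutic$response
  }
  if (inherits(toxic, "contextualized_response")) {
    drug <- toxic$compound_id
    toxic <- toxic$response
  }
  key_a <- paste(therapeutic$entity, therapeutic$time_h)
  key_b <- paste(toxic$entity, toxic$time_h)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b))
    stop_config("therapeutic and toxic responses have mismatched indices")
  m <- match(key_a, key_b)
  out <- data.frame(drug = drug, entity = therapeutic$entity,
                    time_h = therapeutic$time_h,
                    toxic_change = toxic$response[m] - therapeutic$response,
                    stringsAsFactors = FALSE)
  structure(out, n_negative = sum(out$toxic_change < 0),
            class = c("toxic_change_table", "data.frame"))
}

#' Hypergeometric over-representation analysis
#'
#' For each drug, the overlap of its responding genes with each process set
#' is tested with the one-sided hypergeometric tail probability
#' P(X >= overlap), and Benjamini-Hochberg adjusted across processes within
#' that drug.
#'
#' @param responding_genes named list: per drug, the character vector of
#'   responding genes (subset of the universe).
#' @param collection a [gene_set_collection()].
#' @return data.frame with `drug`, `process`, `overlap`, `set_size`,
#'   `n_responding`, `p_raw`, `p_adjusted`.
#' @export
overrepresentation_analysis <- function(responding_genes, collection) {
  uni <- collection$universe
  assert_that(length(uni) > 0, "empty universe")
  out <- list()
  for (drug in names(responding_genes)) {
    resp <- intersect(responding_genes[[drug]], uni)
    rows <- lapply(names(collection$process_sets), function(ps) {
      set <- collection$process_sets[[ps]]
      k <- length(intersect(resp, set))
      # P(X >= k) for X ~ Hypergeom(universe, set, draws = responders)
      p <- stats::phyper(k - 1, length(set), length(uni) - length(set),
                         length(resp), lower.tail = FALSE)
      data.frame(drug = drug, process = ps, overlap = k,
                 set_size = length(set), n_responding = length(resp),
                 p_raw = p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$p_adjusted <- stats::p.adjust(df$p_raw, method = "BH")
    out[[drug]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default responder criterion
#'
#' A gene responds for a drug at a timepoint if its absolute log2 fold
#' change reaches `threshold` at any concentration level of that
#' timepoint; a gene responds for the drug if it responds at any
#' timepoint.
#'
#' @param responses data.frame with `drug`, `gene`, `log2fc` (signed or
#'   absolute) and optionally `level`/`time_h` columns.
#' @param threshold absolute log2FC cutoff, default 1.
#' @return named list per drug of responding gene vectors.
#' @export
responding_genes <- function(responses, threshold = 1) {
  hit <- responses[abs(responses$log2fc) >= threshold, , drop = FALSE]
  split(hit$gene, hit$drug) |> lapply(unique)
}

#' Select key cellular processes across drugs
#'
#' A process is a key process when it is significantly overrepresented
#' (adjusted p below `alpha`) in at least `ceiling(n_drugs * fraction)`
#' drugs, irrespective of the timepoint.
#'
#' @param ora_results output of [overrepresentation_analysis()] (may pool
#'   several timepoints; a drug counts once however many timepoints are
#'   significant).
#' @param n_drugs total number of drugs considered.
#' @param fraction required fraction of drugs, default 1/3.
#' @param alpha adjusted-p threshold, default 0.01.
#' @return character vector of selected process names (sorted).
#' @export
select_key_processes <- function(ora_results, n_drugs, fraction = 1/3,
                                 alpha = 0.01) {
  need <- ceiling(n_drugs * fraction)
  sig <- ora_results[ora_results$p_adjusted < alpha, , drop = FALSE]
  counts <- tapply(sig$drug, sig$process, function(d) length(unique(d)))
  sort(names(counts)[!is.na(counts) & counts >= need])
}

#' Select processes perturbed by a drug group
#'
#' A process is perturbed at a timepoint when its mean toxic change over
#' the group reaches `threshold` (default 10 percent, i.e. 0.10 in
#' absolute log2FC units). The exclusivity report states whether any
#' process also passes in the complementary drug group.
#'
#' @param toxic_changes a `toxic_change_table` (process-level entities).
#' @param group character vector of drugs defining the group.
#' @param threshold mean toxic change cutoff, default 0.10.
#' @param complement_group optional complementary drug group for the
#'   exclusivity report.
#' @return named list of per-timepoint process vectors, with attribute
#'   `exclusivity` (data.frame of complementary-group passes, if any).
#' @export
select_perturbed_processes <- function(toxic_changes, group,
                                       threshold = 0.10,
                                       complement_group = NULL) {
  assert_that(length(group) > 0, "empty drug group")
  assert_that(all(group %in% toxic_changes$drug),
              "group drugs missing from the toxic-change table")
  pick <- function(drugs) {
    sub <- toxic_changes[toxic_changes$drug %in% drugs, , drop = FALSE]
    agg <- stats::aggregate(toxic_change ~ entity + time_h, data = sub,
                            FUN = mean)
    agg[agg$toxic_change >= threshold, , drop = FALSE]
  }
  sel <- pick(group)
  out <- lapply(split(sel$entity, sel$time_h), function(e) sort(unique(e)))
  excl <- NULL
  if (!is.null(complement_group) && length(complement_group)) {
    excl <- pick(complement_group)
    if (nrow(excl))
      warning(sprintf("%d process/timepoint entries also pass in the complementary group",
                      nrow(excl)), call. = FALSE)
  }
  structure(out, exclusivity = excl)
}

#' Validate predicted response profiles against observations
#'
#' Predicted time profiles are linearly interpolated to the observation
#' times (3, 6, 9, 24 h by default); agreement is summarized by the
#' Pearson correlation r, the coefficient of determination R^2 = r^2 and
#' the 95 percent confidence interval of r via the Fisher z-transform.
#'
#' @param predicted data.frame with `time_h` and `response` (one profile,
#'   or pre-matched pairs if `observed_times` is `NULL`).
#' @param observed numeric vector of observed values at `match_times`.
#' @param match_times observation times in h.
#' @return list with `r`, `R_squared`, `ci_95` and the interpolated
#'   `predicted` values.
#' @export
validate_against_observations <- function(predicted, observed,
                                          match_times = c(3, 6, 9, 24)) {
  pred <- stats::approx(predicted$time_h, predicted$response,
                        xout = match_times)$y
  assert_that(!anyNA(pred), "match times outside the predicted support")
  assert_that(length(pred) == length(observed) && length(pred) >= 3,
              "need at least 3 paired points")
  assert_that(stats::sd(pred) > 0 && stats::sd(observed) > 0,
              "zero variance in predicted or observed values")
  r <- stats::cor(pred, observed)
  n <- length(pred)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + stats::qnorm(c(0.025, 0.975)) * se)
  list(r = r, R_squared = r^2, ci_95 = ci, predicted = pred)
}
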