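# End-to-end study driver: PBPK simulation -> PICD contextualization ->
# toxic changes -> process selection -> clustering -> biomarkers -> DDI
# evaluation -> differential pathways.

# default linear clearances (ml/h/kg) giving plausible exposure decay for
# the synthetic drug models
.DEFAULT_HEPATIC_CL <- 50
.DEFAULT_RENAL_CL <- 20

#' Build a simple PBPK model for one panel drug
#'
#' Parent compound only, reduced physiology, default linear hepatic and
#' renal clearances; used by the pipeline for dose-exposure matching.
#'
#' @param compound a [compound_properties()].
#' @param physiology a `physiology` (default [reduced_physiology()]).
#' @param hepatic_cl,renal_cl plasma clearances, ml/h/kg.
#' @return a `pbpk_model`.
#' @export
drug_model <- function(compound, physiology = reduced_physiology("human"),
                       hepatic_cl = .DEFAULT_HEPATIC_CL,
                       renal_cl = .DEFAULT_RENAL_CL) {
  pbpk_model(list(compound), physiology,
             clearances = stats::setNames(
               list(clearance_spec(renal_plasma_clearance = renal_cl,
                                   hepatic_plasma_clearance = hepatic_cl)),
               compound$id))
}

# small deterministic pathway graph over one process's genes: a ring plus
# seeded chords, standing in for a curated signaling topology
.synthetic_pathway <- function(collection, process, seed) {
  members <- sort(collection$process_sets[[process]])
  n <- length(members)
  set.seed(seed)
  edges <- data.frame(source = members, target = members[c(2:n, 1)],
                      interaction = "activates",
                      stringsAsFactors = FALSE)
  n_extra <- max(2L, n %/% 3L)
  from <- sample(members, n_extra, replace = TRUE)
  to <- sample(members, n_extra, replace = TRUE)
  keep <- from != to
  if (any(keep))
    edges <- rbind(edges, data.frame(source = from[keep],
                                     target = to[keep],
                                     interaction = "inhibits",
                                     stringsAsFactors = FALSE))
  pathway_graph(unique(edges), name = process)
}

#' Run the full comparative hepatotoxicity pipeline
#'
#' Executes the complete study on synthetic (or file-supplied) inputs:
#' per-drug PBPK dose-response maps via liver-interstitial AUC matching,
#' contextualized therapeutic and toxic responses, gene- and process-level
#' toxic changes, over-representation-based key-process selection, Ward
#' clustering of drugs into high/low-responsive groups, perturbed-process
#' selection, common and individual biomarker identification, DDI
#' prediction and evaluation, a threshold robustness sweep, and a
#' differential response pathway for the two strongest responders.
#' Deterministic for a fixed config/seed; with `out_dir` set, every
#' intermediate is written as CSV/TSV plus a JSON run manifest.
#'
#' @param config optional `study_config` from [load_study_config()].
#' @param spec optional [synthetic_study_spec()] (overrides
#'   `config$synthetic`).
#' @param seed root seed (overrides the config seed).
#' @param out_dir output directory (overrides the config).
#' @return an object of class `picd_study` with all stage results.
#' @export
run_pipeline <- function(config = NULL, spec = NULL, seed = NULL,
                         out_dir = NULL) {
  thr <- if (!is.null(config)) config$thresholds else
    list(alpha = 0.01, key_process_fraction = 1/3, perturbation = 0.10,
         responder_log2fc = 1, common_mean_mult = 1.5, common_sd_mult = 0.5,
         individual_mult = 7, differential = 0.15, biomarker_alpha = 0.05)
  seed <- seed %||% (if (!is.null(config)) config$seed else 1L)
  out_dir <- out_dir %||% (if (!is.null(config)) config$out_dir)
  if (is.null(spec)) {
    syn_args <- if (!is.null(config)) config$synthetic else list()
    syn_args$seed <- syn_args$seed %||% seed
    spec <- do.call(synthetic_study_spec, syn_args)
  }
  paths <- if (!is.null(config)) config$paths else list()

  stage <- "generate inputs"
  res <- tryCatch({
    collection <- if (!is.null(paths$gene_sets)) {
      sets <- read_gmt(paths$gene_sets)
      classes <- if (!is.null(paths$classes))
        read_gene_classes(paths$classes)
      gene_set_collection(sets, classes,
                          universe = unique(unlist(sets)))
    } else generate_gene_sets(spec)
    if (!is.null(paths$responses)) {
      responses <- read_response_table(paths$responses)
      manifest_truth <- NULL
    } else {
      ds <- generate_expression_dataset(spec, collection)
      responses <- ds$responses
      collection <- ds$collection
      manifest_truth <- ds$manifest
    }
    panel <- if (!is.null(paths$compounds))
      read_compound_table(paths$compounds)
    else generate_compound_panel(spec)
    drugs <- sort(unique(responses$drug))
    assert_that(all(drugs %in% names(panel)),
                "compound table misses drugs: %s",
                paste(setdiff(drugs, names(panel)), collapse = ", "))

    stage <- "PICD contextualization"
    phys <- reduced_physiology("human")
    tc_gene <- list()
    dose_table <- list()
    for (drug in drugs) {
      model <- drug_model(panel[[drug]], phys)
      sub <- responses[responses$drug == drug, , drop = FALSE]
      lv <- c("low", "mid", "high")
      conc <- vapply(lv, function(l)
        unique(sub$conc_um[sub$level == l])[1], 0)
      exposures <- lapply(lv, function(l)
        in_vitro_exposure(drug, conc[[l]], duration = 24,
                          timepoints_measured = sort(unique(sub$time_h))))
      names(exposures) <- lv
      resp_df <- data.frame(entity = sub$gene, level = sub$level,
                            time_h = sub$time_h,
                            response = gene_response_level(sub$log2fc),
                            stringsAsFactors = FALSE)
      map <- build_dose_response_map(model, exposures, resp_df,
                                     route = "iv")
      d_ther <- map$anchors$dose_mg[map$anchors$level == "low"]
      d_tox <- map$anchors$dose_mg[map$anchors$level == "high"]
      ther <- contextualize_response(map, d_ther, "therapeutic")
      tox <- contextualize_response(map, d_tox, "toxic")
      tc_gene[[drug]] <- compute_toxic_change(ther, tox)
      dose_table[[drug]] <- data.frame(drug = drug,
                                       therapeutic_mg = d_ther,
                                       toxic_mg = d_tox,
                                       stringsAsFactors = FALSE)
    }
    tc_gene <- do.call(rbind, tc_gene)
    rownames(tc_gene) <- NULL
    class(tc_gene) <- c("toxic_change_table", "data.frame")
    dose_table <- do.call(rbind, dose_table)
    rownames(dose_table) <- NULL

    stage <- "toxic-change aggregation"
    tc_proc_raw <- aggregate_response(
      data.frame(gene = tc_gene$entity, drug = tc_gene$drug,
                 time_h = tc_gene$time_h, response = tc_gene$toxic_change,
                 stringsAsFactors = FALSE),
      collection)
    tc_proc <- data.frame(drug = tc_proc_raw$drug,
                          entity = tc_proc_raw$entity,
                          time_h = tc_proc_raw$time_h,
                          toxic_change = tc_proc_raw$response,
                          stringsAsFactors = FALSE)
    class(tc_proc) <- c("toxic_change_table", "data.frame")

    stage <- "over-representation analysis"
    responders <- responding_genes(responses, thr$responder_log2fc)
    for (d in setdiff(drugs, names(responders)))
      responders[[d]] <- character(0)
    ora <- overrepresentation_analysis(responders, collection)
    key_processes <- select_key_processes(ora, n_drugs = length(drugs),
                                          fraction = thr$key_process_fraction,
                                          alpha = thr$alpha)

    stage <- "clustering"
    tc_key <- tc_proc[tc_proc$entity %in% key_processes, , drop = FALSE]
    mat <- stats::xtabs(toxic_change ~ paste(entity, time_h, sep = "@")
                        + drug, data = tc_key)
    mat <- matrix(mat, nrow = nrow(mat), dimnames = dimnames(mat))
    norm <- normalize_rows(mat)
    clus <- hierarchical_cluster(norm, axis = "columns", k = 2)
    col_means <- colMeans(mat)
    g1 <- names(clus$labels)[clus$labels == 1]
    g2 <- names(clus$labels)[clus$labels == 2]
    if (mean(col_means[g1]) >= mean(col_means[g2])) {
      high_group <- sort(g1); low_group <- sort(g2)
    } else {
      high_group <- sort(g2); low_group <- sort(g1)
    }

    stage <- "perturbed-process selection"
    perturbed <- select_perturbed_processes(tc_key, high_group,
                                            threshold = thr$perturbation,
                                            complement_group = low_group)

    stage <- "biomarker identification"
    common <- identify_common_biomarkers(tc_gene, high_group, collection,
                                         processes = key_processes,
                                         mean_mult = thr$common_mean_mult,
                                         sd_mult = thr$common_sd_mult)
    common_tested <- test_biomarker_sensitivity(common, tc_gene,
                                                low_group, high_group,
                                                alpha = thr$biomarker_alpha)
    individual <- identify_individual_biomarkers(
      tc_gene, high_group, collection, processes = key_processes,
      multiplier = thr$individual_mult)
    sweep <- sweep_thresholds(tc_gene, high_group, collection,
                              processes = key_processes,
                              mean_mult = thr$common_mean_mult,
                              sd_mult = thr$common_sd_mult,
                              multiplier = thr$individual_mult)

    stage <- "DDI prediction"
    ddi_predicted <- predict_ddis(individual, high_group, collection)
    ddi_reference <- if (!is.null(paths$reference_ddis))
      read_reference_ddis(paths$reference_ddis)
    else generate_reference_ddis(spec, ddi_predicted, high_group)
    ddi_eval <- evaluate_ddi_predictions(ddi_predicted, ddi_reference,
                                         high_group)

    stage <- "differential pathways"
    tot <- tapply(tc_gene$toxic_change[tc_gene$drug %in% high_group],
                  tc_gene$drug[tc_gene$drug %in% high_group], sum)
    top2 <- names(sort(tot, decreasing = TRUE))[1:2]
    focus_proc <- if (length(perturbed)) {
      tps <- names(perturbed)
      perturbed[[tps[length(tps)]]][1]
    } else key_processes[1]
    graph <- .synthetic_pathway(collection, focus_proc,
                                fork_seed(spec$seed, "pathway"))
    genes_in <- collection$process_sets[[focus_proc]]
    deltas <- pairwise_difference(tc_gene, top2[1], top2[2],
                                  genes = genes_in)
    classification <- classify_genes(deltas,
                                     diff_threshold = thr$differential,
                                     high_threshold = thr$differential)
    diff_pathway <- build_differential_response_pathway(classification,
                                                        graph, 24)

    list(spec = spec, thresholds = thr, seed = seed, drugs = drugs,
         collection = collection, responses = responses,
         dose_table = dose_table, toxic_changes_gene = tc_gene,
         toxic_changes_process = tc_proc, ora = ora,
         key_processes = key_processes, cluster = clus,
         high_group = high_group, low_group = low_group,
         perturbed_processes = perturbed, common_biomarkers = common_tested,
         individual_biomarkers = individual, threshold_sweep = sweep,
         ddi_predicted = ddi_predicted, ddi_reference = ddi_reference,
         ddi_evaluation = ddi_eval,
         differential = list(drugs = top2, process = focus_proc,
                             classification = classification,
                             graph = graph, subgraph = diff_pathway),
         manifest = manifest_truth)
  }, error = function(e) {
    stop_config("pipeline aborted at stage '%s': %s", stage,
                conditionMessage(e))
  })
  res <- structure(res, class = "picd_study")
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

#' @export
print.picd_study <- function(x, ...) {
  cat("<picd_study>\n")
  cat(sprintf("  drugs: %d (%d high-responsive: %s)\n", length(x$drugs),
              length(x$high_group), paste(x$high_group, collapse = ", ")))
  cat(sprintf("  key processes: %d; common biomarkers: %d; individual biomarker entries: %d\n",
              length(x$key_processes),
              length(unique(x$common_biomarkers$gene)),
              nrow(x$individual_biomarkers)))
  print(x$ddi_evaluation)
  invisible(x)
}

#' Write every pipeline intermediate to an output directory
#'
#' CSV/TSV tables for each stage plus a JSON run manifest (seed, spec,
#' thresholds, package version). Re-running the pipeline with the same
#' config reproduces byte-identical files.
#'
#' @param study a `picd_study`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_stage_table(study$dose_table, p("dose_table.csv"), "picd")
  write_stage_table(as.data.frame(study$toxic_changes_gene),
                    p("toxic_changes_gene.csv"), "toxic-change")
  write_stage_table(as.data.frame(study$toxic_changes_process),
                    p("toxic_changes_process.csv"), "toxic-change")
  write_stage_table(study$ora, p("overrepresentation.csv"), "ora")
  write_stage_table(data.frame(process = study$key_processes),
                    p("key_processes.csv"), "ora")
  write_stage_table(data.frame(drug = names(study$cluster$labels),
                               cluster = unname(study$cluster$labels),
                               group = ifelse(names(study$cluster$labels)
                                              %in% study$high_group,
                                              "high", "low")),
                    p("clusters.csv"), "clustering")
  writeLines(study$cluster$newick, p("dendrogram.newick"))
  write_stage_table(as.data.frame(study$common_biomarkers),
                    p("common_biomarkers.csv"), "biomarkers")
  write_stage_table(as.data.frame(study$individual_biomarkers),
                    p("individual_biomarkers.csv"), "biomarkers")
  write_stage_table(study$threshold_sweep, p("threshold_sweep.csv"),
                    "biomarkers")
  write_stage_table(study$ddi_predicted, p("ddi_predicted.csv"), "ddi")
  write_stage_table(study$ddi_reference, p("ddi_reference.csv"), "ddi")
  ev <- study$ddi_evaluation
  write_stage_table(data.frame(TP = ev$TP, FP = ev$FP, TN = ev$TN,
                               FN = ev$FN, accuracy = ev$accuracy,
                               sensitivity = ev$sensitivity,
                               specificity = ev$specificity,
                               precision = ev$precision),
                    p("ddi_evaluation.csv"), "ddi")
  write_stage_table(as.data.frame(study$differential$classification),
                    p("differential_classification.csv"), "diffpath")
  write_pathway_graph(study$differential$subgraph,
                      p("differential_pathway.graphml"))
  manifest <- list(seed = study$seed,
                   thresholds = study$thresholds,
                   spec = unclass(study$spec),
                   package_version =
                     as.character(utils::packageVersion("picdtox")),
                   drugs = study$drugs, high_group = study$high_group)
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
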