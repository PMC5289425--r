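# Seeded synthetic study generator.
#
# Emulates the statistical structure of primary-hepatocyte response
# tensors: per-drug log2 fold changes over 3 assay concentrations and
# timepoints 2/8/24 h, with high- and low-responder drug archetypes,
# planted process effects, planted common biomarkers (group-wide high
# mean, low across-drug dispersion), planted single-drug spikes, and a
# planted drug-pair sharing structure for DDI prediction. Every generator
# is a pure function of (spec, seed).

#' Synthetic study specification
#'
#' Defaults mirror the study shape: 15 drugs (8 high-responsive, 7
#' low-responsive), 74 toxicity gene sets over a 2500-gene universe, 3
#' assay concentrations and timepoints 2, 8, 24 h. Signed log2 fold
#' changes are planted effect x concentration factor x time factor plus
#' Gaussian noise; responses downstream are absolute values.
#'
#' @param n_drugs total drugs; the first `n_high` are high responders.
#' @param n_high number of high-responsive drugs.
#' @param n_genes universe size.
#' @param n_processes number of gene sets.
#' @param process_size_range inclusive size range of the sets.
#' @param n_affected number of processes perturbed by the high group.
#' @param concentration_um the three assay concentrations, µmol/L.
#' @param concentration_factors response multipliers per level.
#' @param timepoints_h measured timepoints.
#' @param time_factors response multipliers per timepoint.
#' @param noise_sd Gaussian noise SD on signed log2FC.
#' @param effect_high,effect_low process-effect amplitude per archetype.
#' @param gene_factor_range per-(gene, drug) uniform effect heterogeneity.
#' @param common_per_process planted common biomarkers per affected
#'   process.
#' @param common_mult common-biomarker amplitude relative to
#'   `effect_high`.
#' @param spike_mult individual-biomarker spike as a multiple of the
#'   realized scope mean effect.
#' @param n_ddi_pairs planted drug pairs sharing a spiked gene.
#' @param n_private_spikes additional single-drug spikes without a
#'   partner.
#' @param planted_confusion target DDI confusion counts
#'   `c(TP, FP, TN, FN)` over the high-group pairs.
#' @param seed root seed.
#' @return an object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_drugs = 15, n_high = 8, n_genes = 2500,
                                 n_processes = 74,
                                 process_size_range = c(15, 30),
                                 n_affected = 10,
                                 concentration_um = c(low = 1, mid = 5,
                                                      high = 25),
                                 concentration_factors = c(low = 0.25,
                                                           mid = 0.5,
                                                           high = 1.0),
                                 timepoints_h = c(2, 8, 24),
                                 time_factors = c(`2` = 0.3, `8` = 0.7,
                                                  `24` = 1.0),
                                 noise_sd = 0.1,
                                 effect_high = 1.2, effect_low = 0.02,
                                 gene_factor_range = c(0.3, 1.7),
                                 common_per_process = 2, common_mult = 3,
                                 spike_mult = 15,
                                 n_ddi_pairs = 17, n_private_spikes = 4,
                                 planted_confusion = c(TP = 12, FP = 5,
                                                       TN = 7, FN = 4),
                                 seed = 1) {
  assert_that(n_high >= 2 && n_high < n_drugs,
              "need 2 <= n_high < n_drugs")
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  assert_that(all(timepoints_h %in% c(2, 8, 24)),
              "timepoints must be within {2, 8, 24} h")
  assert_that(n_affected <= n_processes, "n_affected exceeds n_processes")
  assert_that(n_processes * process_size_range[2] <= n_genes,
              "gene sets exceed the universe (%d sets of <= %d genes vs %d)",
              n_processes, process_size_range[2], n_genes)
  assert_that(n_ddi_pairs <= choose(n_high, 2),
              "n_ddi_pairs exceeds the number of high-group pairs")
  assert_that(all(effect_high >= 0, effect_low >= 0, common_mult >= 0,
                  spike_mult >= 0), "amplitudes must be >= 0")
  structure(as.list(environment()), class = "synthetic_study_spec")
}

#' @export
print.synthetic_study_spec <- function(x, ...) {
  cat(sprintf("<synthetic_study_spec: %d drugs (%d high), %d genes, %d sets, seed %d>\n",
              x$n_drugs, x$n_high, x$n_genes, x$n_processes, x$seed))
  invisible(x)
}

.study_drugs <- function(spec) {
  panel <- c("APAP", "AD", "AZA", "CPA", "CSA", "DFN", "ERY", "FT", "HPL",
             "INH", "PB", "PHE", "RIF", "SST", "VPA")
  if (spec$n_drugs <= length(panel)) panel[seq_len(spec$n_drugs)]
  else c(panel, sprintf("SYN%02d", seq_len(spec$n_drugs - length(panel))))
}

#' Generate the compound panel
#'
#' Returns the shipped hepatotoxicant physicochemistry table; drugs beyond
#' the fifteen shipped ones are sampled within the observed property
#' ranges (logP in [-0.98, 4.68], fu in [0.0032, 0.98]) and labelled
#' `SYNxx` (synthetic). Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_study_spec()].
#' @return named list of [compound_properties()].
#' @export
generate_compound_panel <- function(spec) {
  panel <- hepatotoxicant_panel()
  drugs <- .study_drugs(spec)
  extra <- setdiff(drugs, names(panel))
  if (length(extra)) {
    set.seed(fork_seed(spec$seed, "compound_panel"))
    for (id in extra) {
      panel[[id]] <- compound_properties(
        id, molecular_weight = stats::runif(1, 100, 900),
        logP = stats::runif(1, -0.98, 4.68),
        fraction_unbound = stats::runif(1, 0.0032, 0.98),
        compound_type = "neutral",
        water_solubility = 10^stats::runif(1, 0, 5))
    }
  }
  panel
}

#' Generate the toxicity gene sets and functional classes
#'
#' Pairwise-disjoint sets by default (an `overlap_fraction` > 0 reuses
#' that fraction of each set's members from earlier sets), with every gene
#' assigned one functional class; the planted DDI-spike genes get the
#' cytochrome P450 class.
#'
#' @param spec a [synthetic_study_spec()].
#' @param overlap_fraction fraction of each set drawn from already-used
#'   genes.
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(spec, overlap_fraction = 0) {
  set.seed(fork_seed(spec$seed, "gene_sets"))
  universe <- sprintf("g%04d", seq_len(spec$n_genes))
  rng <- spec$process_size_range
  sizes <- if (rng[1] == rng[2]) rep(rng[1], spec$n_processes)
           else sample(rng[1]:rng[2], spec$n_processes, replace = TRUE)
  sets <- list(); used <- character(0)
  pool <- universe
  for (i in seq_len(spec$n_processes)) {
    n_old <- min(floor(sizes[i] * overlap_fraction), length(used))
    members <- c(if (n_old > 0) sample(used, n_old),
                 sample(pool, sizes[i] - n_old))
    pool <- setdiff(pool, members)
    used <- union(used, members)
    sets[[sprintf("process_%02d", i)]] <- sort(members)
  }
  classes <- sample(c("kinase", "transcription regulator", "enzyme",
                      "transporter", "growth factor",
                      "ligand-dependent nuclear receptor", "peptidase",
                      "phosphatase", "other"),
                    spec$n_genes, replace = TRUE)
  names(classes) <- universe
  gene_set_collection(sets, classes, universe)
}

#' Generate the in vitro response tensor with planted ground truth
#'
#' Produces the signed log2FC tensor (drug x gene x concentration level x
#' timepoint) and a manifest listing every planted truth: the high/low
#' drug groups, affected processes, common biomarkers, individual spikes
#' and the planted DDI pair structure. The DDI-spike genes are reassigned
#' the cytochrome P450 class inside the returned collection.
#'
#' @param spec a [synthetic_study_spec()].
#' @param collection a [generate_gene_sets()] result.
#' @return list with `responses` (data.frame drug, gene, level, conc_um,
#'   time_h, log2fc), `collection` (classes updated) and `manifest`.
#' @export
generate_expression_dataset <- function(spec, collection) {
  set.seed(fork_seed(spec$seed, "expression"))
  drugs <- .study_drugs(spec)
  high <- drugs[seq_len(spec$n_high)]
  low <- setdiff(drugs, high)
  procs <- names(collection$process_sets)
  affected <- sort(sample(procs, spec$n_affected))

  # per-(gene, drug) planted effect amplitudes on the signed log2FC scale
  genes <- collection$universe
  eff <- matrix(0, nrow = length(genes), ncol = length(drugs),
                dimnames = list(genes, drugs))
  for (ps in affected) {
    members <- collection$process_sets[[ps]]
    eff[members, high] <- spec$effect_high *
      stats::runif(length(members) * length(high),
                   spec$gene_factor_range[1], spec$gene_factor_range[2])
    eff[members, low] <- spec$effect_low *
      stats::runif(length(members) * length(low),
                   spec$gene_factor_range[1], spec$gene_factor_range[2])
  }

  # reserve the common-biomarker genes per affected process (amplitudes
  # are planted after the spikes, relative to the realized scope mean)
  common <- do.call(rbind, lapply(affected, function(ps) {
    members <- collection$process_sets[[ps]]
    picks <- sample(members, min(spec$common_per_process, length(members)))
    data.frame(gene = picks, process = ps, stringsAsFactors = FALSE)
  }))

  # planted individual spikes: DDI pair genes (one dedicated gene shared
  # by exactly two high drugs) plus private single-drug spikes. Spike and
  # common-biomarker amplitudes within each (process, high-group) scope
  # are set self-consistently against the scope mean they themselves
  # shift: with n values in the scope, n_c of them common (at common_mult
  # x mean) and n_s spiked (at spike_mult x mean), the realized mean is
  #   m = sum(background) / (n - common_mult*n_c - spike_mult*n_s),
  # so planted commons sit at exactly common_mult x the scope mean and
  # spikes at exactly spike_mult x, whatever the load. Spike genes are
  # assigned greedily to the scope with the largest remaining capacity so
  # every denominator stays comfortably positive.
  pair_idx <- utils::combn(high, 2)
  sel_pairs <- sort(sample(ncol(pair_idx), spec$n_ddi_pairs))
  n_spike_genes <- spec$n_ddi_pairs + spec$n_private_spikes
  pools <- lapply(affected, function(ps)
    setdiff(collection$process_sets[[ps]], common$gene))
  names(pools) <- affected
  n_high <- length(high)
  n_scope <- vapply(affected, function(ps)
    length(collection$process_sets[[ps]]) * n_high, 0)
  n_c <- vapply(affected, function(ps)
    sum(common$process == ps) * n_high, 0)
  # capacity in spike values keeping the denominator >= n/10
  capacity <- floor((0.9 * n_scope - spec$common_mult * n_c) /
                      max(spec$spike_mult, 1))
  capacity <- pmin(capacity, lengths(pools) * 2L)
  values_needed <- 2L * spec$n_ddi_pairs + spec$n_private_spikes
  assert_that(sum(pmax(capacity, 0)) >= values_needed,
              "affected processes cannot absorb %d spike values; increase n_affected or process sizes",
              values_needed)
  n_values <- c(rep(2L, spec$n_ddi_pairs), rep(1L, spec$n_private_spikes))
  spike_genes <- character(n_spike_genes)
  spike_proc <- character(n_spike_genes)
  for (k in seq_len(n_spike_genes)) {
    ok <- names(capacity)[capacity >= n_values[k] & lengths(pools) > 0]
    assert_that(length(ok) > 0, "spike capacity exhausted")
    ps <- ok[which.max(capacity[ok])]
    g <- if (length(pools[[ps]]) == 1L) pools[[ps]]
         else sample(pools[[ps]], 1L)
    pools[[ps]] <- setdiff(pools[[ps]], g)
    capacity[ps] <- capacity[ps] - n_values[k]
    spike_genes[k] <- g
    spike_proc[k] <- ps
  }
  spikes <- list()
  for (k in seq_len(spec$n_ddi_pairs)) {
    for (d in pair_idx[, sel_pairs[k]])
      spikes[[length(spikes) + 1L]] <-
        data.frame(drug = d, gene = spike_genes[k],
                   process = spike_proc[k], pair = k,
                   stringsAsFactors = FALSE)
  }
  if (spec$n_private_spikes > 0) {
    priv_drugs <- sample(high, spec$n_private_spikes, replace = TRUE)
    for (k in seq_len(spec$n_private_spikes)) {
      spikes[[length(spikes) + 1L]] <-
        data.frame(drug = priv_drugs[k],
                   gene = spike_genes[spec$n_ddi_pairs + k],
                   process = spike_proc[spec$n_ddi_pairs + k],
                   pair = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  spikes <- do.call(rbind, spikes)
  # self-consistent amplitude solve per scope
  for (ps in affected) {
    members <- collection$process_sets[[ps]]
    com_g <- common$gene[common$process == ps]
    spk <- spikes[spikes$process == ps, , drop = FALSE]
    bg <- eff[members, high, drop = FALSE]
    bg[com_g, ] <- 0
    for (i in seq_len(nrow(spk))) bg[spk$gene[i], spk$drug[i]] <- 0
    n <- length(members) * n_high
    denom <- n - spec$common_mult * length(com_g) * n_high -
      spec$spike_mult * nrow(spk)
    assert_that(denom > 0, "scope '%s' overloaded with planted structure", ps)
    m <- sum(bg) / denom
    eff[com_g, high] <- spec$common_mult * m
    for (i in seq_len(nrow(spk)))
      eff[spk$gene[i], spk$drug[i]] <- spec$spike_mult * m
  }
  # spike genes carry the cytochrome P450 class
  collection$functional_classes[spike_genes] <- "cytochrome P450"

  # planted DDI pair labels (drug_a < drug_b)
  ddi_pairs <- data.frame(
    drug_a = pmin(pair_idx[1, sel_pairs], pair_idx[2, sel_pairs]),
    drug_b = pmax(pair_idx[1, sel_pairs], pair_idx[2, sel_pairs]),
    gene = spike_genes[seq_len(spec$n_ddi_pairs)],
    stringsAsFactors = FALSE)

  # assemble the tensor: effect x concentration factor x time factor + noise
  lv <- names(spec$concentration_factors)
  tp <- spec$timepoints_h
  grid <- expand.grid(level = lv, time_h = tp, drug = drugs,
                      stringsAsFactors = FALSE)
  blocks <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cf <- spec$concentration_factors[[grid$level[i]]]
    tf <- spec$time_factors[[as.character(grid$time_h[i])]]
    mu <- eff[, grid$drug[i]] * cf * tf
    blocks[[i]] <- data.frame(
      drug = grid$drug[i], gene = genes, level = grid$level[i],
      conc_um = unname(spec$concentration_um[[grid$level[i]]]),
      time_h = grid$time_h[i],
      log2fc = mu + stats::rnorm(length(genes), 0, spec$noise_sd),
      stringsAsFactors = FALSE)
  }
  responses <- do.call(rbind, blocks)
  rownames(responses) <- NULL
  manifest <- list(drugs = drugs, high_drugs = high, low_drugs = low,
                   affected_processes = affected,
                   common_biomarkers = common,
                   individual_spikes = spikes,
                   ddi_pairs = ddi_pairs,
                   planted_confusion = spec$planted_confusion,
                   concentration_um = spec$concentration_um,
                   seed = spec$seed)
  list(responses = responses, collection = collection,
       manifest = manifest)
}

#' Construct a reference DDI set realizing requested confusion counts
#'
#' Given the predicted pairs and target counts `(TP, FP, TN, FN)`, selects
#' a reference set of known interactions such that
#' [evaluate_ddi_predictions()] reproduces the requested confusion matrix
#' exactly. Requires `TP + FP` to equal the number of predicted pairs and
#' the counts to sum to `choose(n_drugs, 2)`.
#'
#' @param spec a [synthetic_study_spec()] (provides the seed).
#' @param predicted data.frame with `drug_a`, `drug_b` of predicted pairs.
#' @param drugs the drug group.
#' @param counts named counts `c(TP, FP, TN, FN)` (default: the spec's
#'   planted confusion).
#' @return data.frame with `drug_a`, `drug_b`, `interaction_type`,
#'   `source` (all synthetic).
#' @export
generate_reference_ddis <- function(spec, predicted, drugs,
                                    counts = spec$planted_confusion) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  dd <- sort(unique(drugs))
  n_pairs <- choose(length(dd), 2)
  assert_that(sum(counts) == n_pairs,
              "confusion counts sum to %d but there are %d pairs",
              sum(counts), n_pairs)
  all_pairs <- utils::combn(dd, 2)
  keys <- .canon_pairs(all_pairs[1, ], all_pairs[2, ])
  pred_keys <- if (nrow(predicted))
    .canon_pairs(predicted$drug_a, predicted$drug_b) else character(0)
  assert_that(all(pred_keys %in% keys), "predicted pairs outside the group")
  n_pred <- length(pred_keys)
  if (counts[["TP"]] + counts[["FP"]] != n_pred)
    stop_config("infeasible request: TP + FP = %d but %d pairs are predicted",
                counts[["TP"]] + counts[["FP"]], n_pred)
  if (counts[["TP"]] > n_pred)
    stop_config("infeasible request: TP exceeds the predicted pair count")
  set.seed(fork_seed(spec$seed, "reference_ddis"))
  pos_pred <- sample(pred_keys, counts[["TP"]])
  non_pred <- setdiff(keys, pred_keys)
  assert_that(counts[["FN"]] <= length(non_pred),
              "infeasible request: FN exceeds the non-predicted pair count")
  pos_non <- if (counts[["FN"]] > 0) sample(non_pred, counts[["FN"]])
             else character(0)
  ref_keys <- c(pos_pred, pos_non)
  if (!length(ref_keys))
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      interaction_type = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(ref_keys, "\r", fixed = TRUE))
  out <- data.frame(drug_a = parts[, 1], drug_b = parts[, 2],
                    interaction_type = "unknown", source = "synthetic",
                    stringsAsFactors = FALSE)
  out[order(out$drug_a, out$drug_b), , drop = FALSE]
}

#' Sample noisy PK observations from a simulation
#'
#' Venous plasma concentrations at the requested timepoints with
#' multiplicative lognormal noise of the given coefficient of variation
#' (unit mean). Deterministic for a fixed seed.
#'
#' @param model a [pbpk_model()].
#' @param regimen a [dosing_regimen()].
#' @param timepoints sampling times, h, within the simulation span.
#' @param noise_cv coefficient of variation (>= 0; 0 returns the exact
#'   simulation values).
#' @param seed RNG seed.
#' @param t_end simulation horizon, h (default: just past the last
#'   timepoint).
#' @param ... passed to [simulate_pk()].
#' @return a `pk_profile` of observations.
#' @export
generate_pk_observations <- function(model, regimen, timepoints,
                                     noise_cv = 0.1, seed = 1,
                                     t_end = max(timepoints) * 1.05, ...) {
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  sim <- simulate_pk(model, regimen, t_end = t_end, ...)
  prof <- get_profile(sim)
  vals <- stats::approx(prof$times, prof$values, xout = timepoints)$y
  assert_that(!anyNA(vals), "timepoints outside the simulation span")
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    vals <- vals * stats::rlnorm(length(vals), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
  }
  structure(list(compound_id = prof$compound_id,
                 compartment = "venous_plasma (observed)",
                 times = timepoints, values = vals),
            class = "pk_profile")
}
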