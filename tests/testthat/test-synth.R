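test_that("generators are pure functions of (spec, seed)", {
  spec <- synthetic_study_spec(n_drugs = 6, n_high = 3, n_genes = 300,
                               n_processes = 10, n_affected = 4,
                               n_ddi_pairs = 2, n_private_spikes = 1,
                               planted_confusion = c(TP = 1, FP = 1,
                                                     TN = 1, FN = 0),
                               seed = 5)
  g1 <- generate_gene_sets(spec)
  g2 <- generate_gene_sets(spec)
  expect_identical(g1$process_sets, g2$process_sets)
  d1 <- generate_expression_dataset(spec, g1)
  d2 <- generate_expression_dataset(spec, g2)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$manifest$individual_spikes,
                   d2$manifest$individual_spikes)
  p1 <- generate_compound_panel(spec)
  expect_identical(p1, generate_compound_panel(spec))
})

test_that("with zero planted effects the mean response matches the folded normal", {
  spec <- synthetic_study_spec(n_drugs = 6, n_high = 3, n_genes = 3000,
                               n_processes = 10, n_affected = 2,
                               effect_high = 0, effect_low = 0,
                               common_mult = 0, spike_mult = 0,
                               n_ddi_pairs = 1, n_private_spikes = 0,
                               planted_confusion = c(TP = 1, FP = 0,
                                                     TN = 2, FN = 0),
                               noise_sd = 0.1, seed = 2)
  ds <- generate_expression_dataset(spec, generate_gene_sets(spec))
  m <- mean(abs(ds$responses$log2fc))
  expect_gt(nrow(ds$responses), 1e5)
  expect_equal(m, 0.1 * sqrt(2 / pi), tolerance = 0.03)
})

test_that("gene-set generation respects the universe, disjointness and GMT round trip", {
  spec <- synthetic_study_spec(n_genes = 5000, n_processes = 74,
                               process_size_range = c(30, 30))
  coll <- generate_gene_sets(spec)
  expect_length(coll$process_sets, 74)
  expect_true(all(lengths(coll$process_sets) == 30))
  expect_true(all(unlist(coll$process_sets) %in% coll$universe))
  expect_false(anyDuplicated(names(coll$process_sets)) > 0)
  # overlap 0: pairwise disjoint
  expect_equal(anyDuplicated(unlist(coll$process_sets)), 0)
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll$process_sets, path)
  back <- read_gmt(path)
  expect_identical(lapply(back, identity), coll$process_sets)
})

test_that("planted spikes reach their multiple of the realized scope mean", {
  spec <- synthetic_study_spec(seed = 3)
  coll <- generate_gene_sets(spec)
  ds <- generate_expression_dataset(spec, coll)
  man <- ds$manifest
  r24 <- ds$responses[ds$responses$time_h == 24, ]
  hi <- r24[r24$level == "high", ]
  for (i in sample(nrow(man$individual_spikes), 5)) {
    s <- man$individual_spikes[i, ]
    members <- coll$process_sets[[s$process]]
    scope <- hi$log2fc[hi$gene %in% members & hi$drug %in% man$high_drugs]
    v <- hi$log2fc[hi$gene == s$gene & hi$drug == s$drug]
    expect_gt(abs(v), 7 * mean(abs(scope)))
  }
  # spike genes carry the CYP class
  expect_true(all(ds$collection$functional_classes[
    man$individual_spikes$gene] == "cytochrome P450"))
})

test_that("reference DDI construction realizes the requested confusion exactly", {
  spec <- synthetic_study_spec(seed = 4)
  drugs <- paste0("d", 1:8)
  all_pairs <- t(combn(drugs, 2))
  pred <- data.frame(drug_a = all_pairs[1:17, 1],
                     drug_b = all_pairs[1:17, 2])
  ref <- generate_reference_ddis(spec, pred, drugs,
                                 counts = c(TP = 12, FP = 5, TN = 7,
                                            FN = 4))
  ev <- evaluate_ddi_predictions(pred, ref, drugs)
  expect_equal(c(ev$TP, ev$FP, ev$TN, ev$FN), c(12, 5, 7, 4))
  # all-TN request with empty predictions: specificity 1
  empty <- pred[0, ]
  ref0 <- generate_reference_ddis(spec, empty, drugs,
                                  counts = c(TP = 0, FP = 0, TN = 28,
                                             FN = 0))
  ev0 <- suppressWarnings(evaluate_ddi_predictions(empty, ref0, drugs))
  expect_equal(ev0$specificity, 1)
  expect_true(is.na(ev0$precision))
  # infeasible: TP exceeding the predicted count
  expect_error(generate_reference_ddis(spec, pred, drugs,
                                       counts = c(TP = 20, FP = -3,
                                                  TN = 7, FN = 4)),
               "infeasible")
})

test_that("PK observations carry the requested noise and are seed-stable", {
  m <- one_compartment_model(10, 1, molecular_weight = 100)
  reg <- dosing_regimen("iv_bolus", 10)
  exact <- generate_pk_observations(m, reg, timepoints = c(2, 6, 12),
                                    noise_cv = 0)
  prof <- get_profile(simulate_pk(m, reg, t_end = 13))
  expect_equal(exact$values,
               approx(prof$times, prof$values, xout = c(2, 6, 12))$y,
               tolerance = 1e-4)
  n1 <- generate_pk_observations(m, reg, c(2, 6, 12), noise_cv = 0.1,
                                 seed = 7)
  n2 <- generate_pk_observations(m, reg, c(2, 6, 12), noise_cv = 0.1,
                                 seed = 7)
  expect_identical(n1$values, n2$values)
  # empirical CV across many replicates of the noise model
  set.seed(1)
  sdlog <- sqrt(log(1 + 0.1^2))
  reps <- rlnorm(1e4, -sdlog^2 / 2, sdlog)
  cv <- sd(reps) / mean(reps)
  expect_gt(cv, 0.095); expect_lt(cv, 0.105)
  expect_error(generate_pk_observations(m, reg, c(2, 50), t_end = 24),
               "outside")
})

test_that("the compound panel extends beyond the shipped drugs within observed ranges", {
  spec <- synthetic_study_spec(n_drugs = 18, n_high = 8, seed = 6)
  panel <- generate_compound_panel(spec)
  syn <- panel[grep("^SYN", names(panel))]
  expect_length(syn, 3)
  for (cp in syn) {
    expect_gte(cp$logP, -0.98); expect_lte(cp$logP, 4.68)
    expect_gte(cp$fraction_unbound, 0.0032)
    expect_lte(cp$fraction_unbound, 0.98)
  }
})
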