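test_that("the hand-computed common-biomarker scope selects exactly the outlier", {
  # 10 genes x 4 drugs: gene g01 at 0.9 for every drug, the rest at 0.1
  genes <- sprintf("g%02d", 1:10)
  drugs <- paste0("d", 1:4)
  tc <- matrix(0.1, nrow = 10, ncol = 4, dimnames = list(genes, drugs))
  tc["g01", ] <- 0.9
  tbl <- scope_to_table(tc)
  coll <- scope_collection(genes)
  bm <- identify_common_biomarkers(tbl, drugs, coll)
  # grand mean 0.18; 0.9 > 1.5*0.18 and sd 0 < 0.5*grand sd
  expect_equal(bm$gene, "g01")
  expect_equal(bm$grand_mean[1], 0.18)
  expect_equal(bm$mean_toxic_change[1], 0.9)
})

test_that("degenerate all-equal scopes yield no biomarkers", {
  genes <- sprintf("g%02d", 1:5)
  tc <- matrix(0.3, 5, 3, dimnames = list(genes, paste0("d", 1:3)))
  coll <- scope_collection(genes)
  bm <- identify_common_biomarkers(scope_to_table(tc), paste0("d", 1:3),
                                   coll)
  expect_equal(nrow(bm), 0)
  ind <- identify_individual_biomarkers(scope_to_table(tc),
                                        paste0("d", 1:3), coll)
  expect_equal(nrow(ind), 0)  # value = mean < 7*mean for positive mean
})

test_that("individual biomarkers pass strictly above seven times the scope mean", {
  genes <- sprintf("g%02d", 1:10)
  drugs <- paste0("d", 1:4)
  tc <- matrix(0.1, 10, 4, dimnames = list(genes, drugs))
  tc["g05", "d2"] <- 0.71
  # grand mean = (39*0.1 + 0.71)/40 = 0.11525; 0.71 < 7*0.11525 -> miss
  coll <- scope_collection(genes)
  ind <- identify_individual_biomarkers(scope_to_table(tc), drugs, coll)
  expect_equal(nrow(ind), 0)
  tc["g05", "d2"] <- 1.2  # 1.2 > 7*0.1275
  ind2 <- identify_individual_biomarkers(scope_to_table(tc), drugs, coll)
  expect_equal(ind2$gene, "g05")
  expect_equal(ind2$drug, "d2")
})

test_that("Eq. 2/3 selections match the loop oracle on random scopes", {
  set.seed(31)
  for (i in 1:50) {
    n_g <- sample(3:12, 1); n_d <- sample(2:6, 1)
    tc <- matrix(round(rexp(n_g * n_d, 5), 4), n_g, n_d,
                 dimnames = list(sprintf("g%02d", 1:n_g),
                                 sprintf("d%02d", 1:n_d)))
    coll <- scope_collection(rownames(tc))
    tbl <- scope_to_table(tc)
    oracle <- biomarker_oracle(tc)
    bm <- identify_common_biomarkers(tbl, colnames(tc), coll)
    expect_equal(sort(bm$gene), oracle$common)
    ind <- identify_individual_biomarkers(tbl, colnames(tc), coll)
    expect_equal(sort(paste(ind$drug, ind$gene)), oracle$individual)
  }
})

test_that("selections are invariant to ordering and positive scaling", {
  set.seed(8)
  tc <- matrix(rexp(40, 3), 8, 5,
               dimnames = list(sprintf("g%02d", 1:8), paste0("d", 1:5)))
  coll <- scope_collection(rownames(tc))
  base_c <- identify_common_biomarkers(scope_to_table(tc), paste0("d", 1:5),
                                       coll)
  base_i <- identify_individual_biomarkers(scope_to_table(tc),
                                           paste0("d", 1:5), coll)
  shuf <- scope_to_table(tc)
  shuf <- shuf[sample(nrow(shuf)), ]
  expect_setequal(identify_common_biomarkers(shuf, paste0("d", 1:5),
                                             coll)$gene, base_c$gene)
  scaled <- scope_to_table(tc * 17)
  expect_setequal(identify_common_biomarkers(scaled, paste0("d", 1:5),
                                             coll)$gene, base_c$gene)
  si <- identify_individual_biomarkers(scaled, paste0("d", 1:5), coll)
  expect_setequal(paste(si$drug, si$gene),
                  paste(base_i$drug, base_i$gene))
})

test_that("biomarker group sensitivity testing matches a hand-pooled t-test", {
  genes <- c("g01", "g02")
  hi_d <- paste0("h", 1:4); lo_d <- paste0("l", 1:4)
  tc <- rbind(
    data.frame(drug = hi_d, entity = "g01", time_h = 24,
               toxic_change = c(0.9, 0.9, 0.8, 1.0)),
    data.frame(drug = lo_d, entity = "g01", time_h = 24,
               toxic_change = c(0.1, 0.1, 0.2, 0.0)),
    data.frame(drug = c(hi_d, lo_d), entity = "g02", time_h = 24,
               toxic_change = rep(0.5, 8)))
  common <- structure(
    data.frame(gene = genes, process = "P1", time_h = 24,
               mean_toxic_change = c(0.9, 0.5),
               sd_toxic_change = 0, grand_mean = 0, grand_sd = 0),
    kind = "common", class = c("biomarker_set", "data.frame"))
  out <- test_biomarker_sensitivity(common, tc, lo_d, hi_d)
  oracle <- t.test(c(0.9, 0.9, 0.8, 1.0), c(0.1, 0.1, 0.2, 0.0),
                   var.equal = TRUE)$p.value
  expect_equal(out$p_raw[out$gene == "g01"], oracle)
  expect_equal(out$p_raw[out$gene == "g02"], 1)  # identical groups
  expect_false(out$significant[out$gene == "g02"])
  # BH keeps the raw ordering
  expect_true(out$p_adjusted[out$gene == "g01"] <=
                out$p_adjusted[out$gene == "g02"])
})

test_that("shared individual biomarkers predict symmetric, ranked DDI pairs", {
  bm <- structure(
    data.frame(gene = c("CYP9X", "CYP9X", "gA", "gA", "gA", "gB"),
               drug = c("A", "B", "A", "B", "C", "C"),
               process = "P1", time_h = 24,
               toxic_change = c(2.0, 2.3, 1.0, 1.1, 1.3, 3.0),
               grand_mean = 0.1),
    kind = "individual", class = c("biomarker_set", "data.frame"))
  classes <- c(CYP9X = "cytochrome P450", gA = "enzyme", gB = "kinase")
  coll <- gene_set_collection(list(P1 = names(classes)), classes,
                              universe = names(classes))
  pred <- predict_ddis(bm, c("A", "B", "C"), coll)
  expect_equal(nrow(pred), 3)  # A-B (two genes), A-C and B-C via gA
  ab <- pred[pred$drug_a == "A" & pred$drug_b == "B", ]
  expect_equal(ab$n_shared, 2)
  # |delta| CYP9X = 0.3, gA = 0.1 -> gA first (ascending)
  expect_equal(ab$shared_genes, "gA,CYP9X")
  expect_true(ab$has_cyp)
  expect_false(pred$has_cyp[pred$drug_a == "A" & pred$drug_b == "C"])
  # symmetric: pair appears once regardless of drug order in the input
  expect_equal(anyDuplicated(with(pred, paste(pmin(drug_a, drug_b),
                                              pmax(drug_a, drug_b)))), 0)
})

test_that("ranking sorts three shared genes by ascending absolute difference", {
  bm <- structure(
    data.frame(gene = rep(c("x", "y", "z"), each = 2),
               drug = rep(c("A", "B"), 3), process = "P", time_h = 24,
               toxic_change = c(1.0, 1.3, 1.0, 1.1, 1.0, 1.2),
               grand_mean = 0.1),
    kind = "individual", class = c("biomarker_set", "data.frame"))
  pred <- predict_ddis(bm, c("A", "B"))
  rk <- attr(pred, "ranked")[["A ~ B"]]
  expect_equal(rk$gene, c("y", "z", "x"))
  expect_equal(rk$abs_difference, c(0.1, 0.2, 0.3))
})

test_that("DDI evaluation reproduces counts, metrics and undefined ratios", {
  drugs <- paste0("d", 1:8)
  # perfect prediction
  ref <- data.frame(drug_a = c("d1", "d2"), drug_b = c("d2", "d5"))
  ev <- evaluate_ddi_predictions(ref, ref, drugs)
  expect_equal(c(ev$accuracy, ev$sensitivity, ev$specificity, ev$precision),
               c(1, 1, 1, 1))
  # empty predictions: sensitivity 0, specificity 1, precision undefined
  expect_warning(
    ev0 <- evaluate_ddi_predictions(NULL, ref, drugs), "precision")
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$specificity, 1)
  expect_true(is.na(ev0$precision))
  # duplicates rejected
  dup <- rbind(ref, ref[1, ])
  expect_error(evaluate_ddi_predictions(dup, ref, drugs), "duplicate")
  # oracle equivalence on random prediction/reference sets
  set.seed(99)
  all_pairs <- t(combn(drugs, 2))
  for (i in 1:200) {
    np <- sample(0:28, 1); nr <- sample(0:28, 1)
    pi <- sample(28, np); ri <- sample(28, nr)
    pred <- data.frame(drug_a = all_pairs[pi, 1], drug_b = all_pairs[pi, 2])
    refr <- data.frame(drug_a = all_pairs[ri, 1], drug_b = all_pairs[ri, 2])
    ev <- suppressWarnings(evaluate_ddi_predictions(pred, refr, drugs))
    oc <- confusion_oracle(paste(pred$drug_a, pred$drug_b),
                           paste(refr$drug_a, refr$drug_b), drugs)
    expect_equal(c(TP = ev$TP, FP = ev$FP, TN = ev$TN, FN = ev$FN), oc)
    if (!is.na(ev$accuracy))
      expect_equal(ev$accuracy, (oc[["TP"]] + oc[["TN"]]) / 28)
  }
})

test_that("threshold sweeps report zero change at delta zero and are monotone", {
  set.seed(12)
  tc <- matrix(rexp(60, 4), 12, 5,
               dimnames = list(sprintf("g%02d", 1:12), paste0("d", 1:5)))
  tc["g03", "d2"] <- mean(tc) * 12
  coll <- scope_collection(rownames(tc))
  tbl <- scope_to_table(tc)
  sw0 <- sweep_thresholds(tbl, paste0("d", 1:5), coll, deltas = 0)
  expect_true(all(sw0$pct_change == 0, na.rm = TRUE))
  sw <- sweep_thresholds(tbl, paste0("d", 1:5), coll)
  expect_equal(sort(unique(sw$threshold)),
               c("common_mean_mult", "common_sd_mult", "individual_mult"))
  # raising the individual multiplier never increases the count
  im <- sw[sw$threshold == "individual_mult", ]
  expect_true(im$count[im$delta > 0] <= im$baseline_count[1])
  expect_true(im$count[im$delta < 0] >= im$baseline_count[1])
})
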