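test_that("gene response level is the absolute log2 fold change", {
  expect_equal(gene_response_level(-2), 2)
  expect_equal(gene_response_level(0), 0)
  expect_equal(gene_response_level(c(1.5, -0.3)), c(1.5, 0.3))
  expect_error(gene_response_level(NA_real_), "finite")
})

test_that("process aggregation is the mean over measured members", {
  coll <- gene_set_collection(list(P = c("g1", "g2"), S = "g3"),
                              universe = paste0("g", 1:4))
  gr <- data.frame(gene = c("g1", "g2", "g3"),
                   response = c(0.2, 0.4, 0.7))
  agg <- aggregate_response(gr, coll)
  expect_equal(agg$response[agg$entity == "P"], 0.3)
  expect_equal(agg$response[agg$entity == "S"], 0.7)
  # 50-gene random set: independent summation oracle
  set.seed(9)
  genes <- sprintf("r%03d", 1:60)
  coll2 <- gene_set_collection(list(big = sample(genes, 50)),
                               universe = genes)
  gr2 <- data.frame(gene = genes, response = runif(60))
  agg2 <- aggregate_response(gr2, coll2)
  members <- coll2$process_sets$big
  oracle <- sum(gr2$response[gr2$gene %in% members]) / length(members)
  expect_equal(agg2$response, oracle)
  # permutation invariance under gene relabeling (row order shuffles)
  gr3 <- gr2[sample(nrow(gr2)), ]
  expect_equal(aggregate_response(gr3, coll2)$response, oracle)
})

test_that("unmeasured members are excluded and empty processes warned about", {
  coll <- gene_set_collection(list(P = c("g1", "g2", "g9"),
                                   Q = "g9"),
                              universe = paste0("g", c(1:2, 9)))
  gr <- data.frame(gene = c("g1", "g2"), response = c(0.2, 0.6))
  expect_warning(agg <- aggregate_response(gr, coll), "no measured member")
  expect_equal(agg$response[agg$entity == "P"], 0.4)  # g9 excluded
  cov <- attr(agg, "coverage")
  expect_equal(unname(cov["P", ]), c(2, 3))
})

test_that("toxic change is the toxic minus therapeutic difference", {
  ther <- data.frame(entity = c("a", "b"), time_h = 24,
                     response = c(0.2, 0.5))
  tox <- data.frame(entity = c("a", "b"), time_h = 24,
                    response = c(0.5, 0.3))
  tc <- compute_toxic_change(ther, tox)
  expect_equal(tc$toxic_change, c(0.3, -0.2))
  expect_equal(attr(tc, "n_negative"), 1L)
  # identical inputs give zero; swapping negates
  expect_equal(compute_toxic_change(ther, ther)$toxic_change, c(0, 0))
  expect_equal(compute_toxic_change(tox, ther)$toxic_change,
               -tc$toxic_change)
  # linearity in the responses
  ther2 <- transform(ther, response = 3 * response)
  tox2 <- transform(tox, response = 3 * response)
  expect_equal(compute_toxic_change(ther2, tox2)$toxic_change,
               3 * tc$toxic_change)
  expect_error(compute_toxic_change(ther, tox[1, ]), "mismatch")
})

test_that("hypergeometric ORA matches exact enumeration", {
  # universe 20, set 5, responders 5, full overlap: p = 1/C(20,5)
  uni <- paste0("g", 1:20)
  coll <- gene_set_collection(list(S = uni[1:5]), universe = uni)
  ora <- overrepresentation_analysis(list(d1 = uni[1:5]), coll)
  expect_equal(ora$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  # overlap 0 with zero responders: p = 1
  ora0 <- overrepresentation_analysis(list(d1 = character(0)), coll)
  expect_equal(ora0$p_raw, 1)
  # random configurations vs the enumeration oracle (universes <= 50)
  set.seed(21)
  for (i in 1:25) {
    n_uni <- sample(10:50, 1)
    uni <- paste0("u", seq_len(n_uni))
    set_size <- sample(2:(n_uni - 2), 1)
    n_resp <- sample(1:(n_uni - 1), 1)
    coll <- gene_set_collection(list(S = sample(uni, set_size)),
                                universe = uni)
    resp <- sample(uni, n_resp)
    ora <- overrepresentation_analysis(list(d = resp), coll)
    k <- length(intersect(resp, coll$process_sets$S))
    expect_equal(ora$p_raw, hyper_tail_oracle(k, set_size, n_uni, n_resp),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  uni <- paste0("g", 1:100)
  coll <- gene_set_collection(
    list(A = uni[1:10], B = uni[11:20], C = uni[21:30]), universe = uni)
  ora <- overrepresentation_analysis(list(d = uni[1:12]), coll)
  expect_equal(ora$p_adjusted, bh_oracle(ora$p_raw))
  # the documented worked vector
  expect_equal(bh_oracle(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH"), c(0.003, 0.03, 0.9))
  # adjusted p never below raw p, and the step-up preserves p-ordering
  p <- c(0.04, 0.001, 0.2, 0.03)
  adj <- bh_oracle(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("key-process selection applies the one-third rule across timepoints", {
  mk <- function(drug, process, p) data.frame(drug = drug, process = process,
                                              p_adjusted = p)
  ora <- rbind(mk(paste0("d", 1:4), "P", 0.001),
               mk(paste0("d", 5:15), "P", 0.5),
               mk(paste0("d", 1:5), "Q", 0.001),
               mk(paste0("d", 6:15), "Q", 0.9))
  expect_equal(select_key_processes(ora, n_drugs = 15), "Q")  # 5 >= ceil(5)
  # counted once per drug irrespective of timepoints (duplicate rows)
  ora2 <- rbind(ora, mk(paste0("d", 1:4), "P", 0.001))
  expect_equal(select_key_processes(ora2, n_drugs = 15), "Q")
  # invariant to drug ordering
  expect_equal(select_key_processes(ora[sample(nrow(ora)), ], 15), "Q")
})

test_that("perturbed-process selection uses the group mean threshold", {
  tc <- expand.grid(drug = c("h1", "h2", "l1"), entity = c("P", "Q"),
                    time_h = 24, stringsAsFactors = FALSE)
  tc$toxic_change <- c(0.15, 0.09, 0.01,   # P: high mean 0.12
                       0.10, 0.08, 0.01)   # Q: high mean 0.09
  class(tc) <- c("toxic_change_table", "data.frame")
  sel <- select_perturbed_processes(tc, c("h1", "h2"))
  expect_equal(sel[["24"]], "P")
  expect_warning(
    sel2 <- select_perturbed_processes(tc, c("h1", "h2"),
                                       complement_group = "l1",
                                       threshold = 0.005),
    "complementary")
  expect_error(select_perturbed_processes(tc, character(0)), "empty")
})

test_that("validation statistics behave at the exact and anti-correlated limits", {
  pred <- data.frame(time_h = c(2, 8, 24), response = c(0.1, 0.5, 0.9))
  pv <- approx(pred$time_h, pred$response, xout = c(3, 6, 9, 24))$y
  v <- validate_against_observations(pred, 2 * pv + 1,
                                     match_times = c(3, 6, 9, 24))
  expect_equal(v$r, 1)
  expect_equal(v$R_squared, 1)
  v2 <- validate_against_observations(pred, -pv,
                                      match_times = c(3, 6, 9, 24))
  expect_equal(v2$r, -1)
  expect_error(validate_against_observations(pred, rep(1, 4),
                                             match_times = c(3, 6, 9, 24)),
               "variance")
})
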