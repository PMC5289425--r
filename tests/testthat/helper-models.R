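# Shared fixtures and independent oracles built in code.

# small linear whole-body model for a generic drug
toy_linear_model <- function(hepatic_cl = 100, renal_cl = 50,
                             logP = 1, fu = 0.5, mw = 200) {
  cmp <- compound_properties("drugX", mw, logP, fu, "neutral")
  pbpk_model(list(cmp), reduced_physiology("human"),
             clearances = list(drugX = clearance_spec(
               renal_plasma_clearance = renal_cl,
               hepatic_plasma_clearance = hepatic_cl)))
}

# saturable model: Michaelis-Menten hepatic metabolism to a metabolite
toy_mm_model <- function(vmax = 2000, Km = 10, renal_cl = 50) {
  parent <- compound_properties("par", 200, 1, 0.5, "neutral")
  met <- compound_properties("met", 180, 0, 0.8, "neutral",
                             parent_id = "par")
  pbpk_model(
    list(parent, met), reduced_physiology("human"),
    active_processes = list(
      active_process("metabolism", "liver", "CYP_toy", Km = Km,
                     vmax = vmax, compound_id = "par",
                     product_id = "met")),
    clearances = list(
      par = clearance_spec(renal_plasma_clearance = renal_cl),
      met = clearance_spec(renal_plasma_clearance = 200)))
}

# adjusted Rand index (independent implementation for cluster checks)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# exhaustive hypergeometric tail oracle: P(overlap >= k) by enumeration
# over the hypergeometric pmf computed from binomial coefficients
hyper_tail_oracle <- function(k, set_size, universe, draws) {
  kk <- max(0, k):min(set_size, draws)
  sum(choose(set_size, kk) * choose(universe - set_size, draws - kk)) /
    choose(universe, draws)
}

# hand-rolled Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# loop-based Eq. 2 / Eq. 3 selection oracle over one scope matrix
# (rows: genes, cols: drugs)
biomarker_oracle <- function(tc, mean_mult = 1.5, sd_mult = 0.5,
                             indiv_mult = 7) {
  vals <- as.vector(tc)
  gm <- mean(vals); gs <- sd(vals)
  common <- character(0)
  for (g in rownames(tc)) {
    if (mean(tc[g, ]) > mean_mult * gm && sd(tc[g, ]) < sd_mult * gs)
      common <- c(common, g)
  }
  indiv <- character(0)
  if (gm > 0) {
    for (g in rownames(tc)) for (d in colnames(tc)) {
      if (tc[g, d] > indiv_mult * gm)
        indiv <- c(indiv, paste(d, g))
    }
  }
  list(common = sort(common), individual = sort(indiv))
}

# scope matrix -> tidy toxic-change table for one process at one timepoint
scope_to_table <- function(tc, time_h = 24) {
  data.frame(drug = rep(colnames(tc), each = nrow(tc)),
             entity = rep(rownames(tc), ncol(tc)),
             time_h = time_h, toxic_change = as.vector(tc),
             stringsAsFactors = FALSE)
}

scope_collection <- function(genes, process = "P1") {
  gene_set_collection(stats::setNames(list(genes), process),
                      universe = genes)
}

# brute-force confusion counting over explicit pair grids
confusion_oracle <- function(pred_keys, ref_keys, drugs) {
  dd <- sort(drugs)
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(dd)) for (j in seq_len(i - 1)) {
    key <- paste(dd[j], dd[i])
    p <- key %in% pred_keys
    r <- key %in% ref_keys
    if (p && r) tp <- tp + 1
    else if (p && !r) fp <- fp + 1
    else if (!p && r) fn <- fn + 1
    else tn <- tn + 1
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Independent liver-interstitial AUC oracle for the saturable toy model:
# the parent-drug mass balances of the reduced whole-body layout written
# out directly as an 8-state linear ODE (7 compartments + the AUC
# integral) with the Michaelis-Menten term subtracted on the liver row.
# Returns a fast per-dose evaluator for grid scans.
make_liver_auc_oracle <- function(vmax, Km, renal_cl, duration = 24,
                                  mw = 200, logP = 1, fu = 0.5) {
  phys <- reduced_physiology("human")
  cmp <- compound_properties("par", mw, logP, fu, "neutral")
  kp <- compute_partition_coefficients(cmp, phys)
  kp[c("venous_blood", "arterial_blood")] <- 1
  on <- c("lung", "liver", "gut", "kidney", "adipose", "venous_blood",
          "arterial_blood")
  V <- stats::setNames(phys$volume_l, phys$organ)[on]
  Q <- stats::setNames(phys$flow_l_h, phys$organ)[on]
  kp <- kp[on]
  fc_liv <- phys$f_intracellular[phys$organ == "liver"]
  vmax_abs <- vmax * V[["liver"]] * fc_liv
  cl_r <- renal_cl * attr(phys, "body_weight_kg") / 1000
  q_co <- Q[["lung"]]
  q_liv_out <- Q[["liver"]] + Q[["gut"]]
  # linear part: dx = A %*% cp(x), cp = x / (V * kp); fold the cp
  # transform into the matrix so dx = M %*% x
  i <- function(nm) match(nm, on)
  A <- matrix(0, 8, 8)
  A[i("lung"), i("venous_blood")] <- q_co
  A[i("lung"), i("lung")] <- -q_co
  A[i("liver"), i("arterial_blood")] <- Q[["liver"]]
  A[i("liver"), i("gut")] <- Q[["gut"]]
  A[i("liver"), i("liver")] <- -q_liv_out
  A[i("gut"), i("arterial_blood")] <- Q[["gut"]]
  A[i("gut"), i("gut")] <- -Q[["gut"]]
  A[i("kidney"), i("arterial_blood")] <- Q[["kidney"]]
  A[i("kidney"), i("kidney")] <- -(Q[["kidney"]] + cl_r)
  A[i("adipose"), i("arterial_blood")] <- Q[["adipose"]]
  A[i("adipose"), i("adipose")] <- -Q[["adipose"]]
  A[i("venous_blood"), i("kidney")] <- Q[["kidney"]]
  A[i("venous_blood"), i("adipose")] <- Q[["adipose"]]
  A[i("venous_blood"), i("liver")] <- q_liv_out
  A[i("venous_blood"), i("venous_blood")] <- -q_co
  A[i("arterial_blood"), i("lung")] <- q_co
  A[i("arterial_blood"), i("arterial_blood")] <- -q_co
  A[8, i("liver")] <- 1  # AUC state integrates liver plasma conc
  M <- A %*% diag(c(1 / (V * kp), 1))
  i_liv <- i("liver")
  denom_liv <- V[["liver"]] * kp[["liver"]]
  rhs <- function(t, x, p) {
    d <- M %*% x
    cl <- x[i_liv] / denom_liv
    d[i_liv] <- d[i_liv] - vmax_abs * cl / (Km + cl)
    list(d)
  }
  function(dose_mg) {
    x0 <- numeric(8)
    x0[i("venous_blood")] <- dose_mg / mw * 1000
    out <- deSolve::lsoda(x0, c(0, duration), rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    out[nrow(out), 9]
  }
}
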