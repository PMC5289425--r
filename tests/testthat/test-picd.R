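test_that("in vitro AUC is concentration times duration", {
  expect_equal(in_vitro_auc(in_vitro_exposure("d", 10, 24)), 240)
  expect_equal(in_vitro_auc(in_vitro_exposure("d", 0.5, 8,
                                              timepoints_measured = c(2, 8))),
               4)
  # cross-module identity with the trapezoidal AUC of a constant profile
  const <- list(times = c(0, 24), values = c(10, 10))
  expect_equal(in_vitro_auc(in_vitro_exposure("d", 10, 24)),
               compute_auc(const, c(0, 24)))
})

test_that("the equivalent dose scales linearly on an all-linear model", {
  m <- toy_linear_model()
  exp1 <- in_vitro_exposure("drugX", 1, 24)
  d1 <- find_equivalent_dose(m, exp1)
  expect_lt(attr(d1, "auc_relative_error"), 1e-6)
  # doubling the target doubles the dose
  d2 <- find_equivalent_dose(m, in_vitro_exposure("drugX", 2, 24))
  expect_equal(as.numeric(d2) / as.numeric(d1), 2, tolerance = 1e-5)
  # 5-point slope check: dose proportional to target AUC
  targets <- c(0.5, 1, 2, 4, 8)
  doses <- vapply(targets, function(cc)
    as.numeric(find_equivalent_dose(m, in_vitro_exposure("drugX", cc, 24))),
    0)
  slopes <- doses / targets
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-5)
})

test_that("the search returns a probed dose as its own fixed point", {
  m <- toy_linear_model()
  probe <- 7.3
  sim <- simulate_pk(m, dosing_regimen("iv_bolus", probe), t_end = 24)
  auc <- compute_auc(get_profile(sim, compartment = "liver",
                                 subcompartment = "interstitial"), c(0, 24))
  d <- find_equivalent_dose(m, in_vitro_exposure("drugX", auc / 24, 24))
  expect_equal(as.numeric(d), probe, tolerance = 1e-5)
})

test_that("bisection on a saturable model matches a dose-grid oracle", {
  m <- toy_mm_model(vmax = 1500, Km = 5, renal_cl = 30)
  exposure <- in_vitro_exposure("par", 4, 24)
  d <- find_equivalent_dose(m, exposure, method = "bisection",
                            dose_bracket = c(1, 500))
  expect_lt(attr(d, "auc_relative_error"), 1e-6)
  # oracle: scan a fine dose grid around the root (grid-resolution match)
  target <- in_vitro_auc(exposure)
  grid <- seq(0.9 * d, 1.1 * d, length.out = 201)
  aucs <- vapply(grid, function(dd) {
    sim <- simulate_pk(m, dosing_regimen("iv_bolus", dd), t_end = 24,
                       rtol = 1e-8, atol = 1e-10)
    compute_auc(get_profile(sim, compartment = "liver",
                            subcompartment = "interstitial"), c(0, 24))
  }, 0)
  best <- grid[which.min(abs(aucs - target))]
  expect_equal(as.numeric(d), best, tolerance = diff(grid)[1] * 2 / best)
})

test_that("dose-response maps order anchors and apply oral F-scaling", {
  m <- toy_linear_model()
  exposures <- list(low = in_vitro_exposure("drugX", 1, 24),
                    mid = in_vitro_exposure("drugX", 3, 24),
                    high = in_vitro_exposure("drugX", 9, 24))
  genes <- c("g1", "g2")
  resp <- expand.grid(entity = genes, level = c("low", "mid", "high"),
                      time_h = c(8, 24), stringsAsFactors = FALSE)
  resp$response <- seq(0.1, by = 0.05, length.out = nrow(resp))
  map_iv <- build_dose_response_map(m, exposures, resp, route = "iv")
  expect_equal(map_iv$anchors$level, c("low", "mid", "high"))
  expect_true(all(diff(map_iv$anchors$dose_mg) > 0))
  map_po <- build_dose_response_map(m, exposures, resp, route = "oral",
                                    bioavailability = 0.5)
  expect_equal(map_po$anchors$dose_mg, map_iv$anchors$dose_mg / 0.5,
               tolerance = 1e-9)
})

test_that("contextualization interpolates, clamps and fills 2 h as documented", {
  anchors <- data.frame(level = c("low", "high"), dose_mg = c(10, 30),
                        stringsAsFactors = FALSE)
  resp <- expand.grid(entity = c("g1", "g2"), level = c("low", "high"),
                      time_h = c(8, 24), stringsAsFactors = FALSE)
  resp$response <- c(0.2, 0.1, 0.4, 0.3,   # 8 h low/high per gene
                     0.5, 0.2, 0.9, 0.6)   # 24 h
  map <- structure(list(compound_id = "d", anchors = anchors,
                        responses = resp, route = "iv",
                        bioavailability = 1, timepoints = c(8, 24)),
                   class = "dose_response_map")
  at_anchor <- contextualize_response(map, 30)
  r24 <- at_anchor$response
  expect_equal(r24$response[r24$entity == "g1" & r24$time_h == 24], 0.9)
  # midway between anchors: mean of the two anchor responses
  mid <- contextualize_response(map, 20)$response
  expect_equal(mid$response[mid$entity == "g1" & mid$time_h == 8],
               (0.2 + 0.4) / 2)
  # below the first anchor: interpolation toward (0, 0)
  lowd <- contextualize_response(map, 5)$response
  expect_equal(lowd$response[lowd$entity == "g1" & lowd$time_h == 8],
               0.2 * 5 / 10)
  # above range: clamped with a warning
  expect_warning(hi <- contextualize_response(map, 100), "clamped")
  expect_equal(hi$response$response[hi$response$entity == "g1" &
                                      hi$response$time_h == 24], 0.9)
  # 2 h filled as (2/8) of the 8 h value
  expect_true(2 %in% at_anchor$response$time_h)
  expect_equal(r24$response[r24$entity == "g1" & r24$time_h == 2],
               0.9 * 0 + 0.4 * 2 / 8)
})

test_that("contextualizing at an identified dose round-trips the assay responses", {
  m <- toy_linear_model()
  exposures <- list(low = in_vitro_exposure("drugX", 1, 24),
                    high = in_vitro_exposure("drugX", 5, 24))
  resp <- expand.grid(entity = paste0("g", 1:4), level = c("low", "high"),
                      time_h = c(2, 8, 24), stringsAsFactors = FALSE)
  set.seed(3)
  resp$response <- round(runif(nrow(resp), 0, 2), 3)
  map <- build_dose_response_map(m, exposures, resp, route = "iv")
  d_high <- map$anchors$dose_mg[map$anchors$level == "high"]
  ctx <- contextualize_response(map, d_high)$response
  for (tp in c(2, 8, 24)) {
    want <- resp[resp$level == "high" & resp$time_h == tp, ]
    got <- ctx[ctx$time_h == tp, ]
    expect_equal(got$response[match(want$entity, got$entity)],
                 want$response)
  }
})

test_that("predicted response is monotone in dose for monotone anchors", {
  anchors <- data.frame(level = c("low", "high"), dose_mg = c(10, 30))
  resp <- expand.grid(entity = "g1", level = c("low", "high"),
                      time_h = 24, stringsAsFactors = FALSE)
  resp$response <- c(0.2, 0.8)
  map <- structure(list(compound_id = "d", anchors = anchors,
                        responses = resp, route = "iv",
                        bioavailability = 1, timepoints = 24),
                   class = "dose_response_map")
  doses <- seq(0, 40, by = 2.5)
  vals <- vapply(doses, function(d)
    suppressWarnings(contextualize_response(map, d))$response$response[1], 0)
  expect_true(all(diff(vals) >= -1e-12))
})
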