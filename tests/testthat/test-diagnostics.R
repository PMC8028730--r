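test_that("CWRES reduce to (obs - PRED)/sd without random effects", {
  m <- pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
                sigma_prop = 0.243, sigma_add = 0.019)
  synth <- pk_simulate_study(m, small_design(2), seed = 81)
  fit <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  ok <- fit$predictions$BQL < 0.5
  manual <- (fit$predictions$DV[ok] - fit$predictions$PRED[ok]) /
    residual_sd(m, fit$predictions$PRED[ok])
  expect_equal(fit$predictions$CWRES[ok], manual, tolerance = 1e-10)
  # censored observations carry no residual
  expect_true(all(is.na(fit$predictions$CWRES[!ok])))
  expect_equal(sum(!is.na(fit$predictions$CWRES)), sum(ok))
})

test_that("CWRES are calibrated to N(0,1) under the true model", {
  m <- atropine_model()
  synth <- pk_simulate_study(m, pk_study_design(n_subjects = 100),
                             seed = 91)
  fit <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  cw <- fit$predictions$CWRES[!is.na(fit$predictions$CWRES)]
  expect_gt(length(cw), 1000)
  expect_lt(abs(mean(cw)), 0.1)
  expect_gt(sd(cw), 0.9)
  expect_lt(sd(cw), 1.1)
})

test_that("VPC percentiles are ordered and bins partition the data", {
  m <- atropine_model()
  synth <- pk_simulate_study(m, small_design(4), seed = 101)
  fit <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  v <- pk_vpc(fit, n_sim = 100, seed = 7)
  expect_true(all(v$obs_p20 <= v$obs_p50 & v$obs_p50 <= v$obs_p80))
  expect_true(all(v$sim_p20 <= v$sim_p50 & v$sim_p50 <= v$sim_p80))
  usable <- dplyr::filter(synth$data, is.na(ROUTE), TIME > 0, EXCL == 0)
  expect_equal(sum(v$n_obs), nrow(usable))
  expect_error(pk_vpc(fit, n_sim = 50,
                      bin_centers = list(iv_bolus = c(0.1, 99),
                                         depot_bolus = 0.1,
                                         infusion = 5), seed = 1),
               "empty")
})

test_that("simulated percentile bands are stable in n_sim", {
  m <- atropine_model()
  synth <- pk_simulate_study(m, small_design(4), seed = 111)
  fit <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  v1 <- pk_vpc(fit, n_sim = 100, seed = 5)
  v2 <- pk_vpc(fit, n_sim = 400, seed = 5)
  # medians of simulated percentiles agree within Monte Carlo error
  rel <- abs(v1$sim_p50 - v2$sim_p50) / pmax(v2$sim_p50, 0.025)
  expect_lt(stats::median(rel), 0.10)
})

test_that("VPC on self-simulated data covers as expected", {
  m <- atropine_model()
  # large synthetic study with negligible censoring isolates the
  # percentile property from LOQ imputation
  synth <- pk_simulate_study(m, pk_study_design(n_subjects = 60,
                                                loq = 1e-4), seed = 121)
  fit <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  v <- pk_vpc(fit, n_sim = 200, seed = 9)
  # observed medians inside the simulated 20-80 band in >= 90% of bins
  inside <- v$obs_p50 >= v$sim_p20 & v$obs_p50 <= v$sim_p80
  expect_gte(mean(inside), 0.9)

  # pointwise coverage of the 20-80 band ~ 60%
  blocks <- atropk:::subject_blocks(synth$data)
  obs <- purrr::map_dfr(blocks, function(b) {
    tibble::tibble(OCC = b$occ_labels[b$obs[, 5]], TIME = b$obs[, 1],
                   y = ifelse(b$obs[, 3] > 0.5, b$obs[, 4] / 2,
                              b$obs[, 2]))
  })
  occ_route <- c(iv = "iv_bolus", drop = "depot_bolus", inf = "infusion")
  obs$route <- occ_route[obs$OCC]
  keyed <- dplyr::left_join(
    obs, tibble::as_tibble(v),
    by = c("route", TIME = "bin_center")
  )
  cover <- mean(keyed$y >= keyed$sim_p20 & keyed$y <= keyed$sim_p80)
  expect_gt(cover, 0.55)
  expect_lt(cover, 0.65)
})
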