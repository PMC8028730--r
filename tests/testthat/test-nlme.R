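# fixed-effects model (no IIV) used by several likelihood checks
fixed_model <- function() {
  pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
           sigma_prop = 0.243, sigma_add = 0.019)
}

test_that("Laplace -2LL is exact when all variances are zero", {
  m <- fixed_model()
  synth <- pk_simulate_study(atropine_model(), small_design(2), seed = 21)
  l <- pk_neg2ll(synth$data, m)
  direct <- -2 * sum(vapply(unique(synth$data$ID), function(id) {
    oracle_subject_ll(synth$data, m, id)
  }, numeric(1)))
  expect_equal(as.numeric(l), direct, tolerance = 1e-10)
})

test_that("Laplace matches 64-node Gauss-Hermite quadrature within 0.5%", {
  m <- pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
                omega2 = c(Cl = 0.05), sigma_prop = 0.243,
                sigma_add = 0.019)
  gh <- gauss_hermite(64)
  for (seed in c(3, 8)) {
    synth <- pk_simulate_study(m, small_design(1), seed = seed)
    lap <- as.numeric(pk_neg2ll(synth$data, m))
    lls <- vapply(gh$nodes, function(x) {
      oracle_subject_ll(synth$data, m, synth$data$ID[1],
                        c(Cl = sqrt(2 * 0.05) * x))
    }, numeric(1))
    quad <- -2 * log(sum(gh$weights / sqrt(pi) * exp(lls)))
    expect_lt(abs(lap - quad) / abs(quad), 0.005)
  }
})

test_that("likelihood is invariant to subject order", {
  m <- atropine_model()
  synth <- pk_simulate_study(m, small_design(3), seed = 31)
  l1 <- as.numeric(pk_neg2ll(synth$data, m))
  shuffled <- dplyr::arrange(synth$data, dplyr::desc(.data$ID), .data$OCC,
                             is.na(.data$ROUTE), .data$TIME)
  l2 <- as.numeric(pk_neg2ll(shuffled, m))
  expect_lt(abs(l1 - l2), 1e-9)
})

test_that("a BQL point far below the LOQ contributes nothing", {
  # additive sd well below the LOQ, so P(y < LOQ | pred ~ 0) -> 1
  m <- pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
                sigma_prop = 0.243, sigma_add = 0.002)
  base <- tibble::tibble(
    ID = "H1", OCC = "iv", TIME = c(0, 0.25, 0.5),
    ROUTE = c("iv_bolus", NA, NA), AMT = c(1.5, NA, NA), DUR = c(0, NA, NA),
    DV = c(NA, 1.0, 0.5), BQL = c(NA, 0, 0), LOQ = c(NA, 0.05, 0.05),
    BW = 557, EXCL = 0
  )
  # append a censored sample at a time where the prediction is ~ 0
  with_bql <- dplyr::bind_rows(base, tibble::tibble(
    ID = "H1", OCC = "iv", TIME = 40, ROUTE = NA, AMT = NA, DUR = NA,
    DV = NA, BQL = 1, LOQ = 0.05, BW = 557, EXCL = 0
  ))
  expect_equal(as.numeric(pk_neg2ll(with_bql, m)),
               as.numeric(pk_neg2ll(base, m)), tolerance = 1e-10)
})

test_that("the censored likelihood term is monotone in the prediction", {
  # P(y < LOQ | pred) must decrease as the prediction rises through the LOQ
  m <- fixed_model()
  template <- tibble::tibble(
    ID = "H1", OCC = "iv", TIME = c(0, 1), ROUTE = c("iv_bolus", NA),
    AMT = c(NA, NA), DUR = c(0, NA), DV = NA, BQL = c(NA, 1),
    LOQ = c(NA, 0.05), BW = 557, EXCL = 0
  )
  # sweep the dose so the 1 h prediction sweeps through the LOQ
  l <- vapply(c(0.01, 0.05, 0.2, 1, 5), function(dose) {
    d <- template
    d$AMT[1] <- dose
    as.numeric(pk_neg2ll(d, m))
  }, numeric(1))
  expect_true(all(diff(l) > 0))
})

test_that("noise-free identifiable data recover the generating thetas", {
  truth <- pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
                    sigma_prop = 1e-4, sigma_add = 1e-6)
  synth <- pk_simulate_study(truth, small_design(2, loq = 1e-9), seed = 41)
  init <- pk_model(0.5, 1.5, 1.5, 2, 4, 0.6, 0.6, sigma_prop = 1e-4,
                   sigma_add = 1e-6)
  fit <- suppressWarnings(pk_fit(synth$data, init))
  expect_lt(max(abs(fit$model$theta / truth$theta - 1)), 1e-3)
})

test_that("AIC counts estimated fixed and random parameters", {
  m <- atropine_model()
  synth <- pk_simulate_study(m, small_design(2), seed = 51)
  fit <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  expect_equal(fit$npar, 7 + 6 + 2)
  expect_equal(fit$aic, fit$minus2LL + 2 * (7 + 6 + 2))
  g <- glance(fit)
  expect_equal(g$AIC, fit$aic)
  expect_equal(g$n_obs, nrow(fit$predictions))
})

test_that("post-hoc etas shrink to zero as residual noise is inflated", {
  # pure additive error so that inflating sigma_add removes all information
  m <- pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
                omega2 = c(Vc = 0.633, Cl = 0.013, Vt = 0.213, Cld = 0.261,
                           logitF_drop = 7.606, logitF_inf = 1.123),
                sigma_prop = 0, sigma_add = 0.05)
  synth <- pk_simulate_study(m, small_design(3), seed = 61)
  f1 <- suppressWarnings(pk_fit(synth$data, m, estimate = FALSE))
  m_noisy <- m
  m_noisy$sigma_add <- m$sigma_add * 100
  f2 <- suppressWarnings(pk_fit(synth$data, m_noisy, estimate = FALSE))
  expect_lt(max(abs(f2$eta_matrix)), 0.1)
  expect_lt(max(abs(f2$eta_matrix)), max(abs(f1$eta_matrix)) / 10)
  # empirical shrinkage approaches 1 for every random effect
  shr <- purrr::map_dbl(which(m$omega2 > 0), function(k) {
    as.numeric(eta_shrinkage(f2$eta_matrix[, k], m$omega2[k]))
  })
  expect_true(all(shr > 0.9))
})

test_that("fitting refuses the inter-occasion variability config", {
  m <- atropine_model()
  m$iov_cl <- 0.1
  synth <- pk_simulate_study(atropine_model(), small_design(2), seed = 71)
  expect_error(pk_fit(synth$data, m), "inter-occasion")
})
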