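test_that("default design mirrors the study protocol", {
  d <- pk_study_design()
  sched <- design_schedule(d)
  expect_equal(sum(sched$OCC == "iv"), 13L)   # pre-dose + 12 samples
  expect_equal(sum(sched$OCC == "drop"), 13L)
  expect_equal(sum(sched$OCC == "inf"), 11L)  # pre-dose + 10 samples
  # the first post-dose infusion sample is flagged excluded
  inf <- dplyr::filter(sched, OCC == "inf")
  expect_equal(inf$EXCL, c(0, 1, rep(0, 9)))
  expect_equal(d$loq, 0.05)
  # per-kg dose for a 557 kg horse
  expect_equal(d$dose_bolus_ug / 557, 1.499, tolerance = 1e-3)
})

test_that("same seed gives a byte-identical dataset", {
  m <- atropine_model()
  s1 <- pk_simulate_study(m, small_design(2), seed = 161)
  s2 <- pk_simulate_study(m, small_design(2), seed = 161)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- pk_simulate_study(m, small_design(2), seed = 162)
  expect_false(identical(s1$data, s3$data))
})

test_that("zero noise and zero IIV reproduce typical predictions exactly", {
  m <- pk_model(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738,
                sigma_prop = 1e-300, sigma_add = 1e-300)
  synth <- pk_simulate_study(m, small_design(1, loq = 1e-12), seed = 171)
  obs <- dplyr::filter(synth$data, is.na(ROUTE), TIME > 0)
  p <- individual_params(m)
  for (oc in unique(obs$OCC)) {
    o <- dplyr::filter(obs, OCC == oc)
    dose <- dplyr::filter(synth$data, !is.na(ROUTE), OCC == oc)
    expected <- pk_concentration(
      p, pk_doses(dose$TIME, dose$ROUTE, dose$AMT, dose$DUR), o$TIME)
    expect_equal(o$DV, expected, tolerance = 1e-9)
  }
})

test_that("censoring responds to the LOQ and accumulates late", {
  m <- atropine_model()
  n_bql <- function(loq, seed) {
    s <- pk_simulate_study(m, small_design(3, loq = loq), seed = seed)
    sum(s$data$BQL == 1, na.rm = TRUE)
  }
  for (seed in c(181, 182, 183)) {
    expect_gte(n_bql(0.05, seed), n_bql(0.025, seed))
  }
  # BQL fraction rises with time after the bolus doses
  s <- pk_simulate_study(m, pk_study_design(n_subjects = 30), seed = 191)
  obs <- dplyr::filter(s$data, is.na(ROUTE), OCC != "inf", TIME > 0)
  early <- dplyr::filter(obs, TIME <= 1)
  late <- dplyr::filter(obs, TIME >= 4)
  expect_gt(mean(late$BQL), mean(early$BQL))
})

test_that("truth table matches the generating parameters", {
  m <- atropine_model()
  s <- pk_simulate_study(m, small_design(2), seed = 201)
  expect_equal(nrow(s$truth), 2L)
  p1 <- individual_params(
    m, setNames(as.numeric(s$truth[1, paste0("eta_", atropk:::omega_names)]),
                atropk:::omega_names))
  expect_equal(s$truth$Cl[1], p1$Cl)
  expect_equal(s$truth$Vc[1], p1$Vc)
  # generated data refit at the truth as init improves on a mis-specified
  # start (sanity of the generator/likelihood pairing)
  l_truth <- as.numeric(pk_neg2ll(s$data, m))
  wrong <- m
  wrong$theta[["tvCl"]] <- 4
  expect_gt(as.numeric(pk_neg2ll(s$data, wrong)), l_truth)
})
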