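test_that("iv bolus initial condition and linearity in dose", {
  p <- table1_params()
  c0 <- pk_concentration(p, pk_doses(0, "iv_bolus", 1.5), 1e-9)
  expect_equal(c0, 1.5 / 0.646, tolerance = 1e-6)

  times <- c(0.1, 0.5, 1, 3, 6)
  doses <- pk_doses(c(0, 2, 4), c("iv_bolus", "depot_bolus", "depot_bolus"),
                    c(1.5, 1.5, 1.5))
  doses2 <- dplyr::mutate(doses, amount = 2 * amount)
  expect_equal(pk_concentration(p, doses2, times),
               2 * pk_concentration(p, doses, times))
})

test_that("closed forms match the ODE oracle for all three routes", {
  p <- table1_params()
  times <- c(0.05, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
  for (route in c("iv_bolus", "depot_bolus", "infusion")) {
    doses <- pk_doses(0, route, 1.5,
                      duration = if (route == "infusion") 24 else 0)
    cf <- pk_concentration(p, doses, times)
    ode <- ode_conc(p, doses, times)
    expect_lt(max(abs(cf - ode) / ode), 1e-8)
  }
})

test_that("superposition: multi-dose profile is the sum of shifted doses", {
  p <- table1_params()
  times <- seq(0.25, 12, by = 0.25)
  dose_times <- c(0, 1, 3, 6)
  multi <- pk_concentration(
    p, pk_doses(dose_times, "depot_bolus", 1.5), times)
  single_sum <- Reduce(`+`, lapply(dose_times, function(td) {
    c0 <- pk_concentration(p, pk_doses(0, "depot_bolus", 1.5),
                           pmax(times - td, 0))
    c0[times <= td] <- 0
    c0
  }))
  expect_equal(multi, single_sum, tolerance = 1e-12)
})

test_that("mass balance: Cl * AUC = F * dose for each route", {
  p <- table1_params()
  for (route in c("iv_bolus", "depot_bolus", "infusion")) {
    doses <- pk_doses(0, route, 5,
                      duration = if (route == "infusion") 24 else 0)
    auc <- stats::integrate(function(t) pk_concentration(p, doses, t),
                            0, Inf, rel.tol = 1e-10,
                            subdivisions = 500L)$value
    f_eff <- switch(route, iv_bolus = 1,
                    depot_bolus = 1 / (1 + exp(-0.781)),
                    infusion = 1 / (1 + exp(-0.738)))
    expect_equal(p$Cl * auc, f_eff * 5, tolerance = 1e-6)
  }
})

test_that("constant infusion approaches the analytic steady state", {
  p <- table1_params()
  # long infusion: C at the end ~ Css = F_inf * rate / Cl
  doses <- pk_doses(0, "infusion", 5 / 24 * 500, duration = 500)
  css <- (1 / (1 + exp(-0.738))) * (5 / 24) / 1.905
  expect_equal(pk_concentration(p, doses, 499), css, tolerance = 1e-4)
  expect_equal(css, 0.0739, tolerance = 2e-3)
})

test_that("secondary parameters reproduce the published transforms", {
  sec <- pk_secondary(table1_params())
  expect_equal(sec$F_drop, 0.685, tolerance = 5e-3)
  expect_equal(sec$F_inf, 0.676, tolerance = 5e-3)
  expect_equal(sec$t_half_abs, 0.117, tolerance = 5e-3)
  expect_equal(sec$Vss, 1.794, tolerance = 1e-12)
  expect_equal(sec$MRT, 1.794 / 1.905, tolerance = 1e-12)
  # beta equals the smaller-magnitude eigenvalue of the disposition matrix
  p <- table1_params()
  k10 <- p$Cl / p$Vc; k12 <- p$Cld / p$Vc; k21 <- p$Cld / p$Vt
  lam <- eigen(matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2))$values
  expect_equal(sec$beta, min(abs(lam)), tolerance = 1e-12)
  expect_equal(sec$alpha, max(abs(lam)), tolerance = 1e-12)
})

test_that("beta tends to Cl/Vss as distribution becomes instantaneous", {
  p <- table1_params()
  p_fast <- pk_params(p$Vc, p$Vt, p$Cl, 1e6, p$ka, p$logitF_drop,
                      p$logitF_inf)
  sec <- pk_secondary(p_fast)
  expect_equal(sec$beta, p$Cl / (p$Vc + p$Vt), tolerance = 1e-4)
})

test_that("absorption half-life is strictly decreasing in ka", {
  p <- table1_params()
  kas <- c(0.5, 1, 2, 5.948, 20, 100)
  th <- vapply(kas, function(k) {
    pk_secondary(pk_params(p$Vc, p$Vt, p$Cl, p$Cld, k, p$logitF_drop,
                           p$logitF_inf))$t_half_abs
  }, numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("depot profile is continuous through the repeated-root regime", {
  p <- table1_params()
  alpha <- pk_secondary(p)$alpha
  times <- c(0.05, 0.2, 0.5, 1)
  base <- pk_concentration(
    pk_params(p$Vc, p$Vt, p$Cl, p$Cld, alpha * (1 + 1e-6), p$logitF_drop,
              p$logitF_inf),
    pk_doses(0, "depot_bolus", 1.5), times)
  for (eps in c(1e-9, 1e-12, 0)) {
    near <- pk_concentration(
      pk_params(p$Vc, p$Vt, p$Cl, p$Cld, alpha * (1 + eps), p$logitF_drop,
                p$logitF_inf),
      pk_doses(0, "depot_bolus", 1.5), times)
    expect_true(all(is.finite(near)))
    expect_equal(near, base, tolerance = 1e-4)
  }
})

test_that("regimen profiles scale linearly and report interval summaries", {
  p <- table1_params()
  r1 <- pk_regimen_profile(p, pk_regimen("depot_bolus", 0.5, interval = 6,
                                         horizon = 24), grid = 0.01)
  r3 <- pk_regimen_profile(p, pk_regimen("depot_bolus", 1.5, interval = 6,
                                         horizon = 24), grid = 0.01)
  expect_equal(3 * r1$profile$conc, r3$profile$conc, tolerance = 1e-12)
  expect_equal(nrow(r3$intervals), 4L)
  # q6h washout: every pre-dose concentration sits below the LOQ
  expect_true(all(r3$intervals$trough < 0.05))
  expect_error(pk_regimen_profile(p, pk_regimen("depot_bolus", 1.5,
                                                interval = 6), grid = -1),
               "grid")
})

test_that("invalid structural parameters and doses are rejected", {
  expect_error(pk_params(-1, 1, 1, 1, 1, 0, 0), "positive")
  expect_error(pk_params(1, 1, 1, 1, 1, Inf, 0), "finite")
  expect_error(pk_doses(0, "oral", 1), "unknown route")
  expect_error(pk_doses(0, "infusion", 1, duration = 0), "duration")
  expect_error(pk_doses(0, "iv_bolus", 1, duration = 2), "duration")
})
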