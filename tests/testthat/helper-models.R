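# shared fixtures: published typical values and small synthetic designs

table1_params <- function() {
  pk_params(Vc = 0.646, Vt = 1.148, Cl = 1.905, Cld = 2.477, ka = 5.948,
            logitF_drop = 0.781, logitF_inf = 0.738)
}

# a light design for fast fitting tests: fewer subjects, same 3 occasions
small_design <- function(n = 3, loq = 0.05) {
  pk_study_design(n_subjects = n, loq = loq)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix);
# independent of the package's Laplace machinery
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
}

# direct (no Laplace) censored log-likelihood of one subject at fixed etas,
# written independently in R as an oracle for the C++ likelihood
oracle_subject_ll <- function(data, model, id, eta = numeric()) {
  blocks <- atropk:::subject_blocks(data)
  b <- blocks[[match(id, purrr::map_chr(blocks, "id"))]]
  p <- individual_params(model, eta)
  cc <- numeric(nrow(b$obs))
  for (o in unique(b$obs[, 5])) {
    sel <- b$obs[, 5] == o
    dsel <- b$doses[, 5] == o
    dd <- b$doses[dsel, , drop = FALSE]
    r <- atropk:::disposition_rates(p)
    cc[sel] <- vapply(b$obs[sel, 1], function(t) {
      tot <- 0
      for (j in seq_len(nrow(dd))) {
        s <- t - dd[j, 1]
        if (s <= 0) next
        tot <- tot + oracle_conc_one(p, r, dd[j, 2], dd[j, 3], dd[j, 4], s)
      }
      max(tot, 0)
    }, numeric(1))
  }
  sdv <- sqrt(model$sigma_prop^2 * cc^2 + model$sigma_add^2)
  sum(ifelse(b$obs[, 3] > 0.5,
             pnorm(b$obs[, 4], cc, sdv, log.p = TRUE),
             dnorm(b$obs[, 2], cc, sdv, log = TRUE)))
}

# single-dose concentration written from the textbook biexponential forms
oracle_conc_one <- function(p, r, route, amt, dur, s) {
  a <- r$alpha; b <- r$beta; k21 <- r$k21
  A <- (a - k21) / (p$Vc * (a - b))
  B <- (k21 - b) / (p$Vc * (a - b))
  if (route == 1) {
    amt * (A * exp(-a * s) + B * exp(-b * s))
  } else if (route == 2) {
    Fd <- 1 / (1 + exp(-p$logitF_drop))
    ka <- p$ka
    Fd * amt * ka / p$Vc * (
      (k21 - a) * exp(-a * s) / ((ka - a) * (b - a)) +
      (k21 - b) * exp(-b * s) / ((ka - b) * (a - b)) +
      (k21 - ka) * exp(-ka * s) / ((a - ka) * (b - ka)))
  } else {
    Fi <- 1 / (1 + exp(-p$logitF_inf))
    rate <- Fi * amt / dur
    se <- min(s, dur)
    rate * (A / a * (1 - exp(-a * se)) * exp(-a * max(s - dur, 0)) +
            B / b * (1 - exp(-b * se)) * exp(-b * max(s - dur, 0)))
  }
}

# numeric ODE oracle for the three-compartment (depot/central/peripheral)
# linear system, used to validate the closed forms
ode_conc <- function(p, doses, times, rtol = 1e-12, atol = 1e-14) {
  skip_if_not_installed("deSolve")
  k10 <- p$Cl / p$Vc; k12 <- p$Cld / p$Vc; k21 <- p$Cld / p$Vt
  Fd <- 1 / (1 + exp(-p$logitF_drop))
  Fi <- 1 / (1 + exp(-p$logitF_inf))
  rhs <- function(t, y, parms) {
    inf <- 0
    for (j in seq_len(nrow(doses))) {
      if (doses$route[j] == "infusion" && t > doses$time[j] &&
          t <= doses$time[j] + doses$duration[j]) {
        inf <- inf + Fi * doses$amount[j] / doses$duration[j]
      }
    }
    dAd <- -p$ka * y[1]
    dAc <- p$ka * y[1] + inf - (k10 + k12) * y[2] + k21 * y[3]
    dAt <- k12 * y[2] - k21 * y[3]
    list(c(dAd, dAc, dAt))
  }
  bolus_events <- doses[doses$route != "infusion", , drop = FALSE]
  ev <- NULL
  if (nrow(bolus_events)) {
    ev <- data.frame(
      var = ifelse(bolus_events$route == "iv_bolus", "Ac", "Ad"),
      time = bolus_events$time,
      value = ifelse(bolus_events$route == "iv_bolus",
                     bolus_events$amount, Fd * bolus_events$amount),
      method = "add"
    )
    ev <- ev[order(ev$time), ]
  }
  tt <- sort(unique(c(0, doses$time, times)))
  y0 <- c(Ad = 0, Ac = 0, At = 0)
  out <- if (is.null(ev)) {
    deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
  } else {
    deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol, atol = atol,
                   events = list(data = ev))
  }
  out[match(times, out[, 1]), "Ac"] / p$Vc
}
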