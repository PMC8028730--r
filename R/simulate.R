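#' Dosing regimen
#'
#' A topical dosing schedule for simulation: repeated eye-drop boluses at a
#' fixed interval, or a constant-rate ocular infusion.
#'
#' @param route `"depot_bolus"` or `"infusion"`.
#' @param amount ug/kg per administration for boluses; total ug/kg delivered
#'   over `duration` for an infusion.
#' @param interval Dosing interval (h), bolus schedules only.
#' @param duration Infusion duration (h), infusions only.
#' @param horizon Simulation horizon (h).
#'
#' @return A `pk_regimen` object.
#' @export
#' @examples
#' pk_regimen("depot_bolus", amount = 1.5, interval = 1, horizon = 24)
#' pk_regimen("infusion", amount = 5, duration = 24, horizon = 48)
pk_regimen <- function(route = c("depot_bolus", "infusion"), amount,
                       interval = NULL, duration = NULL, horizon = 24) {
  route <- match.arg(route)
  if (!is.numeric(amount) || amount <= 0) abort("amount must be > 0")
  if (horizon <= 0) abort("horizon must be > 0")
  if (route == "depot_bolus") {
    if (is.null(interval) || interval <= 0 || horizon < interval) {
      abort("bolus regimens need horizon >= interval > 0")
    }
    duration <- 0
  } else {
    if (is.null(duration) || duration <= 0) {
      abort("infusion regimens need duration > 0")
    }
    interval <- NA_real_
  }
  structure(list(route = route, amount = amount, interval = interval,
                 duration = duration, horizon = horizon),
            class = "pk_regimen")
}

format_regimen <- function(r) {
  if (r$route == "infusion") {
    sprintf("infusion %.3g ug/kg over %g h (horizon %g h)", r$amount,
            r$duration, r$horizon)
  } else {
    sprintf("eye drops %.3g ug/kg q%gh (horizon %g h)", r$amount,
            r$interval, r$horizon)
  }
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat(format_regimen(x), "\n")
  invisible(x)
}

regimen_doses <- function(regimen) {
  if (regimen$route == "infusion") {
    pk_doses(0, "infusion", regimen$amount, regimen$duration)
  } else {
    times <- seq(0, regimen$horizon - 1e-9, by = regimen$interval)
    pk_doses(times, "depot_bolus", regimen$amount)
  }
}

#' Deterministic typical-value regimen simulation
#'
#' Solves the model at the typical values (all etas fixed to 0, no residual
#' noise) for a dosing regimen and summarises each dosing interval by peak
#' and trough; for infusions the analytic steady-state concentration
#' `Css = F_inf * rate / Cl` is reported alongside the profile.
#'
#' @param model A [pk_model()] object.
#' @param regimen A [pk_regimen()] object.
#' @param grid Evaluation grid step (h).
#'
#' @return A `pk_profile` object (see [pk_regimen_profile()]); for infusions
#'   with element `css` added.
#' @export
#' @examples
#' sim <- pk_simulate_typical(atropine_model(),
#'                            pk_regimen("depot_bolus", 1.5, interval = 1))
#' tail(sim$intervals, 2)
pk_simulate_typical <- function(model, regimen, grid = 0.005) {
  stopifnot(inherits(model, "pk_model"))
  out <- pk_regimen_profile(individual_params(model), regimen, grid)
  if (regimen$route == "infusion") {
    out$css <- ilogit(model$theta[["tvLogitFinf"]]) *
      (regimen$amount / regimen$duration) / model$theta[["tvCl"]]
  }
  out
}

#' Monte Carlo population regimen simulation
#'
#' Draws `n` individual parameter sets from the inter-individual distribution
#' (etas from the diagonal omega; no residual noise, i.e. individual-level
#' predictions) and simulates the regimen for each. For constant-rate
#' infusions the per-horse steady-state concentration is computed exactly as
#' `F_inf_i * rate / Cl_i`, avoiding horizon-truncation bias; for bolus
#' schedules full profiles are simulated and summarised per time point.
#'
#' @param model A [pk_model()] object.
#' @param regimen A [pk_regimen()] object.
#' @param n Number of simulated horses.
#' @param seed Optional integer seed.
#' @param grid Grid step (h) for bolus-schedule profiles.
#'
#' @return A list of class `pk_popsim`: for infusions, `css` (tibble `horse`,
#'   `css`) and `quantiles` (5th/50th/95th percentiles of steady-state
#'   concentration); for bolus schedules, `quantiles` is a tibble of
#'   per-time-point 5th/50th/95th percentile bands.
#' @export
#' @examples
#' reg <- pk_regimen("infusion", amount = 5, duration = 24)
#' pk_simulate_population(atropine_model(), reg, n = 200, seed = 1)$quantiles
pk_simulate_population <- function(model, regimen, n = 1000, seed = NULL,
                                   grid = 0.05) {
  stopifnot(inherits(model, "pk_model"), n >= 1)
  check_seed(seed)
  active <- which(model$omega2 > 0)
  etas <- matrix(0, n, 6)
  for (k in active) etas[, k] <- rnorm(n, sd = sqrt(model$omega2[k]))
  params <- purrr::map(seq_len(n), function(i) {
    individual_params(model, setNames(etas[i, ], omega_names))
  })

  if (regimen$route == "infusion") {
    rate <- regimen$amount / regimen$duration
    css <- purrr::map_dbl(params, function(p) {
      ilogit(p$logitF_inf) * rate / p$Cl
    })
    q <- quantile(css, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
    out <- list(
      css = tibble::tibble(horse = seq_len(n), css = css),
      quantiles = tibble::tibble(quantile = c(0.05, 0.5, 0.95), css = q),
      regimen = regimen, n = n
    )
  } else {
    times <- seq(0, regimen$horizon, by = grid)
    doses <- regimen_doses(regimen)
    profs <- vapply(params, function(p) pk_concentration(p, doses, times),
                    numeric(length(times)))
    qmat <- apply(profs, 1, quantile, probs = c(0.05, 0.5, 0.95), type = 7)
    out <- list(
      quantiles = tibble::tibble(time = times, q5 = qmat[1, ],
                                 q50 = qmat[2, ], q95 = qmat[3, ]),
      regimen = regimen, n = n
    )
  }
  structure(out, class = "pk_popsim")
}

#' @export
print.pk_popsim <- function(x, ...) {
  cat("Population simulation (n =", x$n, "):", format_regimen(x$regimen),
      "\n")
  print(x$quantiles, n = 6)
  invisible(x)
}

#' @rdname pk_simulate_population
#' @param object,... A `pk_popsim` object (for `autoplot`).
#' @method autoplot pk_popsim
#' @export
autoplot.pk_popsim <- function(object, ...) {
  if (object$regimen$route == "infusion") {
    ggplot2::ggplot(object$css, ggplot2::aes(.data$css)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::geom_vline(xintercept = object$quantiles$css,
                          linetype = c(2, 1, 2), colour = "red") +
      ggplot2::labs(x = "Steady-state conc. (µg/L)", y = "Horses",
                    title = format_regimen(object$regimen))
  } else {
    ggplot2::ggplot(object$quantiles, ggplot2::aes(.data$time)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q5, ymax = .data$q95),
                           alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$q50)) +
      ggplot2::labs(x = "Time (h)", y = "Atropine plasma conc. (µg/L)",
                    title = format_regimen(object$regimen))
  }
}
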