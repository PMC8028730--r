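#' Structural (per-individual) two-compartment parameters
#'
#' Bundles the disposition parameters of the two-compartment model with
#' first-order ocular absorption: central and peripheral volumes, plasma and
#' inter-compartmental distribution clearances, the absorption rate constant,
#' and the logit-scale bioavailabilities of the two topical routes. All
#' volumes and clearances are per kg body weight, so a dose in ug/kg yields
#' concentrations in ug/L.
#'
#' @param Vc Central volume of distribution (L/kg).
#' @param Vt Peripheral volume of distribution (L/kg).
#' @param Cl Plasma clearance (L/kg/h).
#' @param Cld Inter-compartmental distribution clearance (L/kg/h).
#' @param ka First-order absorption rate constant from the ocular deposit
#'   (1/h).
#' @param logitF_drop,logitF_inf Logit-scale bioavailability of the eye-drop
#'   and infusion routes; back-transform with the inverse logit.
#'
#' @return A `pk_params` object (named list).
#' @export
#' @examples
#' pk_params(Vc = 0.646, Vt = 1.148, Cl = 1.905, Cld = 2.477,
#'           ka = 5.948, logitF_drop = 0.781, logitF_inf = 0.738)
pk_params <- function(Vc, Vt, Cl, Cld, ka, logitF_drop, logitF_inf) {
  p <- list(Vc = Vc, Vt = Vt, Cl = Cl, Cld = Cld, ka = ka,
            logitF_drop = logitF_drop, logitF_inf = logitF_inf)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    abort("all structural parameters must be finite")
  }
  if (any(vals[c("Vc", "Vt", "Cl", "Cld", "ka")] <= 0)) {
    abort("Vc, Vt, Cl, Cld and ka must be strictly positive")
  }
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment structural parameters (per kg):\n")
  print(unlist(x))
  invisible(x)
}

par_vector <- function(params) {
  c(params$Vc, params$Vt, params$Cl, params$Cld, params$ka,
    ilogit(params$logitF_drop), ilogit(params$logitF_inf))
}

# hybrid micro rate constants and exponents of the disposition system
disposition_rates <- function(params) {
  k10 <- params$Cl / params$Vc
  k12 <- params$Cld / params$Vc
  k21 <- params$Cld / params$Vt
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Dose event table
#'
#' Builds a validated dose-event tibble used by [pk_concentration()]. All
#' amounts are ug of atropine per kg body weight; an infusion delivers its
#' amount at a constant (zero-order) rate over `duration` hours.
#'
#' @param time Dose times (hours).
#' @param route One of `"iv_bolus"`, `"depot_bolus"`, `"infusion"` (recycled).
#' @param amount Dose amounts (ug/kg).
#' @param duration Infusion durations (h); must be 0 for bolus routes and
#'   positive for infusions.
#'
#' @return A tibble with columns `time`, `route`, `amount`, `duration`.
#' @export
pk_doses <- function(time, route, amount, duration = 0) {
  d <- tibble::tibble(time = as.numeric(time), route = route,
                      amount = as.numeric(amount),
                      duration = as.numeric(duration))
  route_code(d$route) # validates
  if (any(d$time < 0)) abort("dose times must be >= 0")
  if (any(d$amount <= 0)) abort("dose amounts must be > 0")
  bad <- (d$route == "infusion") != (d$duration > 0)
  if (any(bad)) abort("duration must be > 0 exactly for infusion doses")
  d
}

#' Closed-form concentration-time profile
#'
#' Evaluates the central-compartment concentration of the two-compartment
#' model for an arbitrary set of dose events by superposition of the
#' closed-form single-dose solutions (the model is linear). Eye-drop boluses
#' enter a depot emptying at rate `ka` and are scaled by the drop
#' bioavailability; infusions are zero-order inputs scaled by the infusion
#' bioavailability. When the absorption rate constant nearly coincides with a
#' disposition exponent the evaluation switches to the limiting
#' (repeated-root) form, keeping the profile finite and continuous.
#'
#' @param params A [pk_params()] object.
#' @param doses A dose table from [pk_doses()] (or a data frame with the same
#'   columns).
#' @param times Numeric vector of times (h, >= 0).
#'
#' @return Numeric vector of concentrations (ug/L), one per time.
#' @export
#' @examples
#' p <- pk_params(0.646, 1.148, 1.905, 2.477, 5.948, 0.781, 0.738)
#' pk_concentration(p, pk_doses(0, "iv_bolus", 1.5), c(0.05, 0.5, 2))
pk_concentration <- function(params, doses, times) {
  stopifnot(inherits(params, "pk_params"))
  if (any(times < 0)) abort("times must be >= 0")
  dm <- cbind(doses$time, route_code(doses$route), doses$amount,
              doses$duration)
  cpp_conc(par_vector(params), dm, as.numeric(times))
}

#' Secondary (derived) pharmacokinetic parameters
#'
#' Transforms the structural parameters into the reported secondary
#' quantities: bioavailabilities on the probability scale, the distribution
#' (alpha) and terminal (beta) exponents with their half-lives, the
#' absorption half-life, the steady-state volume of distribution
#' (`Vss = Vc + Vt`) and the mean residence time (`MRT = Vss / Cl`). `beta`
#' is the smaller root of the disposition quadratic; `alpha` the companion
#' (larger) root.
#'
#' @param params A [pk_params()] object.
#'
#' @return A one-row tibble with columns `F_drop`, `F_inf`, `alpha`, `beta`,
#'   `t_half_alpha`, `t_half_beta`, `t_half_abs`, `Vss`, `MRT`.
#' @export
pk_secondary <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  r <- disposition_rates(params)
  if (r$beta <= 0) abort("degenerate disposition system: beta <= 0")
  tibble::tibble(
    F_drop = ilogit(params$logitF_drop),
    F_inf = ilogit(params$logitF_inf),
    alpha = r$alpha,
    beta = r$beta,
    t_half_alpha = log(2) / r$alpha,
    t_half_beta = log(2) / r$beta,
    t_half_abs = log(2) / params$ka,
    Vss = params$Vc + params$Vt,
    MRT = (params$Vc + params$Vt) / params$Cl
  )
}

#' Multiple-dose regimen profile with per-interval summaries
#'
#' Expands a dosing regimen into individual dose events, evaluates the
#' concentration profile on a regular grid, and summarises each dosing
#' interval by its peak and its trough (the concentration at the end of the
#' interval, immediately before the next dose). An interval is flagged as at
#' steady state once its trough differs from the previous one by less than
#' 1e-3 relative.
#'
#' @param params A [pk_params()] object.
#' @param regimen A [pk_regimen()] object.
#' @param grid Time step of the evaluation grid (h, > 0). The default 0.005 h
#'   (18 s) resolves the sharp absorption peaks.
#'
#' @return A list of class `pk_profile` with elements `profile` (tibble
#'   `time`, `conc`) and `intervals` (tibble `interval`, `start`, `end`,
#'   `peak`, `trough`, `steady_state`).
#' @export
pk_regimen_profile <- function(params, regimen, grid = 0.005) {
  stopifnot(inherits(params, "pk_params"), inherits(regimen, "pk_regimen"))
  if (grid <= 0) abort("grid step must be > 0")
  doses <- regimen_doses(regimen)
  times <- seq(0, regimen$horizon, by = grid)
  if (tail(times, 1) < regimen$horizon) times <- c(times, regimen$horizon)
  conc <- pk_concentration(params, doses, times)
  profile <- tibble::tibble(time = times, conc = conc)

  if (regimen$route == "infusion") {
    css <- ilogit(params$logitF_inf) * (regimen$amount / regimen$duration) /
      params$Cl
    intervals <- tibble::tibble(
      interval = 1L, start = 0, end = regimen$horizon,
      peak = max(conc), trough = conc[length(conc)],
      steady_state = abs(conc[length(conc)] - css) < 1e-3 * css
    )
  } else {
    starts <- doses$time
    ends <- c(starts[-1], regimen$horizon)
    intervals <- purrr::map2_dfr(starts, ends, function(s, e) {
      sel <- times >= s & times <= e
      tibble::tibble(start = s, end = e, peak = max(conc[sel]),
                     trough = conc[sel][sum(sel)])
    })
    intervals <- dplyr::mutate(
      intervals,
      interval = dplyr::row_number(),
      steady_state = c(FALSE, abs(diff(.data$trough)) <
                         1e-3 * head(.data$trough, -1)),
      .before = 1
    )
  }
  structure(list(profile = profile, intervals = intervals,
                 regimen = regimen),
            class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat("Regimen profile:", format_regimen(x$regimen), "\n")
  print(x$intervals, n = 5)
  invisible(x)
}

#' @rdname pk_regimen_profile
#' @param object,... A `pk_profile` object (for `autoplot`).
#' @method autoplot pk_profile
#' @export
autoplot.pk_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$time, .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Atropine plasma conc. (µg/L)",
                  title = format_regimen(object$regimen))
}
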