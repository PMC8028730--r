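#' Study design for synthetic data generation
#'
#' Describes the crossover design the generator emulates. The defaults mirror
#' the six-horse experiment this package models: every horse receives, on
#' separate occasions, an intravenous bolus and a topical eye-drop bolus of
#' 835 ug atropine (1 mg atropine sulfate), and a 24-h constant-rate ocular
#' infusion of 120 ug/h atropine (0.14 mg/h atropine sulfate); bolus
#' occasions are sampled at 5-420 min, the infusion occasion at 30-1440 min,
#' with a pre-dose sample each. The sulfate-to-base conversion (factor 0.835)
#' is already applied to the default amounts; doses are converted to ug/kg at
#' generation time using each horse's body weight. The first (30 min)
#' infusion sample is flagged excluded, reflecting the spurious bolus that
#' activating the infusion pump can deliver.
#'
#' @param n_subjects Number of horses.
#' @param bw_range Body-weight range (kg); weights are drawn uniformly.
#' @param dose_bolus_ug Total atropine dose (ug) for the IV and drop
#'   occasions.
#' @param infusion_rate_ug_h Infusion rate (ug atropine/h).
#' @param infusion_duration_h Infusion duration (h).
#' @param loq Lower limit of quantification (ug/L).
#' @param bolus_times_min,infusion_times_min Post-dose sampling schedules
#'   (minutes), strictly increasing.
#' @param discard_first_infusion_sample Flag the first infusion sample
#'   `EXCL = 1`.
#'
#' @return A list of class `pk_design`.
#' @export
pk_study_design <- function(n_subjects = 6, bw_range = c(502, 642),
                            dose_bolus_ug = 835, infusion_rate_ug_h = 120,
                            infusion_duration_h = 24, loq = 0.05,
                            bolus_times_min = c(5, 10, 15, 20, 40, 60, 120,
                                                180, 240, 300, 360, 420),
                            infusion_times_min = c(30, 60, 180, 240, 300,
                                                   420, 540, 660, 780, 1440),
                            discard_first_infusion_sample = TRUE) {
  stopifnot(n_subjects >= 1, loq > 0, all(diff(bolus_times_min) > 0),
            all(diff(infusion_times_min) > 0), all(bw_range > 0),
            bw_range[2] >= bw_range[1])
  structure(list(
    n_subjects = n_subjects, bw_range = bw_range,
    dose_bolus_ug = dose_bolus_ug,
    infusion_rate_ug_h = infusion_rate_ug_h,
    infusion_duration_h = infusion_duration_h, loq = loq,
    bolus_times_min = bolus_times_min,
    infusion_times_min = infusion_times_min,
    discard_first_infusion_sample = discard_first_infusion_sample
  ), class = "pk_design")
}

#' Occasion schedules of a design
#'
#' One row per scheduled sample (pre-dose included) per occasion.
#'
#' @param design A [pk_study_design()].
#'
#' @return A tibble with columns `OCC`, `TIME` (h) and `EXCL`.
#' @export
design_schedule <- function(design) {
  stopifnot(inherits(design, "pk_design"))
  bolus <- tibble::tibble(TIME = c(0, design$bolus_times_min / 60),
                          EXCL = 0)
  inf <- tibble::tibble(
    TIME = c(0, design$infusion_times_min / 60),
    EXCL = as.numeric(design$discard_first_infusion_sample *
                        (seq_along(TIME) == 2))
  )
  dplyr::bind_rows(
    dplyr::mutate(bolus, OCC = "iv", .before = 1),
    dplyr::mutate(bolus, OCC = "drop", .before = 1),
    dplyr::mutate(inf, OCC = "inf", .before = 1)
  )
}

#' Generate a synthetic study dataset
#'
#' Simulates the full data-generating process of the population model on a
#' study design: per horse, one eta vector drawn from the diagonal omega and
#' shared across the three occasions (plus, if `model$iov_cl > 0`,
#' independent per-occasion deviations on clearance), true profiles from the
#' closed-form model, combined proportional-plus-additive residual noise,
#' truncation of negative simulated concentrations at zero, and censoring of
#' values below the LOQ as BQL records. The generating etas and individual
#' parameters are returned as a separate truth table so that the dataset
#' itself is schema-identical to a real study export.
#'
#' @param model A [pk_model()] object (the generating truth).
#' @param design A [pk_study_design()].
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#'
#' @return A list with elements `data` (event-record tibble) and `truth`
#'   (tibble of body weights, etas and individual parameters).
#' @export
#' @examples
#' synth <- pk_simulate_study(atropine_model(), pk_study_design(), seed = 1)
#' dplyr::count(synth$data, OCC, dose = !is.na(ROUTE))
pk_simulate_study <- function(model, design = pk_study_design(),
                              seed = NULL) {
  stopifnot(inherits(model, "pk_model"), inherits(design, "pk_design"))
  check_seed(seed)
  n <- design$n_subjects
  ids <- sprintf("H%02d", seq_len(n))
  bw <- runif(n, design$bw_range[1], design$bw_range[2])
  active <- which(model$omega2 > 0)
  etas <- matrix(0, n, 6, dimnames = list(NULL, omega_names))
  for (k in active) etas[, k] <- rnorm(n, sd = sqrt(model$omega2[k]))
  sched <- design_schedule(design)
  occs <- c("iv", "drop", "inf")

  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    amt_bolus <- design$dose_bolus_ug / bw[i]
    amt_inf <- design$infusion_rate_ug_h * design$infusion_duration_h / bw[i]
    dose_tbl <- tibble::tibble(
      OCC = occs,
      TIME = 0,
      ROUTE = c("iv_bolus", "depot_bolus", "infusion"),
      AMT = c(amt_bolus, amt_bolus, amt_inf),
      DUR = c(0, 0, design$infusion_duration_h)
    )
    p_base <- individual_params(model, setNames(etas[i, ], omega_names))
    obs <- purrr::map_dfr(occs, function(oc) {
      p <- p_base
      if (model$iov_cl > 0) { # optional between-occasion deviation on Cl
        p$Cl <- p$Cl * exp(rnorm(1, sd = model$iov_cl))
      }
      st <- dplyr::filter(sched, .data$OCC == oc)
      d <- dplyr::filter(dose_tbl, .data$OCC == oc)
      doses <- pk_doses(d$TIME, d$ROUTE, d$AMT, d$DUR)
      cc <- numeric(nrow(st))
      post <- st$TIME > 0
      cc[post] <- pk_concentration(p, doses, st$TIME[post])
      y <- cc * (1 + rnorm(length(cc), sd = model$sigma_prop)) +
        rnorm(length(cc), sd = model$sigma_add)
      y[!post] <- 0 # pre-dose samples are drug-free
      y <- pmax(y, 0)
      bql <- as.numeric(y < design$loq)
      tibble::tibble(OCC = oc, TIME = st$TIME, ROUTE = NA_character_,
                     AMT = NA_real_, DUR = NA_real_,
                     DV = ifelse(bql == 1, NA_real_, y), BQL = bql,
                     LOQ = design$loq, EXCL = st$EXCL)
    })
    dose_rows <- dplyr::mutate(dose_tbl, DV = NA_real_, BQL = NA_real_,
                               LOQ = NA_real_, EXCL = 0)
    rows[[i]] <- dplyr::mutate(dplyr::bind_rows(dose_rows, obs),
                               ID = ids[i], BW = bw[i])
    truth[[i]] <- dplyr::bind_cols(
      tibble::tibble(ID = ids[i], BW = bw[i]),
      tibble::as_tibble(as.list(setNames(etas[i, ],
                                         paste0("eta_", omega_names)))),
      tibble::as_tibble(unclass(p_base))
    )
  }
  data <- dplyr::bind_rows(rows)[dataset_cols]
  data <- dplyr::arrange(data, .data$ID, .data$OCC, is.na(.data$ROUTE),
                         .data$TIME)
  validate_pk_dataset(data)
  list(data = data, truth = dplyr::bind_rows(truth))
}
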