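#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement (a subject's occasions travel
#' together, preserving the crossover structure), refits the population model
#' on each replicate starting from the original point estimate, and
#' summarises every primary parameter and the secondary parameters derived
#' from each replicate's typical values by their median, CV% and 2.5/97.5
#' percentiles. Computing the secondary parameters per replicate and then
#' summarising is deliberate: medians are not invariant under non-monotone
#' transforms, so e.g. the median steady-state volume generally differs from
#' the sum of the median volumes.
#'
#' @param data An event-record dataset with at least 2 subjects.
#' @param init A [pk_model()] with initial values for the original fit, or a
#'   `pk_fit` object whose estimate seeds all replicates directly.
#' @param n_rep Number of bootstrap replicates (>= 50 recommended; the
#'   package default for reported runs is 1000).
#' @param seed Optional integer seed (same seed, same resample indices).
#' @param control A [pk_fit_control()].
#'
#' @return A tibble of class `pk_boot` with columns `term`, `type`,
#'   `median`, `cv_pct`, `q2.5`, `q97.5`. Attributes: `n_rep`, `n_failed`
#'   (non-converged replicates, dropped), `replicates` (per-replicate
#'   estimates, long format).
#' @export
pk_bootstrap <- function(data, init, n_rep = 200, seed = NULL,
                         control = pk_fit_control()) {
  validate_pk_dataset(data)
  ids <- unique(data$ID)
  if (length(ids) < 2) abort("bootstrap needs at least 2 subjects")
  check_seed(seed)

  if (inherits(init, "pk_fit")) {
    origin <- init$model
  } else {
    stopifnot(inherits(init, "pk_model"))
    origin <- pk_fit(data, init, control)$model
  }

  one_rep <- function(r) {
    take <- sample(ids, length(ids), replace = TRUE)
    boot_data <- purrr::imap_dfr(take, function(id, k) {
      d <- dplyr::filter(data, .data$ID == id)
      d$ID <- sprintf("B%03d", k)
      d
    })
    fit <- tryCatch(suppressWarnings(pk_fit(boot_data, origin, control)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    m <- fit$model
    sec <- pk_secondary(individual_params(m))
    tibble::tibble(
      replicate = r,
      term = c(theta_names, "sigma_prop", "sigma_add",
               paste0("omega2_", omega_names[m$omega2 > 0],
                      recycle0 = TRUE),
               "F_drop", "F_inf", "t_half_abs", "t_half_alpha",
               "t_half_beta", "Vss", "MRT"),
      type = c(rep("theta", 7), rep("sigma", 2),
               rep("omega2", sum(m$omega2 > 0)), rep("secondary", 7)),
      estimate = c(unname(m$theta), m$sigma_prop, m$sigma_add,
                   unname(m$omega2[m$omega2 > 0]),
                   sec$F_drop, sec$F_inf, sec$t_half_abs, sec$t_half_alpha,
                   sec$t_half_beta, sec$Vss, sec$MRT)
    )
  }

  reps <- purrr::compact(purrr::map(seq_len(n_rep), one_rep))
  n_failed <- n_rep - length(reps)
  if (n_failed > 0.2 * n_rep) {
    warn(sprintf("%d of %d bootstrap replicates failed to converge",
                 n_failed, n_rep))
  }
  if (!length(reps)) abort("no bootstrap replicate converged")
  long <- dplyr::bind_rows(reps)
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$term, .data$type),
    median = median(.data$estimate),
    cv_pct = 100 * sd(.data$estimate) / mean(.data$estimate),
    q2.5 = quantile(.data$estimate, 0.025, type = 7, names = FALSE),
    q97.5 = quantile(.data$estimate, 0.975, type = 7, names = FALSE),
    .groups = "drop"
  )
  ord <- c(theta_names, "sigma_prop", "sigma_add",
           paste0("omega2_", omega_names), "F_drop", "F_inf", "t_half_abs",
           "t_half_alpha", "t_half_beta", "Vss", "MRT")
  summary <- dplyr::arrange(summary, match(.data$term, ord))
  structure(summary, class = c("pk_boot", class(summary)),
            n_rep = n_rep, n_failed = n_failed, replicates = long,
            origin = origin)
}
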