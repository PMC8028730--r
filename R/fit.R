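#' Control settings for the population fit
#'
#' @param outer_iter_max,outer_eval_max Iteration and evaluation budget of
#'   the outer quasi-Newton search over the transformed population
#'   parameters.
#' @param rel_tol Relative convergence tolerance on -2LL.
#' @param x_tol Relative convergence tolerance on the transformed parameters.
#' @param certify_tol A solution is accepted as converged when an
#'   optimisation restarted at it cannot improve -2LL by more than this;
#'   on the chi-squared deviance scale changes this small are immaterial
#'   (guards against spurious "false convergence" reports on an objective
#'   whose inner Laplace modes are located numerically).
#' @param trace Keep the -2LL trajectory in the fit object.
#'
#' @return A list of class `pk_fit_control`.
#' @export
pk_fit_control <- function(outer_iter_max = 500, outer_eval_max = 5000,
                           rel_tol = 1e-9, x_tol = 1e-6,
                           certify_tol = 0.01, trace = FALSE) {
  structure(list(outer_iter_max = outer_iter_max,
                 outer_eval_max = outer_eval_max, rel_tol = rel_tol,
                 x_tol = x_tol, certify_tol = certify_tol, trace = trace),
            class = "pk_fit_control")
}

# model <-> unconstrained parameter vector. Thetas, variances and residual
# SDs are searched on the log scale to enforce positivity.
pack_model <- function(model, active_w, est_sp, est_sa) {
  c(log(unname(model$theta)),
    log(unname(model$omega2[active_w])),
    if (est_sp) log(model$sigma_prop),
    if (est_sa) log(model$sigma_add))
}

unpack_model <- function(x, template, active_w, est_sp, est_sa) {
  m <- template
  m$theta[] <- exp(x[1:7])
  i <- 7
  if (length(active_w)) {
    m$omega2[active_w] <- exp(x[i + seq_along(active_w)])
    i <- i + length(active_w)
  }
  if (est_sp) { i <- i + 1; m$sigma_prop <- exp(x[i]) }
  if (est_sa) { i <- i + 1; m$sigma_add <- exp(x[i]) }
  m
}

# concentration at the usable observation rows of one subject block
block_pred <- function(params, block) {
  out <- numeric(nrow(block$obs))
  if (!length(out)) return(out)
  pv <- par_vector(params)
  for (o in unique(block$obs[, 5])) {
    sel <- block$obs[, 5] == o
    dsel <- block$doses[, 5] == o
    out[sel] <- cpp_conc(pv, block$doses[dsel, 1:4, drop = FALSE],
                         block$obs[sel, 1])
  }
  out
}

eta_row_named <- function(etas, i) setNames(etas[i, ], omega_names)

call_m2ll <- function(model, subj, eta_start) {
  cpp_m2ll(unname(model$theta), unname(model$omega2), model$sigma_prop,
           model$sigma_add, subj, eta_start)
}

#' Marginal -2 log-likelihood of a population model
#'
#' Evaluates the population marginal likelihood by a subject-wise Laplace
#' approximation around each subject's conditional mode, the standard
#' objective when below-quantification (BQL) samples are censored rather
#' than discarded: quantified observations contribute Gaussian densities
#' under the combined residual model; BQL observations contribute the normal
#' probability mass below the LOQ (the M3 likelihood). A subject's occasions
#' share a single vector of random effects. Excluded (`EXCL = 1`) and
#' pre-dose (`TIME <= 0`) rows are skipped. With all variances at zero the
#' Laplace approximation is exact and the value reduces to the fixed-effects
#' censored Gaussian -2 log-likelihood.
#'
#' @param data An event-record dataset (see [validate_pk_dataset()]).
#' @param model A [pk_model()] object.
#'
#' @return The -2 log marginal likelihood (scalar). Attribute `etas` holds
#'   the per-subject conditional modes (post-hoc values).
#' @export
pk_neg2ll <- function(data, model) {
  stopifnot(inherits(model, "pk_model"))
  blocks <- subject_blocks(data)
  subj <- purrr::map(blocks, function(b) list(doses = b$doses, obs = b$obs))
  r <- call_m2ll(model, subj, matrix(0, length(blocks), 6))
  if (!all(r$conv)) {
    bad <- purrr::map_chr(blocks, "id")[!r$conv]
    warn(paste("inner mode search did not converge for subject(s):",
               paste(bad, collapse = ", ")))
  }
  structure(r$m2ll, etas = r$etas)
}

#' Fit the population model by Laplace-approximate maximum likelihood
#'
#' Minimises the marginal -2 log-likelihood of [pk_neg2ll()] over the typical
#' values, the diagonal inter-individual variances and the residual SDs (all
#' log-transformed during the search). The inner per-subject mode searches
#' are warm-started across outer iterations. The fitted object carries the
#' post-hoc (empirical Bayes) etas, population (`PRED`, etas = 0) and
#' individual (`IPRED`, post-hoc etas) predictions, conditional weighted
#' residuals, per-parameter shrinkage and IIV CV%, and the AIC
#' (`-2LL + 2 * n_estimated`).
#'
#' @param data An event-record dataset.
#' @param init A [pk_model()] giving initial values; parameters with
#'   `omega2 = 0` in `init` are treated as having no inter-individual
#'   variability. Defaults to [init_from_data()] applied to `data`.
#' @param control A [pk_fit_control()] list.
#' @param estimate If `FALSE`, skip the outer optimisation and evaluate all
#'   fit output (post-hocs, predictions, residuals) at `init` - useful for
#'   diagnostics under a known model.
#'
#' @return An object of class `pk_fit`; see [tidy.pk_fit()] and
#'   [glance.pk_fit()].
#' @export
pk_fit <- function(data, init = init_from_data(data),
                   control = pk_fit_control(), estimate = TRUE) {
  stopifnot(inherits(init, "pk_model"))
  if (init$iov_cl > 0) {
    abort(paste("inter-occasion variability is available for simulation",
                "only; refit with iov_cl = 0"))
  }
  blocks <- subject_blocks(data)
  subj <- purrr::map(blocks, function(b) list(doses = b$doses, obs = b$obs))
  n <- length(blocks)
  active_w <- which(init$omega2 > 0)
  est_sp <- init$sigma_prop > 0
  est_sa <- init$sigma_add > 0

  cache <- new.env(parent = emptyenv())
  cache$etas <- matrix(0, n, 6)
  cache$trace <- numeric()

  objective <- function(x) {
    m <- unpack_model(x, init, active_w, est_sp, est_sa)
    r <- call_m2ll(m, subj, cache$etas)
    if (is.finite(r$m2ll)) {
      cache$etas <- r$etas
      if (control$trace) cache$trace <- c(cache$trace, r$m2ll)
      r$m2ll
    } else {
      1e10
    }
  }

  x0 <- pack_model(init, active_w, est_sp, est_sa)
  lower <- c(rep(-12, 7), rep(-18, length(active_w)),
             rep(-18, est_sp + est_sa))
  upper <- c(rep(12, 7), rep(6, length(active_w)), rep(3, est_sp + est_sa))

  # explicit central-difference gradient: the objective is reproducible to
  # ~1e-9 (inner modes are converged tightly), so a 1e-5 step gives accurate
  # gradients where the optimizer's own machine-epsilon-scale differences
  # would drown in the residual numerical noise of the Laplace terms
  gradient <- function(x) {
    h <- 1e-5
    vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- x[i] + h
      xm[i] <- x[i] - h
      (objective(xp) - objective(xm)) / (2 * h)
    }, numeric(1))
  }

  if (estimate) {
    nlctl <- list(iter.max = control$outer_iter_max,
                  eval.max = control$outer_eval_max,
                  rel.tol = control$rel_tol, x.tol = control$x_tol)
    opt <- nlminb(x0, objective, gradient = gradient, lower = lower,
                  upper = upper, control = nlctl)
    # certify by restart: at a genuine optimum a fresh search goes nowhere
    opt2 <- nlminb(opt$par, objective, gradient = gradient, lower = lower,
                   upper = upper, control = nlctl)
    certified <- (opt$objective - opt2$objective) < control$certify_tol
    if (opt2$objective <= opt$objective) opt <- opt2
    model <- unpack_model(opt$par, init, active_w, est_sp, est_sa)
    outer_code <- if (opt$convergence == 0L || certified) 0L else
      opt$convergence
    outer_msg <- opt$message
    iterations <- opt$iterations
  } else {
    model <- init
    outer_code <- 0L
    outer_msg <- "evaluation at init (estimate = FALSE)"
    iterations <- 0L
  }

  final <- call_m2ll(model, subj, cache$etas)
  m2ll <- final$m2ll
  etas <- final$etas
  inner_ok <- all(final$conv)
  if (!inner_ok) {
    warn(paste("post-hoc mode search flagged subject(s):",
               paste(purrr::map_chr(blocks, "id")[!final$conv],
                     collapse = ", ")))
  }
  npar <- 7L + length(active_w) + est_sp + est_sa

  ids <- purrr::map_chr(blocks, "id")
  etas_tbl <- tibble::as_tibble(etas, .name_repair = ~paste0("eta_",
                                                             omega_names))
  etas_tbl <- dplyr::bind_cols(tibble::tibble(ID = ids), etas_tbl)

  typical <- individual_params(model)
  pred_tbl <- purrr::imap_dfr(blocks, function(b, i) {
    idx <- match(b$id, ids)
    ip <- individual_params(model, eta_row_named(etas, idx))
    tibble::tibble(
      .row = b$rows,
      ID = b$id,
      OCC = b$occ_labels[b$obs[, 5]],
      TIME = b$obs[, 1],
      DV = ifelse(b$obs[, 3] > 0.5, NA_real_, b$obs[, 2]),
      BQL = b$obs[, 3],
      LOQ = b$obs[, 4],
      PRED = block_pred(typical, b),
      IPRED = block_pred(ip, b)
    )
  })
  pred_tbl <- dplyr::arrange(pred_tbl, .data$.row)
  pred_tbl$.row <- NULL

  fit <- structure(list(
    model = model, minus2LL = m2ll, aic = m2ll + 2 * npar, npar = npar,
    etas = etas_tbl, eta_matrix = etas, predictions = pred_tbl,
    data = data, init = init, control = control,
    converged = (outer_code == 0L) && inner_ok && is.finite(m2ll),
    outer = list(code = outer_code, message = outer_msg,
                 iterations = iterations),
    trace = cache$trace
  ), class = "pk_fit")

  fit$predictions$CWRES <- pk_cwres(fit)
  active <- model$omega2 > 0
  fit$shrinkage <- tibble::tibble(
    parameter = omega_names[active],
    omega2 = unname(model$omega2[active]),
    iiv_cv = iiv_cv(unname(model$omega2[active])),
    shrinkage = purrr::map_dbl(which(active),
                               function(k) eta_shrinkage(etas[, k],
                                                         model$omega2[k])),
    flagged = .data$shrinkage > 0.3
  )
  fit
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (Laplace, M3 censoring)\n")
  cat(sprintf("  subjects: %d   observations: %d   -2LL: %.3f   AIC: %.3f\n",
              nrow(x$etas), nrow(x$predictions), x$minus2LL, x$aic))
  cat(sprintf("  converged: %s\n", x$converged))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy a population fit into a parameter table
#'
#' @param x A `pk_fit` object.
#' @param ... Unused.
#'
#' @return A tibble with one row per estimated parameter: `term`, `type`
#'   (`"theta"`, `"omega2"` or `"sigma"`), `estimate`, and for variance terms
#'   the derived `iiv_cv` and `shrinkage`.
#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  m <- x$model
  active <- m$omega2 > 0
  dplyr::bind_rows(
    tibble::tibble(term = theta_names, type = "theta",
                   estimate = unname(m$theta)),
    tibble::tibble(term = paste0("omega2_", omega_names[active],
                                 recycle0 = TRUE),
                   type = "omega2", estimate = unname(m$omega2[active]),
                   iiv_cv = x$shrinkage$iiv_cv,
                   shrinkage = x$shrinkage$shrinkage),
    tibble::tibble(term = c("sigma_prop", "sigma_add"), type = "sigma",
                   estimate = c(m$sigma_prop, m$sigma_add))
  )
}

#' One-row summary of a population fit
#'
#' @param x A `pk_fit` object.
#' @param ... Unused.
#'
#' @return A one-row tibble with `minus2LL`, `AIC`, `npar`, `n_subjects`,
#'   `n_obs`, `n_bql` and `converged`.
#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    minus2LL = x$minus2LL, AIC = x$aic, npar = x$npar,
    n_subjects = nrow(x$etas), n_obs = nrow(x$predictions),
    n_bql = sum(x$predictions$BQL > 0.5), converged = x$converged
  )
}

#' Goodness-of-fit plot for a population fit
#'
#' Observed concentrations against population (`PRED`) and individual
#' (`IPRED`) predictions on log-log axes, with the line of unity.
#'
#' @param object A `pk_fit` object.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, ...) {
  d <- dplyr::filter(object$predictions, .data$BQL < 0.5)
  d <- tidyr::pivot_longer(d, c("PRED", "IPRED"), names_to = "prediction",
                           values_to = "pred")
  ggplot2::ggplot(d, ggplot2::aes(.data$pred, .data$DV)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~prediction) +
    ggplot2::labs(x = "Predicted (µg/L)", y = "Observed (µg/L)")
}

#' Initial values from log-linear heuristics
#'
#' Naive-pooled starting values: the terminal slope and back-extrapolated
#' intercept of the pooled IV observations give starting volumes and
#' clearance; absorption and bioavailability start at generic values
#' (`ka = 5`/h, logit bioavailabilities 0.5); variances start at 0.1 and the
#' residual SDs at 20% proportional and half the LOQ additive.
#'
#' @param data An event-record dataset.
#'
#' @return A [pk_model()] object.
#' @export
init_from_data <- function(data) {
  validate_pk_dataset(data)
  iv_occ <- dplyr::filter(data, !is.na(.data$ROUTE),
                          .data$ROUTE == "iv_bolus")
  obs <- dplyr::semi_join(
    dplyr::filter(data, is.na(.data$ROUTE), .data$TIME > 0,
                  .data$EXCL == 0, .data$BQL == 0, .data$DV > 0),
    iv_occ, by = c("ID", "OCC")
  )
  loq <- stats::median(data$LOQ, na.rm = TRUE)
  if (nrow(obs) < 4 || nrow(iv_occ) == 0) {
    # no usable IV arm: fall back to generic mid-range starting values
    return(pk_model(0.5, 1, 1, 1, 5, 0.5, 0.5,
                    omega2 = setNames(rep(0.1, 6), omega_names),
                    sigma_prop = 0.2, sigma_add = loq / 2))
  }
  dose <- stats::median(iv_occ$AMT)
  # terminal slope from the late half of the pooled IV points
  late <- dplyr::filter(obs, .data$TIME >= stats::median(.data$TIME))
  slope <- -stats::coef(stats::lm(log(DV) ~ TIME, data = late))[["TIME"]]
  beta <- max(slope, 0.05)
  c0 <- exp(max(stats::predict(stats::lm(log(DV) ~ TIME, data = obs),
                               newdata = data.frame(TIME = 0))))
  vc <- max(dose / c0, 1e-3)
  cl <- max(beta * 2 * vc, 1e-3) # beta underestimates k10; scale up
  pk_model(vc, 2 * vc, cl, cl, 5, 0.5, 0.5,
           omega2 = setNames(rep(0.1, 6), omega_names),
           sigma_prop = 0.2, sigma_add = loq / 2)
}
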