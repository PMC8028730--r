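#' Conditional weighted residuals
#'
#' Residuals standardised by a first-order conditional linearisation of the
#' model about each subject's post-hoc etas: with `f` the individual
#' prediction and `G = df/deta` at the conditional mode, the approximate
#' marginal moments are `E[y] = f(eta_hat) - G eta_hat` and
#' `Cov[y] = G Omega G' + diag(residual variance at f(eta_hat))`, and the
#' residual vector is whitened by the Cholesky factor of `Cov`. Under a
#' correctly specified model CWRES are approximately standard normal.
#' Censored (BQL) observations get `NA`.
#'
#' @param fit A `pk_fit` object.
#'
#' @return Numeric vector aligned with `fit$predictions` rows.
#' @export
pk_cwres <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  model <- fit$model
  blocks <- subject_blocks(fit$data)
  ids <- purrr::map_chr(blocks, "id")
  active <- which(model$omega2 > 0)
  out <- rep(NA_real_, nrow(fit$predictions))
  pos <- 0L
  h <- 1e-4
  for (b in blocks) {
    nb <- nrow(b$obs)
    rows <- pos + seq_len(nb)
    pos <- pos + nb
    keep <- b$obs[, 3] < 0.5 # quantified only
    if (!any(keep)) next
    i <- match(b$id, ids)
    eta_hat <- fit$eta_matrix[i, ]
    f0 <- block_pred(individual_params(model,
                                       setNames(eta_hat, omega_names)), b)
    y <- b$obs[keep, 2]
    f0k <- f0[keep]
    if (length(active)) {
      G <- matrix(0, sum(keep), length(active))
      for (j in seq_along(active)) {
        ep <- em <- eta_hat
        ep[active[j]] <- ep[active[j]] + h
        em[active[j]] <- em[active[j]] - h
        fp <- block_pred(individual_params(model,
                                           setNames(ep, omega_names)), b)
        fm <- block_pred(individual_params(model,
                                           setNames(em, omega_names)), b)
        G[, j] <- (fp[keep] - fm[keep]) / (2 * h)
      }
      V <- G %*% diag(model$omega2[active],
                      length(active)) %*% t(G) +
        diag(residual_sd(model, f0k)^2, sum(keep))
      mu <- f0k - as.numeric(G %*% eta_hat[active])
    } else {
      V <- diag(residual_sd(model, f0k)^2, sum(keep))
      mu <- f0k
    }
    L <- tryCatch(t(chol(V)), error = function(e) {
      abort(paste0("singular conditional covariance for subject ", b$id))
    })
    out[rows[keep]] <- as.numeric(forwardsolve(L, y - mu))
  }
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the study under the fitted model with the
#' original design (same subjects, doses, sampling times and LOQ), and
#' compares the observed 20th/50th/80th concentration percentiles per time
#' bin and route with the medians of the same percentiles across simulated
#' replicates. Censoring is treated symmetrically: simulated values below the
#' LOQ, like observed BQL records, enter the percentile computation at LOQ/2.
#' Each observation is assigned to the nearest bin center of its route.
#'
#' @param fit A `pk_fit` object.
#' @param n_sim Number of simulated replicates (>= 100 recommended).
#' @param bin_centers Optional named list of numeric bin centers per route;
#'   defaults to the distinct scheduled sampling times of each route.
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `pk_vpc` with columns `route`, `bin_center`,
#'   `n_obs`, `obs_p20`, `obs_p50`, `obs_p80`, `sim_p20`, `sim_p50`,
#'   `sim_p80`.
#' @export
pk_vpc <- function(fit, n_sim = 500, bin_centers = NULL, seed = NULL) {
  stopifnot(inherits(fit, "pk_fit"))
  check_seed(seed)
  model <- fit$model
  data <- fit$data
  blocks <- subject_blocks(data)
  active <- which(model$omega2 > 0)

  # route of each usable observation, via its occasion's dose route
  occ_route <- dplyr::distinct(
    dplyr::filter(data, !is.na(.data$ROUTE)),
    .data$ID, .data$OCC, route = .data$ROUTE
  )
  obs_tbl <- purrr::map_dfr(blocks, function(b) {
    tibble::tibble(ID = b$id, OCC = b$occ_labels[b$obs[, 5]],
                   TIME = b$obs[, 1],
                   y_obs = ifelse(b$obs[, 3] > 0.5, b$obs[, 4] / 2,
                                  b$obs[, 2]),
                   LOQ = b$obs[, 4])
  })
  obs_tbl <- dplyr::left_join(obs_tbl, occ_route, by = c("ID", "OCC"))

  if (is.null(bin_centers)) {
    bin_centers <- purrr::map(split(obs_tbl$TIME, obs_tbl$route),
                              function(t) sort(unique(t)))
  }
  assign_bin <- function(time, route) {
    centers <- bin_centers[[route]]
    if (is.null(centers)) abort(paste("no bin centers for route", route))
    centers[max.col(-abs(outer(time, centers, "-")), ties.method = "first")]
  }
  obs_tbl$bin <- NA_real_
  for (rt in unique(obs_tbl$route)) {
    sel <- obs_tbl$route == rt
    obs_tbl$bin[sel] <- assign_bin(obs_tbl$TIME[sel], rt)
  }
  empty <- purrr::imap(bin_centers, function(centers, rt) {
    centers[!centers %in% obs_tbl$bin[obs_tbl$route == rt]]
  })
  empty <- purrr::compact(purrr::keep(empty, ~length(.x) > 0))
  if (length(empty)) {
    abort(paste("empty VPC bin(s) at center(s):",
                paste(unlist(empty), collapse = ", ")))
  }

  qs <- function(x) quantile(x, c(0.2, 0.5, 0.8), type = 7, names = FALSE)
  # simulate replicates: one eta vector per subject, residual noise, LOQ
  # censoring imputed at LOQ/2 exactly as for the observed data
  sim_q <- array(NA_real_, dim = c(n_sim, nrow(obs_tbl)))
  for (r in seq_len(n_sim)) {
    ysim <- numeric(0)
    for (b in blocks) {
      eta <- numeric(6)
      eta[active] <- rnorm(length(active),
                           sd = sqrt(model$omega2[active]))
      p <- individual_params(model, setNames(eta, omega_names))
      cc <- block_pred(p, b)
      y <- cc * (1 + rnorm(length(cc), sd = model$sigma_prop)) +
        rnorm(length(cc), sd = model$sigma_add)
      y <- pmax(y, 0)
      y <- ifelse(y < b$obs[, 4], b$obs[, 4] / 2, y)
      ysim <- c(ysim, y)
    }
    sim_q[r, ] <- ysim
  }

  groups <- split(seq_len(nrow(obs_tbl)),
                  list(obs_tbl$route, obs_tbl$bin), drop = TRUE)
  res <- purrr::map_dfr(groups, function(idx) {
    oq <- qs(obs_tbl$y_obs[idx])
    sq <- apply(purrr::map_dfr(seq_len(n_sim), function(r) {
      q <- qs(sim_q[r, idx])
      tibble::tibble(p20 = q[1], p50 = q[2], p80 = q[3])
    }), 2, median)
    tibble::tibble(route = obs_tbl$route[idx[1]],
                   bin_center = obs_tbl$bin[idx[1]], n_obs = length(idx),
                   obs_p20 = oq[1], obs_p50 = oq[2], obs_p80 = oq[3],
                   sim_p20 = sq[1], sim_p50 = sq[2], sim_p80 = sq[3])
  })
  res <- dplyr::arrange(res, .data$route, .data$bin_center)
  structure(res, class = c("pk_vpc", class(res)), n_sim = n_sim)
}

#' @rdname pk_vpc
#' @param object,... A `pk_vpc` object (for `autoplot`).
#' @method autoplot pk_vpc
#' @export
autoplot.pk_vpc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_center)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p20,
                                      ymax = .data$sim_p80),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p50),
                       colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), colour = "red",
                       linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_p20), colour = "red",
                        shape = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_p80), colour = "red",
                        shape = 6) +
    ggplot2::facet_wrap(~route, scales = "free") +
    ggplot2::labs(x = "Time (h)", y = "Atropine plasma conc. (µg/L)")
}
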