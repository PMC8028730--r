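#' End-to-end analysis replay
#'
#' Runs the whole pipeline on synthetic data: generate a study, fit the
#' population model, compute diagnostics (predictions with CWRES, a VPC),
#' bootstrap the fit, and simulate the reported dosing regimens both
#' deterministically and by Monte Carlo. Every stage writes a CSV artifact
#' into `out_dir` and the run closes with a JSON manifest recording
#' configuration, seeds, per-stage status and timings. A stage failure is
#' recorded in the manifest and downstream stages are skipped; stages never
#' mutate their inputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; each stage derives its own fixed offset
#'   stream from it, so stages are individually reproducible.
#' @param config Optional overrides, a list with any of: `model`
#'   (generating/init [pk_model()], default [atropine_model()]), `design`
#'   (a [pk_study_design()]), `n_boot`, `n_vpc`, `n_mc`, `regimens` (list of
#'   [pk_regimen()]), `control` (a [pk_fit_control()]).
#'
#' @return Invisibly, the manifest list.
#' @export
pk_replay <- function(out_dir, seed = 1, config = list()) {
  cfg <- utils::modifyList(list(
    model = atropine_model(), design = pk_study_design(), n_boot = 200,
    n_vpc = 300, n_mc = 1000,
    regimens = list(
      pk_regimen("depot_bolus", 1.5, interval = 1, horizon = 24),
      pk_regimen("depot_bolus", 1.5, interval = 3, horizon = 24),
      pk_regimen("depot_bolus", 1.5, interval = 6, horizon = 24),
      pk_regimen("depot_bolus", 0.5, interval = 1, horizon = 24),
      pk_regimen("depot_bolus", 0.5, interval = 3, horizon = 24),
      pk_regimen("depot_bolus", 0.5, interval = 6, horizon = 24),
      pk_regimen("infusion", 5, duration = 24, horizon = 24)
    ),
    control = pk_fit_control()
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "atropk",
                   version = as.character(utils::packageVersion("atropk")),
                   seed = seed, stages = list())
  state <- new.env(parent = emptyenv())
  state$failed <- FALSE

  stage <- function(name, fun) {
    if (state$failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 2)
    if (inherits(res, "error")) {
      state$failed <- TRUE
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(res),
                                       seconds = elapsed)
      invisible(NULL)
    } else {
      manifest$stages[[name]] <<- list(status = "ok", seconds = elapsed)
      res
    }
  }
  out <- function(f) file.path(out_dir, f)

  synth <- stage("synth", function() {
    s <- pk_simulate_study(cfg$model, cfg$design, seed = seed)
    write_pk_dataset(s$data, out("study.csv"))
    readr::write_csv(s$truth, out("truth.csv"))
    s
  })
  fit <- stage("fit", function() {
    f <- pk_fit(synth$data, cfg$model, cfg$control)
    readr::write_csv(tidy(f), out("params.csv"))
    readr::write_csv(f$etas, out("etas.csv"))
    readr::write_csv(f$shrinkage, out("iiv.csv"))
    readr::write_csv(f$predictions, out("predictions.csv"))
    f
  })
  stage("vpc", function() {
    v <- pk_vpc(fit, n_sim = cfg$n_vpc, seed = seed + 1L)
    readr::write_csv(tibble::as_tibble(v), out("vpc.csv"))
    v
  })
  stage("bootstrap", function() {
    b <- pk_bootstrap(synth$data, fit, n_rep = cfg$n_boot, seed = seed + 2L)
    readr::write_csv(tibble::as_tibble(b), out("bootstrap.csv"))
    b
  })
  stage("simulate", function() {
    typ <- purrr::map_dfr(cfg$regimens, function(r) {
      s <- pk_simulate_typical(cfg$model, r)
      dplyr::mutate(s$intervals, regimen = format_regimen(r), .before = 1)
    })
    readr::write_csv(typ, out("regimen_typical.csv"))
    inf <- purrr::keep(cfg$regimens, function(r) r$route == "infusion")
    mc <- purrr::map_dfr(inf, function(r) {
      s <- pk_simulate_population(cfg$model, r, n = cfg$n_mc,
                                  seed = seed + 3L)
      dplyr::mutate(s$quantiles, regimen = format_regimen(r), .before = 1)
    })
    readr::write_csv(mc, out("regimen_mc.csv"))
    list(typ = typ, mc = mc)
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
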