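dataset_cols <- c("ID", "OCC", "TIME", "ROUTE", "AMT", "DUR", "DV", "BQL",
                  "LOQ", "BW", "EXCL")

#' Study datasets as flat event records
#'
#' A study dataset is a tibble with one row per event, in the flat
#' event-record idiom standard for pharmacokinetic data. Columns:
#'
#' * `ID` subject label, `OCC` occasion label, `BW` body weight (kg),
#' * `TIME` hours since the occasion's first dose (pre-dose samples have
#'   `TIME <= 0` and never enter the likelihood),
#' * dose rows: `ROUTE` (`iv_bolus`, `depot_bolus`, `infusion`), `AMT`
#'   (ug atropine per kg body weight) and `DUR` (h; 0 for boluses),
#' * observation rows: `DV` (ug/L; `NA` when censored), `BQL` (1 when the
#'   sample fell below the quantification limit), `LOQ` (ug/L), and `EXCL`
#'   (1 for samples carried in the file but excluded from analysis, such as
#'   the spurious first infusion sample).
#'
#' `validate_pk_dataset()` checks the schema and invariants and is called by
#' both the reader and the writer.
#'
#' @param data A data frame of event records.
#'
#' @return `data` invisibly, validated.
#' @export
validate_pk_dataset <- function(data) {
  missing <- setdiff(dataset_cols, names(data))
  if (length(missing)) {
    abort(paste("dataset format error: missing column(s):",
                paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("dataset must be non-empty")
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      abort(paste0("dataset validation error: ", what, " in row(s) ",
                   paste(which(cond), collapse = ", ")))
    }
  }
  is_dose <- !is.na(data$ROUTE)
  bad_row(!is.finite(data$TIME), "non-finite TIME")
  bad_row(data$TIME < 0, "negative TIME")
  bad_row(!(data$BW > 0), "BW <= 0")
  bad_row(is_dose & !(data$AMT > 0), "dose AMT <= 0")
  bad_row(is_dose & !(data$ROUTE %in% route_levels), "unknown ROUTE")
  bad_row(is_dose & ((data$ROUTE == "infusion") != (data$DUR > 0)),
          "DUR > 0 must hold exactly for infusion doses")
  bad_row(!is_dose & !(data$LOQ > 0), "LOQ <= 0 on observation row")
  bad_row(!is_dose & !(data$BQL %in% c(0, 1)), "BQL must be 0 or 1")
  bad_row(!is_dose & data$BQL == 0 & is.na(data$DV),
          "quantified observation with missing DV")
  bad_row(!is_dose & data$BQL == 1 & !is.na(data$DV) & data$DV >= data$LOQ,
          "BQL observation with DV >= LOQ")
  bad_row(!(data$EXCL %in% c(0, 1)), "EXCL must be 0 or 1")
  n_inf <- dplyr::count(
    dplyr::filter(data, !is.na(.data$ROUTE), .data$ROUTE == "infusion"),
    .data$ID, .data$OCC
  )
  if (any(n_inf$n > 1)) {
    abort("dataset validation error: more than one infusion per occasion")
  }
  invisible(data)
}

#' Read a study dataset from its canonical CSV form
#'
#' @param path Path to a CSV file with the columns described in
#'   [validate_pk_dataset()].
#'
#' @return A validated tibble of event records, observations sorted by time
#'   within subject and occasion.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  # numeric fields come in as text and are converted by base R's strtod,
  # which (unlike the fast multi-threaded parser) reproduces every double
  # to the last ulp - required for exact write/read round trips
  data <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  num_cols <- setdiff(dataset_cols, c("ID", "OCC", "ROUTE"))
  for (cl in intersect(num_cols, names(data))) {
    data[[cl]] <- as.numeric(data[[cl]])
  }
  missing <- setdiff(dataset_cols, names(data))
  if (length(missing)) {
    abort(paste("dataset format error: missing column(s):",
                paste(missing, collapse = ", ")))
  }
  data <- data[dataset_cols]
  validate_pk_dataset(data)
  dplyr::arrange(data, .data$ID, .data$OCC, is.na(.data$ROUTE), .data$TIME)
}

#' Write a study dataset to its canonical CSV form
#'
#' Writes one row per dose event or observation with a stable column order
#' and full numeric precision, so that a write/read round trip reproduces
#' the dataset exactly.
#'
#' @param data A validated event-record tibble.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  validate_pk_dataset(data)
  out <- data[dataset_cols]
  # serialise doubles with 17 significant digits so a write/read round trip
  # is bit-exact
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# Internal: split a dataset into per-subject blocks for the likelihood.
# Occasions are integer-coded; pre-dose (TIME <= 0) and EXCL rows are
# dropped from `obs` but kept in `rows` bookkeeping for diagnostics.
subject_blocks <- function(data) {
  validate_pk_dataset(data)
  data$.row <- seq_len(nrow(data))
  split_id <- split(data, data$ID)
  purrr::map(split_id, function(d) {
    occ <- match(d$OCC, unique(d$OCC))
    is_dose <- !is.na(d$ROUTE)
    doses <- cbind(d$TIME[is_dose], route_code(d$ROUTE[is_dose]),
                   d$AMT[is_dose], d$DUR[is_dose], occ[is_dose])
    use <- !is_dose & d$TIME > 0 & d$EXCL == 0
    obs <- cbind(d$TIME[use], ifelse(is.na(d$DV[use]), 0, d$DV[use]),
                 d$BQL[use], d$LOQ[use], occ[use])
    list(id = d$ID[1], bw = d$BW[1], doses = doses, obs = obs,
         rows = d$.row[use], occ_labels = unique(d$OCC))
  })
}
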