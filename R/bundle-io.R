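#' Read and write registry bundles
#'
#' A registry bundle is stored as five tables (`admissions`,
#' `dispensations`, `diagnoses`, `deaths`, `outcomes`) in a directory,
#' either as CSV (dates in ISO-8601, missing values as empty fields) or as
#' Parquet (requires the `arrow` package).
#'
#' @param bundle A `registry_bundle`.
#' @param dir Directory to write to / read from (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return `write_registry()` returns `dir` invisibly; `read_registry()`
#'   returns a `registry_bundle`.
#' @export
write_registry <- function(bundle, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("admissions", "dispensations", "diagnoses", "deaths",
               "outcomes")) {
    tab <- bundle[[nm]]
    if (format == "csv") {
      utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the 'arrow' package is required for parquet output",
             call. = FALSE)
      }
      arrow::write_parquet(tab, file.path(dir, paste0(nm, ".parquet")))
    }
  }
  invisible(dir)
}

.date_cols <- list(admissions = c("admission_date", "discharge_date"),
                   dispensations = "dispense_date", diagnoses = "date",
                   deaths = "death_date", outcomes = "event_date")

#' @rdname write_registry
#' @export
read_registry <- function(dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  out <- list()
  for (nm in names(.date_cols)) {
    path <- file.path(dir, paste0(nm, ".", format))
    if (!file.exists(path)) stop("missing bundle table: ", path, call. = FALSE)
    tab <- if (format == "csv") {
      utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the 'arrow' package is required for parquet input",
             call. = FALSE)
      }
      as.data.frame(arrow::read_parquet(path))
    }
    for (dc in intersect(.date_cols[[nm]], names(tab))) {
      bad <- !is.na(tab[[dc]]) & is.na(as.Date(as.character(tab[[dc]]),
                                               optional = TRUE))
      if (any(bad)) {
        stop(sprintf("malformed date in %s$%s, row %d", nm, dc,
                     which(bad)[1]), call. = FALSE)
      }
      tab[[dc]] <- as.Date(as.character(tab[[dc]]))
    }
    out[[nm]] <- tab
  }
  structure(out, class = "registry_bundle")
}

#' Validate registry bundle integrity
#'
#' Checks referential integrity (child `person_id`s exist in admissions),
#' that post-baseline rows are not dated before admission, and that outcome
#' rows are unique by (person, type, date).
#'
#' @param bundle A `registry_bundle`.
#' @return The bundle, invisibly; stops on violation.
#' @export
validate_registry <- function(bundle) {
  ids <- bundle$admissions$person_id
  if (anyDuplicated(ids)) {
    stop("duplicate person_id in admissions", call. = FALSE)
  }
  for (nm in c("dispensations", "diagnoses", "deaths", "outcomes")) {
    orphan <- setdiff(bundle[[nm]]$person_id, ids)
    if (length(orphan)) {
      stop("person_id in ", nm, " not present in admissions: ",
           paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
    }
  }
  key <- with(bundle$outcomes, paste(person_id, event_type, event_date))
  if (anyDuplicated(key)) {
    stop("duplicate (person_id, event_type, event_date) in outcomes",
         call. = FALSE)
  }
  adm_date <- bundle$admissions$admission_date[match(bundle$deaths$person_id,
                                                     ids)]
  if (any(bundle$deaths$death_date < adm_date)) {
    stop("death before admission", call. = FALSE)
  }
  ev_adm <- bundle$admissions$admission_date[match(bundle$outcomes$person_id,
                                                   ids)]
  if (any(bundle$outcomes$event_date < ev_adm)) {
    stop("outcome event before admission", call. = FALSE)
  }
  invisible(bundle)
}

#' Read a synthetic-registry configuration from YAML or JSON
#'
#' The document mirrors the arguments of [synthetic_config()]; unspecified
#' fields keep their defaults. Covariates may be given as a list of mappings
#' with `name`, `kind` and distribution parameters.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  doc <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- doc
  for (fld in c("treatment_coefs", "hazard_coefs", "adherence_stop_coefs",
                "crossover_start_coefs", "event_type_probs", "missing_rate",
                "noneligible_counts")) {
    if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
  }
  if (!is.null(args$time_trend)) args$time_trend <- unlist(args$time_trend)
  do.call(synthetic_config, args)
}
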