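#' The cohort-table schema
#'
#' One row per participant: identity, farming-experience covariates, the
#' nine looked-for lameness-sign indicators, engagement covariates, time
#' played (minutes), and the two game scores (percent; accuracy may be `NA`
#' when a player marked no sheep).
#'
#' @return Data frame with columns `name` and `type`
#'   (`"integer"`, `"boolean"`, `"category"`, `"continuous"`).
#' @export
cohort_columns <- function() {
  data.frame(
    name = c("participant_id", "farming_experience", "years_with_sheep",
             "lameness_prevalence_band",
             "sign_uneven_posture", "sign_shortened_stride",
             "sign_quickened_opposite", "sign_head_nod", "sign_limp",
             "sign_raised_leg", "sign_reluctance_to_move",
             "sign_grazing_on_knees", "sign_other",
             "times_played_before", "control_problems", "observing_type",
             "moving_type", "tutorial_completed", "pointing_device",
             "time_played", "accuracy", "recall"),
    type = c("integer", "boolean", "continuous", "category",
             rep("boolean", 9),
             "category", "boolean", "category", "category", "category",
             "category", "continuous", "continuous", "continuous"),
    stringsAsFactors = FALSE
  )
}

empty_cohort_row <- function() {
  schema <- cohort_columns()
  row <- lapply(schema$type, function(t) {
    switch(t,
           integer = NA_integer_,
           boolean = NA,
           category = NA_character_,
           continuous = NA_real_)
  })
  names(row) <- schema$name
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Read and write cohort tables as CSV
#'
#' The CSV surface uses the documented schema ([cohort_columns()]): booleans
#' written `TRUE`/`FALSE`, missing values `NA`. Reading validates the header
#' (missing or extra columns are schema errors listing the offenders) and
#' coerces each column to its declared type; a value that cannot be coerced
#' — e.g. `"maybe"` in a boolean column — is an error naming the row and
#' column. `NA` accuracy rows are preserved (they are excluded, with a
#' message, by accuracy-based analyses downstream).
#'
#' @param path CSV file path.
#' @param table Cohort data frame to write.
#' @return `read_cohort_csv` returns the typed cohort data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_cohort_csv: no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  schema <- cohort_columns()
  missing_cols <- setdiff(schema$name, names(raw))
  extra_cols <- setdiff(names(raw), schema$name)
  if (length(missing_cols) || length(extra_cols)) {
    stop("read_cohort_csv: schema error",
         if (length(missing_cols))
           paste0("; missing columns: ", paste(missing_cols, collapse = ", ")),
         if (length(extra_cols))
           paste0("; unexpected columns: ", paste(extra_cols, collapse = ", ")),
         call. = FALSE)
  }
  out <- raw[, schema$name, drop = FALSE]
  for (k in seq_len(nrow(schema))) {
    col <- schema$name[k]
    v <- out[[col]]
    v[v == "" | v == "NA"] <- NA
    out[[col]] <- switch(
      schema$type[k],
      integer = coerce_col(v, col, function(z) as.integer(z)),
      continuous = coerce_col(v, col, function(z) as.numeric(z)),
      boolean = coerce_bool(v, col),
      category = as.character(v)
    )
  }
  if (anyDuplicated(out$participant_id)) {
    stop("read_cohort_csv: duplicate participant_id values", call. = FALSE)
  }
  out
}

coerce_col <- function(v, col, fn) {
  res <- suppressWarnings(fn(v))
  bad <- which(!is.na(v) & is.na(res))
  if (length(bad)) {
    stop("read_cohort_csv: cannot coerce value '", v[bad[1]],
         "' in column '", col, "', row ", bad[1], call. = FALSE)
  }
  res
}

coerce_bool <- function(v, col) {
  up <- toupper(v)
  res <- rep(NA, length(v))
  res[up %in% c("TRUE", "T")] <- TRUE
  res[up %in% c("FALSE", "F")] <- FALSE
  bad <- which(!is.na(v) & is.na(res))
  if (length(bad)) {
    stop("read_cohort_csv: cannot coerce value '", v[bad[1]],
         "' in boolean column '", col, "', row ", bad[1], call. = FALSE)
  }
  res
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  schema <- cohort_columns()
  missing_cols <- setdiff(schema$name, names(table))
  if (length(missing_cols)) {
    stop("write_cohort_csv: table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(table[, schema$name, drop = FALSE], path,
                   row.names = FALSE, na = "NA")
  invisible(path)
}

#' Load a typed configuration from a flat key-value file
#'
#' Reads a YAML (or JSON) file whose keys are exactly the fields of the
#' requested configuration type, fills defaults for omitted keys, validates,
#' and rejects unknown keys. An empty file yields the full default
#' configuration.
#'
#' @param path File path.
#' @param type `"behavior"`, `"observer"` or `"effect"`.
#' @return A [behavior_config()], [observer_config()] or [effect_spec()].
#' @export
load_config <- function(path, type = c("behavior", "observer", "effect")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("load_config: no such file: ", path, call. = FALSE)
  }
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) {
                     stop("load_config: parse error in ", path, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (is.null(vals)) vals <- list()
  ctor <- switch(type,
                 behavior = behavior_config,
                 observer = observer_config,
                 effect = effect_spec)
  allowed <- setdiff(names(formals(ctor)), "config")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("load_config: unknown key(s) for ", type, " config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(ctor, vals)
}

#' Save a configuration back to YAML
#'
#' @param config A configuration object from [behavior_config()],
#'   [observer_config()] or [effect_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run records exactly one manifest: the subcommand, md5 hashes of
#' the input configuration files, the seeds in effect (drawn and recorded
#' when the user omitted one), timestamps, package version and output paths.
#'
#' @param command Subcommand name.
#' @param config_files Character vector of input file paths (hashed).
#' @param seeds Named or unnamed integer vector of seeds used.
#' @param outputs Character vector of output paths.
#' @param path Manifest destination (JSON).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(command, config_files = character(0),
                               seeds = integer(0),
                               outputs = character(0),
                               path) {
  hashes <- if (length(config_files)) {
    h <- unname(tools::md5sum(config_files))
    stats::setNames(h, basename(config_files))
  } else NULL
  manifest <- list(
    command = command,
    config_hash = as.list(hashes),
    seeds = as.list(seeds),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("woolsim")),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
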