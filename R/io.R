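# Configuration files, dataset serialization and the run manifest.

config_defaults <- function() {
  list(cohort = unclass(cohort_config()), design = unclass(trial_design()))
}

#' Load and validate a trial configuration file
#'
#' Reads a YAML or JSON file with optional top-level `cohort` and `design`
#' sections whose keys override the documented defaults (31 subjects, 2:1
#' allocation in blocks of eight, 30 h / 60 sessions / 24 weeks). Unknown
#' keys and out-of-range values are collected into one aggregated error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with validated `cohort` ([cohort_config()]) and `design`
#'   ([trial_design()]) entries, of class `trial_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config file: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw <- raw %||% list()
  problems <- character()
  bad_sections <- setdiff(names(raw), c("cohort", "design"))
  if (length(bad_sections) > 0) {
    problems <- c(problems, paste0("unknown section(s): ",
                                   paste(bad_sections, collapse = ", ")))
  }
  defaults <- config_defaults()
  for (section in c("cohort", "design")) {
    unknown <- setdiff(names(raw[[section]]), names(defaults[[section]]))
    if (length(unknown) > 0) {
      problems <- c(problems, sprintf("unknown %s key(s): %s", section,
                                      paste(unknown, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid configuration file:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  cohort_args <- modifyList(list(),
                            raw$cohort[intersect(names(raw$cohort),
                                                 names(defaults$cohort))] %||% list())
  design_args <- raw$design[intersect(names(raw$design),
                                      names(defaults$design))] %||% list()
  design_args$timepoints <- NULL
  structure(
    list(cohort = do.call(cohort_config, cohort_args),
         design = do.call(trial_design, design_args)),
    class = "trial_config"
  )
}

#' Save a trial configuration
#'
#' @param config A `trial_config` (or a list with `cohort`/`design`).
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  payload <- list(cohort = unclass(config$cohort),
                  design = unclass(config$design))
  payload$design$timepoints <- NULL
  payload$design$sessions_per_week <- as.numeric(payload$design$sessions_per_week)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path, precision = 15)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

build_manifest <- function(config, design, seed, granularity) {
  cfg <- list(cohort = unclass(config), design = unclass(design))
  list(
    artifact_version = as.character(utils::packageVersion("adaptrain")),
    master_seed = seed,
    component_seeds = list(
      randomize = derive_seed(seed, "randomize"),
      dropout = derive_seed(seed, "dropout"),
      compliance = derive_seed(seed, "compliance"),
      calendar = derive_seed(seed, "calendar"),
      training = derive_seed(seed, "training"),
      assessments = derive_seed(seed, "assessments")
    ),
    granularity = granularity,
    config_hash = rlang::hash(cfg)
  )
}

dataset_files <- function() {
  c(subjects = "subjects.csv", training = "training.csv",
    trials = "trials.csv", assessments = "assessments.csv")
}

#' Write a trial dataset to a directory
#'
#' Serializes the dataset as UTF-8 CSV long tables (`subjects.csv`,
#' `training.csv`, `assessments.csv`, and `trials.csv` when a trial-level
#' log exists) plus `config.json` and a `manifest.json` recording the master
#' seed, derived component seeds, package version and configuration hash.
#' Identical `(config, seed)` runs produce byte-identical files.
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- dataset_files()
  readr::write_csv(dataset$subjects, file.path(dir, files[["subjects"]]))
  readr::write_csv(dataset$training, file.path(dir, files[["training"]]))
  readr::write_csv(dataset$assessments, file.path(dir, files[["assessments"]]))
  if (!is.null(dataset$trials)) {
    readr::write_csv(dataset$trials, file.path(dir, files[["trials"]]))
  }
  save_config(list(cohort = dataset$config, design = dataset$design),
              file.path(dir, "config.json"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

read_table_checked <- function(path, what) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed %s table (%s): first problem at row %d (%s).",
                  what, basename(path), probs$row[1], probs$expected[1]))
  }
  out
}

#' Read a trial dataset from a directory
#'
#' Reads the tables written by [write_dataset()], restores the
#' configuration and manifest, and re-validates the upstream invariants
#' (assessment schedule, completer-hours consistency). Malformed CSV rows
#' abort with the offending row number.
#'
#' @param dir Directory containing a written dataset.
#' @return A `trial_dataset`.
#' @export
read_dataset <- function(dir) {
  files <- dataset_files()
  for (f in files[c("subjects", "training", "assessments")]) {
    if (!file.exists(file.path(dir, f))) {
      abort(paste0("Dataset directory lacks ", f))
    }
  }
  subjects <- read_table_checked(file.path(dir, files[["subjects"]]), "subjects")
  training <- read_table_checked(file.path(dir, files[["training"]]), "training")
  assessments <- read_table_checked(file.path(dir, files[["assessments"]]),
                                    "assessments")
  trials_path <- file.path(dir, files[["trials"]])
  trials <- if (file.exists(trials_path)) {
    read_table_checked(trials_path, "trials")
  } else {
    NULL
  }
  validate_assessments(assessments)
  bad <- subjects |>
    filter((.data$status == "completer" & .data$logged_hours < 30) |
             (.data$status == "partial" &
                (.data$logged_hours <= 0 | .data$logged_hours >= 30)) |
             (.data$status == "dropout" & .data$logged_hours != 0))
  if (nrow(bad) > 0) {
    abort(paste0("Completer-status/hours mismatch for: ",
                 paste(bad$subject_id, collapse = ", ")))
  }
  dropouts <- subjects$subject_id[subjects$status == "dropout"]
  leaked <- assessments |>
    filter(.data$subject_id %in% dropouts, .data$timepoint != "baseline")
  if (nrow(leaked) > 0) {
    abort("Dropouts must have baseline-only assessments.")
  }
  cfg <- load_config(file.path(dir, "config.json"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(subjects = subjects, training = training, trials = trials,
         assessments = assessments, design = cfg$design, config = cfg$cohort,
         seed = manifest$master_seed,
         granularity = manifest$granularity %||% "session",
         manifest = manifest),
    class = "trial_dataset"
  )
}
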