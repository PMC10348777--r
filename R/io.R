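# CSV round-tripping for the documented file interface. All dates ISO-8601.

encounter_col_types <- function() {
  readr::cols(
    rln = readr::col_character(), facility_id = readr::col_character(),
    record_kind = readr::col_character(), admit_date = readr::col_date(),
    discharge_date = readr::col_date(), disposition = readr::col_character(),
    admission_type = readr::col_character(), age = readr::col_integer(),
    sex = readr::col_character(), race = readr::col_character(),
    ethnicity = readr::col_character(), insurance = readr::col_character(),
    riss = readr::col_integer(), mechanism = readr::col_character(),
    body_region = readr::col_character(), burn_flag = readr::col_logical(),
    injury_dx = readr::col_logical(), year = readr::col_integer(),
    surgery_class = readr::col_character()
  )
}

#' Read an encounter record CSV
#'
#' @param path CSV with the documented encounter columns (see
#'   `system.file("extdata", "data_dictionary.csv", package = "retriage")`).
#' @return Encounter tibble.
#' @export
read_encounters_csv <- function(path) {
  readr::read_csv(path, col_types = encounter_col_types())
}

#' Read a hospital directory CSV
#'
#' @param path CSV with facility-year rows.
#' @return Directory tibble of class `retriage_directory`.
#' @export
read_hospital_directory_csv <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    facility_id = readr::col_character(), name = readr::col_character(),
    latitude = readr::col_double(), longitude = readr::col_double(),
    facility_type = readr::col_character(), lemsa_id = readr::col_character(),
    rtcc_id = readr::col_character(), year = readr::col_integer(),
    level = readr::col_character()))
  class(d) <- c("retriage_directory", class(d))
  d
}

#' Write the synthetic dataset to CSV files
#'
#' Writes `ed.csv`, `inpatient.csv`, `hospitals.csv` and `ground_truth.csv`
#' into `dir`, plus a copy of the column data dictionary.
#'
#' @param data A [generate_encounters()] result.
#' @param directory A hospital directory.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(data, directory, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ed = file.path(dir, "ed.csv"),
             inpatient = file.path(dir, "inpatient.csv"),
             hospitals = file.path(dir, "hospitals.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  readr::write_csv(data$ed, paths[["ed"]], na = "")
  readr::write_csv(data$inpatient, paths[["inpatient"]], na = "")
  readr::write_csv(tibble::as_tibble(directory), paths[["hospitals"]], na = "")
  readr::write_csv(data$truth, paths[["ground_truth"]], na = "")
  dict <- system.file("extdata", "data_dictionary.csv", package = "retriage")
  if (nzchar(dict)) {
    file.copy(dict, file.path(dir, "data_dictionary.csv"), overwrite = TRUE)
  }
  invisible(paths)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a `simulation:` block (arguments to [sim_config()]),
#' `stages:`, `seed:`, `outdir:`, `percent_digits:` and `network_year:`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$p_suboptimal_given_retriage) &&
      is.list(sim_args$p_suboptimal_given_retriage)) {
    sim_args$p_suboptimal_given_retriage <-
      unlist(sim_args$p_suboptimal_given_retriage)
  }
  if (!is.null(sim_args$n_hospitals) && is.list(sim_args$n_hospitals)) {
    sim_args$n_hospitals <- unlist(sim_args$n_hospitals)
  }
  pipeline_config(
    simulation = do.call(sim_config, sim_args),
    stages = y$stages %||% pipeline_stages(),
    seed = y$seed, outdir = y$outdir,
    percent_digits = y$percent_digits %||% 1,
    network_year = y$network_year
  )
}
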