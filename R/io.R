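# CSV dialects shared by the generators and the analysis stages

#' Read a host-choice trials CSV
#'
#' Columns `individual,population,sex,time_h,choice` (choice 0/1, 1 = the
#' comparison's reference host); an optional `comparison` column assigns
#' rows to named population-pair comparisons.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "sex", "time_h", "choice")
  if (!all(need %in% names(df))) {
    stop("trials CSV must have columns individual,population,sex,time_h,choice",
         call. = FALSE)
  }
  df
}

#' Read a morphometrics CSV
#'
#' Columns `individual,population,sex,width_mm,elytron_mm`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_morph <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "sex", "width_mm", "elytron_mm")
  if (!all(need %in% names(df))) {
    stop("morph CSV must have columns individual,population,sex,width_mm,elytron_mm",
         call. = FALSE)
  }
  df
}

#' Write a generated study to CSV files
#'
#' Writes the four input files consumed by [run_pipeline()]:
#' `occurrences.csv`, `trials.csv`, `morph.csv` and `spectra.csv`.
#'
#' @param study a list as returned by [sim_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    occurrences = file.path(dir, "occurrences.csv"),
    trials = file.path(dir, "trials.csv"),
    morph = file.path(dir, "morph.csv"),
    spectra = file.path(dir, "spectra.csv"))
  write.csv(study$occurrences, paths[["occurrences"]], row.names = FALSE,
            quote = FALSE)
  write.csv(study$trials, paths[["trials"]], row.names = FALSE, quote = FALSE)
  write.csv(study$morph, paths[["morph"]], row.names = FALSE, quote = FALSE)
  write_spectra(study$spectra, paths[["spectra"]])
  invisible(paths)
}
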