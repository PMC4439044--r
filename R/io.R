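# CSV persistence of a synthetic world and its truth file.  All tables
# use the same schemas the pipeline reads, so a world written to disk
# round-trips through read_world() into run_pipeline() unchanged.

world_files <- c(catch = "catch.csv", measured = "measured.csv",
                 trials = "trials.csv", environment = "environment.csv",
                 spots = "spots.csv", calibration = "calibration.csv",
                 isoscape_ref = "isoscape_reference.csv")

#' Write a synthetic world to CSV
#'
#' Persists all pipeline input tables, the escapement configuration and
#' the ground truth (as JSON) under `dir`.
#'
#' @param world A list from [simulate_world()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(world_files)) {
    utils::write.csv(world$inputs[[nm]], file.path(dir, world_files[[nm]]),
                     row.names = FALSE)
  }
  esc <- world$inputs$escapement
  esc$escapement_by_year <- as.list(esc$escapement_by_year)  # keep year keys
  esc$age_distribution <- as.list(esc$age_distribution)
  jsonlite::write_json(esc, file.path(dir, "escapement.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- world$truth
  truth$daily <- NULL  # bulky; regenerate from params/seed when needed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic world from CSV
#'
#' Inverse of [write_world()]; validates that every expected table and
#' its required columns are present, naming the offending file or
#' column otherwise.
#'
#' @param dir Directory written by [write_world()].
#' @return List with `inputs` and `truth` (truth may be `NULL` when no
#'   truth file is present).
#' @export
read_world <- function(dir) {
  inputs <- list()
  schemas <- list(catch = c("date", "raw_count", "operational"),
                  measured = c("date", "fl_mm"),
                  trials = c("date", "released", "recaptured", "phenotype",
                             "flow"),
                  environment = c("date", "flow"),
                  spots = c("fish_id", "index", "distance_um", "ratio"),
                  calibration = c("or_um", "fl_mm"),
                  isoscape_ref = c("site", "ratio"))
  for (nm in names(world_files)) {
    path <- file.path(dir, world_files[[nm]])
    if (!file.exists(path)) stop(sprintf("missing input file: %s", path))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    require_columns(df, schemas[[nm]], world_files[[nm]])
    if ("date" %in% names(df)) df$date <- as.Date(df$date)
    inputs[[nm]] <- df
  }
  esc_path <- file.path(dir, "escapement.json")
  if (file.exists(esc_path)) {
    esc <- jsonlite::read_json(esc_path, simplifyVector = TRUE)
    esc$escapement_by_year <- unlist(esc$escapement_by_year)
    esc$age_distribution <- unlist(esc$age_distribution)
    inputs$escapement <- esc
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(inputs = inputs, truth = truth)
}
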