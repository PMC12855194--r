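#' Read a particle-diameter CSV
#'
#' Parses a Coulter-counter-style export with columns `sample_id`, `time_h`
#' and `diameter_um` (an optional `condition` column is kept if present).
#' Non-numeric or non-positive diameters are rejected with the offending
#' data row named.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per particle, row order preserved.
#' @export
read_particle_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Particle file not found: ", path),
          class = "phenoswitch_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  .require_columns(raw, c("sample_id", "time_h", "diameter_um"),
                   "particle CSV")
  diam <- suppressWarnings(as.numeric(raw$diameter_um))
  bad <- which(is.na(diam) & !is.na(raw$diameter_um) | is.na(raw$diameter_um))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric diameter at data row %d: '%s'",
                  bad[1], raw$diameter_um[bad[1]]),
          class = "phenoswitch_parse_error")
  }
  nonpos <- which(diam <= 0)
  if (length(nonpos) > 0) {
    abort(sprintf("Non-positive diameter at data row %d: %s",
                  nonpos[1], raw$diameter_um[nonpos[1]]),
          class = "phenoswitch_parse_error")
  }
  time_h <- suppressWarnings(as.numeric(raw$time_h))
  if (anyNA(time_h)) {
    abort(sprintf("Non-numeric time_h at data row %d",
                  which(is.na(time_h))[1]),
          class = "phenoswitch_parse_error")
  }
  out <- tibble(sample_id = raw$sample_id, time_h = time_h,
                diameter_um = diam)
  if ("condition" %in% names(raw)) out$condition <- raw$condition
  out
}

#' Classify particles into small and large size classes
#'
#' Threshold classification of diameters into the two phenotypic classes:
#' small ancestral-like propagules and large multicellular clusters. The
#' boundary is closed on the small side — a particle exactly at the
#' threshold is small, matching the 3--13 um small-propagule class.
#'
#' @param data A particle tibble with a `diameter_um` column, or a numeric
#'   vector of diameters.
#' @param threshold Class boundary in um (default 13, the small/large
#'   boundary of the diameter distributions; image-based workflows use an
#'   area threshold instead, which this rule applies unchanged to any
#'   tabulated size measure).
#'
#' @return A tibble with `count_small`, `count_large`, `fraction_small` and
#'   `threshold`, one row per `(sample_id, time_h)` group when those columns
#'   are present, otherwise a single row.
#' @examples
#' classify_particles(c(5, 14))
#' @export
classify_particles <- function(data, threshold = 13) {
  if (is.numeric(data)) data <- tibble(diameter_um = data)
  .require_columns(data, "diameter_um", "particle table")
  if (nrow(data) == 0) {
    abort("Cannot classify an empty particle sample.",
          class = "phenoswitch_validation_error")
  }
  keys <- intersect(c("sample_id", "time_h"), names(data))
  counted <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      count_small = sum(.data$diameter_um <= threshold),
      count_large = sum(.data$diameter_um > threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction_small = .data$count_small /
        (.data$count_small + .data$count_large),
      threshold = threshold
    )
  counted
}
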