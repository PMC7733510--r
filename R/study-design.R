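#' Study design parameters
#'
#' Bundles the handful of tunable constants that drive every classification
#' rule in the pipeline:
#'
#' * `schedule` -- the fecal sampling days post-inoculation (default
#'   2, 7, 14, 21, 28, 35, 40).
#' * `min_sample_depth` -- samples with fewer total reads are removed
#'   (default 10,500; "fewer than" is strict, a sample at the threshold
#'   survives).
#' * `detection_min_count` -- reads required to call an ASV present in a
#'   sample (default 1).
#' * `persistence_min_timepoints` -- scheduled days on which an ASV must be
#'   detected in a majority of animals to be a persistent colonizer
#'   (default 4 of the 7-day schedule).
#' * `persistence_fraction` -- the majority threshold; a day qualifies when
#'   the detected fraction of sampled animals is strictly greater than this
#'   (default 0.5, so 5 of 10 animals does not qualify but 2 of 3 does).
#' * `alpha` -- significance level for the donor-like abundance test
#'   (default 0.05, applied to BH-adjusted p values).
#'
#' @param schedule Integer vector of sampling days.
#' @param min_sample_depth Minimum per-sample read count.
#' @param persistence_min_timepoints Minimum number of qualifying days.
#' @param persistence_fraction Majority threshold (strict), in (0, 1).
#' @param detection_min_count Minimum reads for presence, >= 1.
#' @param alpha Significance level in (0, 1).
#' @return An object of class `study_design` (a named list).
#' @examples
#' study_design()
#' study_design(detection_min_count = 5)
#' @export
study_design <- function(schedule = c(2L, 7L, 14L, 21L, 28L, 35L, 40L),
                         min_sample_depth = 10500,
                         persistence_min_timepoints = 4,
                         persistence_fraction = 0.5,
                         detection_min_count = 1,
                         alpha = 0.05) {
  schedule <- as.integer(schedule)
  stopifnot(
    length(schedule) >= 1, !anyNA(schedule), !anyDuplicated(schedule),
    min_sample_depth >= 0,
    persistence_min_timepoints >= 1,
    persistence_min_timepoints <= length(schedule),
    persistence_fraction > 0, persistence_fraction < 1,
    detection_min_count >= 1,
    alpha > 0, alpha < 1
  )
  structure(
    list(
      schedule = sort(schedule),
      min_sample_depth = min_sample_depth,
      persistence_min_timepoints = as.integer(persistence_min_timepoints),
      persistence_fraction = persistence_fraction,
      detection_min_count = as.integer(detection_min_count),
      alpha = alpha
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Engraftment study design\n")
  cat("  sampling schedule (days):", paste(x$schedule, collapse = ", "), "\n")
  cat("  min sample depth:", x$min_sample_depth, "\n")
  cat("  detection threshold (reads):", x$detection_min_count, "\n")
  cat("  persistence: >", x$persistence_fraction * 100,
      "% of animals on >=", x$persistence_min_timepoints, "days\n")
  cat("  alpha:", x$alpha, "\n")
  invisible(x)
}

#' Cross-check a feature table against its sample metadata
#'
#' Diagnostic consistency report run before any analysis: every analysed
#' sample needs exactly one metadata record, every donor needs at least one
#' inoculum aliquot, and fecal samples must sit on the sampling schedule.
#'
#' @param ft A feature table.
#' @param metadata A sample metadata tibble (see [read_sample_metadata()] for
#'   the column contract).
#' @param design A [study_design()].
#' @return An object of class `study_validation`: a list with `ok` (logical)
#'   and character/tibble fields `samples_missing_metadata`,
#'   `metadata_without_samples`, `donors_without_inoculum`,
#'   `off_schedule_samples`.
#' @export
validate_study <- function(ft, metadata, design = study_design()) {
  metadata <- validate_sample_metadata(metadata)
  table_samples <- unique(ft$sample_id)
  meta_samples <- metadata$sample_id

  fecal <- dplyr::filter(metadata, .data$sample_type == "fecal")
  off_schedule <- dplyr::filter(
    fecal, !.data$day_post_inoculation %in% design$schedule
  )

  donors <- unique(metadata$donor_id)
  inoc_donors <- metadata |>
    dplyr::filter(.data$sample_type == "inoculum",
                  .data$sample_id %in% table_samples) |>
    dplyr::pull("donor_id") |>
    unique()

  out <- list(
    samples_missing_metadata = setdiff(table_samples, meta_samples),
    metadata_without_samples = setdiff(meta_samples, table_samples),
    donors_without_inoculum = setdiff(donors, inoc_donors),
    off_schedule_samples = off_schedule[
      c("sample_id", "donor_id", "host", "day_post_inoculation")
    ]
  )
  out$ok <- length(out$samples_missing_metadata) == 0 &&
    length(out$metadata_without_samples) == 0 &&
    length(out$donors_without_inoculum) == 0 &&
    nrow(out$off_schedule_samples) == 0
  structure(out, class = "study_validation")
}

#' @export
print.study_validation <- function(x, ...) {
  cat("Study validation:", if (x$ok) "OK" else "PROBLEMS FOUND", "\n")
  cat("  samples missing metadata:",
      length(x$samples_missing_metadata), "\n")
  cat("  metadata without samples:",
      length(x$metadata_without_samples), "\n")
  cat("  donors without inoculum:",
      length(x$donors_without_inoculum), "\n")
  cat("  off-schedule fecal samples:", nrow(x$off_schedule_samples), "\n")
  invisible(x)
}

# Internal metadata contract shared by validate_study and the classifiers.
validate_sample_metadata <- function(metadata) {
  required <- c("sample_id", "donor_id", "host", "sample_type",
                "subject_id", "day_post_inoculation")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  bad_type <- setdiff(unique(metadata$sample_type), c("inoculum", "fecal"))
  if (length(bad_type) > 0) {
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  inoc <- metadata$sample_type == "inoculum"
  if (any(inoc & metadata$host != "human_donor")) {
    stop("inoculum samples must have host = human_donor", call. = FALSE)
  }
  if (any(inoc & !is.na(metadata$day_post_inoculation))) {
    stop("inoculum samples must not carry a day_post_inoculation",
         call. = FALSE)
  }
  fecal <- !inoc
  if (any(fecal & (is.na(metadata$subject_id) |
                   is.na(metadata$day_post_inoculation)))) {
    stop("fecal samples require subject_id and day_post_inoculation",
         call. = FALSE)
  }
  if (any(fecal & metadata$host == "human_donor")) {
    stop("fecal samples must belong to an animal host", call. = FALSE)
  }
  metadata
}
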