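#' Identify a donor's core inoculum ASVs
#'
#' A donor's core community is the set of ASVs detected (count >=
#' `detection_min_count`, default 1 read) in **every** inoculum aliquot of
#' that donor. Aliquots are the donor's `sample_type == "inoculum"` samples;
#' fecal samples never influence membership. A donor with a failed aliquot
#' simply uses the surviving aliquots, and the number used is recorded.
#'
#' @param ft A feature table.
#' @param metadata Sample metadata.
#' @param donor_id The donor to profile.
#' @param design A [study_design()].
#' @return A tibble of class `core_set` with columns `donor_id`, `asv_id`,
#'   and attribute `n_aliquots_used`.
#' @export
identify_core_asvs <- function(ft, metadata, donor_id,
                               design = study_design()) {
  metadata <- validate_sample_metadata(metadata)
  aliquots <- metadata |>
    dplyr::filter(.data$donor_id == !!donor_id,
                  .data$sample_type == "inoculum",
                  .data$sample_id %in% unique(ft$sample_id))
  if (nrow(aliquots) == 0) {
    stop("donor '", donor_id, "' has no inoculum aliquots in the table",
         call. = FALSE)
  }
  core <- ft |>
    dplyr::semi_join(aliquots, by = "sample_id") |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(
      n_detected = sum(.data$count >= design$detection_min_count),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_detected == nrow(aliquots)) |>
    dplyr::arrange(.data$asv_id)
  out <- tibble::tibble(donor_id = donor_id, asv_id = core$asv_id)
  attr(out, "n_aliquots_used") <- nrow(aliquots)
  class(out) <- c("core_set", class(out))
  out
}

#' Fraction of inoculum reads captured by a core set
#'
#' @param ft A feature table.
#' @param metadata Sample metadata.
#' @param donor_id The donor whose aliquots are summed.
#' @param core A core set (tibble with `asv_id`), typically from
#'   [identify_core_asvs()].
#' @return A tibble with one row per aliquot plus a `"pooled"` row summing
#'   over aliquots; columns `sample_id`, `core_reads`, `total_reads`,
#'   `core_fraction`.
#' @export
core_read_fraction <- function(ft, metadata, donor_id, core) {
  metadata <- validate_sample_metadata(metadata)
  if (nrow(core) == 0) {
    warning("empty core set for donor '", donor_id, "'; fractions are 0")
  }
  extra <- setdiff(core$asv_id, unique(ft$asv_id))
  if (length(extra) > 0) {
    stop("core ASVs absent from the table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  aliquots <- metadata |>
    dplyr::filter(.data$donor_id == !!donor_id,
                  .data$sample_type == "inoculum")
  per <- ft |>
    dplyr::semi_join(aliquots, by = "sample_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      core_reads = sum(.data$count[.data$asv_id %in% core$asv_id]),
      total_reads = sum(.data$count),
      .groups = "drop"
    )
  pooled <- tibble::tibble(
    sample_id = "pooled",
    core_reads = sum(per$core_reads),
    total_reads = sum(per$total_reads)
  )
  dplyr::bind_rows(per, pooled) |>
    dplyr::mutate(core_fraction = ifelse(.data$total_reads > 0,
                                         .data$core_reads / .data$total_reads,
                                         0))
}

#' ASVs shared by every donor core
#'
#' Set intersection across two or more core sets, ordered by the first core's
#' ordering. Used to find the ASVs common to all inoculum aliquots of a group
#' of donors.
#'
#' @param cores A list of core sets (each a tibble with `asv_id`).
#' @return A character vector of shared ASV identifiers.
#' @export
shared_core_asvs <- function(cores) {
  stopifnot(is.list(cores), length(cores) >= 2)
  shared <- purrr::reduce(purrr::map(cores, ~ .x$asv_id), intersect)
  cores[[1]]$asv_id[cores[[1]]$asv_id %in% shared]
}
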