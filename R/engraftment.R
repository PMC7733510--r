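#' Classify core donor ASVs as colonizers of a host group
#'
#' A core donor ASV is a *colonizer* of an animal model when it is detected
#' (count >= the design's detection threshold) in at least one fecal sample
#' of that donor-host group -- a single read in a single animal on a single
#' day is enough. ASVs outside the core set are never called.
#'
#' @param ft A feature table.
#' @param metadata Sample metadata.
#' @param donor_id,host The donor-host group to classify.
#' @param core The donor's core set ([identify_core_asvs()]).
#' @param design A [study_design()].
#' @return A tibble with one row per core ASV: `donor_id`, `host`, `asv_id`,
#'   `status` (`"non_colonizer"` or `"colonizer"`), `n_fecal_detected`.
#' @export
classify_colonizers <- function(ft, metadata, donor_id, host, core,
                                design = study_design()) {
  fecal <- fecal_samples(ft, metadata, donor_id, host)
  det <- ft |>
    dplyr::semi_join(fecal, by = "sample_id") |>
    dplyr::filter(.data$asv_id %in% core$asv_id) |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(
      n_fecal_detected = sum(.data$count >= design$detection_min_count),
      .groups = "drop"
    )
  core |>
    dplyr::select("asv_id") |>
    dplyr::left_join(det, by = "asv_id") |>
    dplyr::mutate(
      donor_id = !!donor_id, host = !!host,
      n_fecal_detected = dplyr::coalesce(.data$n_fecal_detected, 0L),
      status = ifelse(.data$n_fecal_detected > 0, "colonizer",
                      "non_colonizer")
    ) |>
    dplyr::select("donor_id", "host", "asv_id", "status",
                  "n_fecal_detected")
}

#' Classify core donor ASVs on the full colonization ladder
#'
#' Extends [classify_colonizers()] with the persistence rule. For each
#' scheduled day, the detection fraction is (animals whose fecal sample on
#' that day detects the ASV) / (animals with a fecal sample on that day);
#' animals that died contribute nothing on days where they have no sample. A
#' day qualifies when that fraction is **strictly** greater than
#' `persistence_fraction` (default 0.5), and an ASV is a *persistent
#' colonizer* when at least `persistence_min_timepoints` (default 4) of the
#' scheduled days qualify. When an animal yields several samples on one day,
#' the animal counts as detected if any of them detects the ASV.
#'
#' @inheritParams classify_colonizers
#' @return A tibble with one row per core ASV: `donor_id`, `host`, `asv_id`,
#'   `status` on the ladder `non_colonizer < colonizer <
#'   persistent_colonizer`, `n_fecal_detected`, `n_majority_timepoints`, and
#'   a `day_fraction` list-column holding the per-day detection fractions
#'   (named by day; `NaN` for scheduled days with no sampled animal).
#' @export
classify_persistent <- function(ft, metadata, donor_id, host, core,
                                design = study_design()) {
  calls <- classify_colonizers(ft, metadata, donor_id, host, core, design)
  fecal <- fecal_samples(ft, metadata, donor_id, host)

  empty_days <- setdiff(design$schedule, fecal$day_post_inoculation)
  if (length(empty_days) > 0) {
    warning("donor '", donor_id, "', host '", host,
            "': no fecal samples on scheduled day(s) ",
            paste(empty_days, collapse = ", "),
            "; these days cannot qualify for persistence")
  }

  frac <- ft |>
    dplyr::inner_join(
      fecal[c("sample_id", "subject_id", "day_post_inoculation")],
      by = "sample_id"
    ) |>
    dplyr::filter(.data$asv_id %in% core$asv_id,
                  .data$day_post_inoculation %in% design$schedule) |>
    dplyr::group_by(.data$asv_id, .data$day_post_inoculation,
                    .data$subject_id) |>
    dplyr::summarise(
      detected = any(.data$count >= design$detection_min_count),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(fraction = mean(.data$detected), .groups = "drop")

  frac_full <- tidyr::expand_grid(
    asv_id = core$asv_id, day_post_inoculation = design$schedule
  ) |>
    dplyr::left_join(frac, by = c("asv_id", "day_post_inoculation")) |>
    dplyr::mutate(fraction = ifelse(is.na(.data$fraction), NaN,
                                    .data$fraction))

  persist <- frac_full |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(
      n_majority_timepoints = sum(
        !is.nan(.data$fraction) &
          .data$fraction > design$persistence_fraction
      ),
      day_fraction = list(setNames(.data$fraction,
                                   .data$day_post_inoculation)),
      .groups = "drop"
    )

  calls |>
    dplyr::left_join(persist, by = "asv_id") |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$status == "colonizer" &
          .data$n_majority_timepoints >= design$persistence_min_timepoints ~
          "persistent_colonizer",
        .default = .data$status
      )
    ) |>
    dplyr::select("donor_id", "host", "asv_id", "status",
                  "n_fecal_detected", "n_majority_timepoints",
                  "day_fraction")
}

# Fecal sample records for one donor-host group; errors when there are none.
fecal_samples <- function(ft, metadata, donor_id, host) {
  metadata <- validate_sample_metadata(metadata)
  fecal <- metadata |>
    dplyr::filter(.data$donor_id == !!donor_id, .data$host == !!host,
                  .data$sample_type == "fecal",
                  .data$sample_id %in% unique(ft$sample_id))
  if (nrow(fecal) == 0) {
    stop("no fecal samples in the table for donor '", donor_id,
         "', host '", host, "'", call. = FALSE)
  }
  fecal
}

STATUS_LEVELS <- c("non_colonizer", "colonizer", "persistent_colonizer")

status_rank <- function(status) {
  match(status, STATUS_LEVELS)
}

#' Establishment percentage under the reporting convention
#'
#' Percentages of established ASVs are reported as `100 * count / total`
#' rounded half-away-from-zero: 1 decimal in table-style output, 0 decimals
#' in prose-style output.
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @param digits Decimals to keep (0 or 1 in practice).
#' @return The rounded percentage.
#' @examples
#' establishment_pct(21, 26)      # 80.8
#' establishment_pct(7, 16, 0)    # 44
#' @export
establishment_pct <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, digits)
}

#' Summarize a donor-host group's colonization calls
#'
#' Produces one summary row in the style of the study's establishment table:
#' core size, colonizer and persistent-colonizer counts with percentages of
#' the core (half-away-from-zero, 1 decimal), and the mean fecal read depth
#' rounded to an integer.
#'
#' @param calls Calls for a single donor-host group
#'   ([classify_persistent()]).
#' @param ft The feature table (for fecal depths); optional.
#' @param metadata Sample metadata; required when `ft` is given.
#' @return A one-row tibble: `donor_id`, `host`, `n_core`, `n_colonizers`,
#'   `pct_colonizers`, `n_persistent`, `pct_persistent`,
#'   `mean_fecal_depth` (NA when `ft` is not supplied).
#' @export
summarize_engraftment <- function(calls, ft = NULL, metadata = NULL) {
  stopifnot(nrow(calls) > 0)
  if (dplyr::n_distinct(calls$donor_id) != 1 ||
      dplyr::n_distinct(calls$host) != 1) {
    stop("calls must come from a single donor-host group", call. = FALSE)
  }
  n_core <- nrow(calls)
  n_col <- sum(status_rank(calls$status) >= 2)
  n_per <- sum(status_rank(calls$status) >= 3)
  depth <- NA_real_
  if (!is.null(ft)) {
    fecal <- fecal_samples(ft, metadata, calls$donor_id[1], calls$host[1])
    depth <- round_half_up(mean(
      dplyr::semi_join(sample_depths(ft), fecal, by = "sample_id")$depth
    ))
  }
  tibble::tibble(
    donor_id = calls$donor_id[1],
    host = calls$host[1],
    n_core = n_core,
    n_colonizers = n_col,
    pct_colonizers = round_half_up(100 * n_col / n_core, 1),
    n_persistent = n_per,
    pct_persistent = round_half_up(100 * n_per / n_core, 1),
    mean_fecal_depth = depth
  )
}

#' Cross-host colonization contingency for one donor
#'
#' Partitions a donor's core set by colonization outcome in two hosts: ASVs
#' that established in both, in one only, or in neither. The basis may be the
#' colonizer rule (default) or the stricter persistent-colonizer rule.
#'
#' @param calls_host_a,calls_host_b Calls for the same donor core in two
#'   hosts.
#' @param basis `"colonizer"` or `"persistent_colonizer"`.
#' @return A one-row tibble: `donor_id`, `host_a`, `host_b`, `basis`,
#'   `both_hosts`, `host_a_only`, `host_b_only`, `neither`, `n_core`.
#' @export
cross_model_contingency <- function(calls_host_a, calls_host_b,
                                    basis = c("colonizer",
                                              "persistent_colonizer")) {
  basis <- match.arg(basis)
  if (!setequal(calls_host_a$asv_id, calls_host_b$asv_id) ||
      nrow(calls_host_a) != nrow(calls_host_b)) {
    stop("the two call sets cover different core sets", call. = FALSE)
  }
  threshold <- status_rank(basis)
  a <- setNames(status_rank(calls_host_a$status) >= threshold,
                calls_host_a$asv_id)
  b <- setNames(status_rank(calls_host_b$status) >= threshold,
                calls_host_b$asv_id)
  b <- b[names(a)]
  tibble::tibble(
    donor_id = calls_host_a$donor_id[1],
    host_a = calls_host_a$host[1],
    host_b = calls_host_b$host[1],
    basis = basis,
    both_hosts = sum(a & b),
    host_a_only = sum(a & !b),
    host_b_only = sum(!a & b),
    neither = sum(!a & !b),
    n_core = length(a)
  )
}

#' Roll colonization calls up to a taxonomic rank
#'
#' Aggregates per-ASV calls into per-taxon counts of core members,
#' colonizers, and persistent colonizers, within each donor-host group
#' present in `calls`. ASVs without an assignment at the requested rank are
#' grouped as `"unclassified"`. Per-taxon counts always sum back to the
#' ungrouped totals.
#'
#' @param calls Colonization calls (any number of donor-host groups).
#' @param taxonomy A taxonomy tibble ([read_taxonomy()]).
#' @param rank One of domain, phylum, class, order, family, genus, species.
#' @return A tibble with columns `donor_id`, `host`, `taxon`, `n_core`,
#'   `n_colonizers`, `n_persistent`.
#' @export
rollup_by_taxon <- function(calls, taxonomy, rank = "phylum") {
  if (!rank %in% RANK_NAMES) {
    stop("unknown rank '", rank, "'; expected one of ",
         paste(RANK_NAMES, collapse = ", "), call. = FALSE)
  }
  tax <- tibble::tibble(
    asv_id = taxonomy$asv_id,
    taxon = dplyr::coalesce(taxonomy[[rank]], "unclassified")
  )
  calls |>
    dplyr::left_join(tax, by = "asv_id") |>
    dplyr::mutate(taxon = dplyr::coalesce(.data$taxon, "unclassified")) |>
    dplyr::group_by(.data$donor_id, .data$host, .data$taxon) |>
    dplyr::summarise(
      n_core = dplyr::n(),
      n_colonizers = sum(status_rank(.data$status) >= 2),
      n_persistent = sum(status_rank(.data$status) >= 3),
      .groups = "drop"
    )
}

#' Roll calls across donors up to a rank, deduplicating ASVs
#'
#' Counts each ASV identifier once across all donors: an ASV is a
#' union-colonizer of a host when it is a colonizer in at least one donor's
#' calls for that host (persistence likewise). Requires ASV identifiers to be
#' comparable across donors (a shared denoising universe).
#'
#' @param calls Calls pooled over donors (single or multiple hosts).
#' @param taxonomy A taxonomy tibble.
#' @param rank Taxonomic rank for grouping.
#' @return A tibble with columns `host`, `taxon`, `n_core`, `n_colonizers`,
#'   `n_persistent`, where `n_core` counts unique ASV identifiers.
#' @export
union_rollup <- function(calls, taxonomy, rank = "phylum") {
  if (!rank %in% RANK_NAMES) {
    stop("unknown rank '", rank, "'", call. = FALSE)
  }
  tax <- tibble::tibble(
    asv_id = taxonomy$asv_id,
    taxon = dplyr::coalesce(taxonomy[[rank]], "unclassified")
  )
  calls |>
    dplyr::group_by(.data$host, .data$asv_id) |>
    dplyr::summarise(best = max(status_rank(.data$status)),
                     .groups = "drop") |>
    dplyr::left_join(tax, by = "asv_id") |>
    dplyr::mutate(taxon = dplyr::coalesce(.data$taxon, "unclassified")) |>
    dplyr::group_by(.data$host, .data$taxon) |>
    dplyr::summarise(
      n_core = dplyr::n(),
      n_colonizers = sum(.data$best >= 2),
      n_persistent = sum(.data$best >= 3),
      .groups = "drop"
    )
}
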