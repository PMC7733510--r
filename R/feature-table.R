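#' Build a tidy ASV feature table
#'
#' The feature table is the single substrate of every downstream stage: a tidy
#' tibble with one row per (sample, ASV) cell and columns `sample_id`,
#' `asv_id`, `count`. The grid is dense -- every sample carries a row for every
#' ASV, zeros included -- so presence fractions and per-sample totals never
#' depend on which zeros happen to be stored. Cells are identifier-keyed:
#' reordering rows never changes any result.
#'
#' @param x A data frame with columns `sample_id`, `asv_id`, `count`, or a
#'   numeric matrix with samples as rows and ASVs as columns (dimnames
#'   required).
#' @return A tibble with columns `sample_id` (character), `asv_id`
#'   (character), `count` (integer), densely covering samples x ASVs.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' feature_table(m)
#' @export
feature_table <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input must carry sample row names and ASV column names",
           call. = FALSE)
    }
    ft <- tibble::as_tibble(x, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "asv_id",
                          values_to = "count")
  } else {
    ft <- tibble::as_tibble(x)
  }
  validate_feature_table(ft)
}

#' Validate feature-table invariants
#'
#' Checks that counts are non-negative integers, that no (sample, ASV) cell is
#' duplicated, and that the grid is dense (every sample has a row for every
#' ASV). Fractional counts are rejected rather than rounded: downstream
#' detection and count-model testing assume true read counts.
#'
#' @param ft A candidate feature-table data frame.
#' @return The validated table as a tibble with `count` coerced to integer.
#' @export
validate_feature_table <- function(ft) {
  required <- c("sample_id", "asv_id", "count")
  missing <- setdiff(required, names(ft))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ft <- tibble::as_tibble(ft)
  ft$sample_id <- as.character(ft$sample_id)
  ft$asv_id <- as.character(ft$asv_id)
  if (anyNA(ft$count)) {
    bad <- ft[is.na(ft$count), ]
    stop("missing count for sample '", bad$sample_id[1], "', ASV '",
         bad$asv_id[1], "'", call. = FALSE)
  }
  if (!is.numeric(ft$count)) {
    stop("counts must be numeric integers", call. = FALSE)
  }
  frac <- ft$count != floor(ft$count)
  if (any(frac)) {
    bad <- ft[frac, ]
    stop("non-integer count ", bad$count[1], " for sample '",
         bad$sample_id[1], "', ASV '", bad$asv_id[1], "'", call. = FALSE)
  }
  if (any(ft$count < 0)) {
    bad <- ft[ft$count < 0, ]
    stop("negative count ", bad$count[1], " for sample '", bad$sample_id[1],
         "', ASV '", bad$asv_id[1], "'", call. = FALSE)
  }
  dup <- duplicated(ft[c("sample_id", "asv_id")])
  if (any(dup)) {
    bad <- ft[dup, ]
    stop("duplicate cell for sample '", bad$sample_id[1], "', ASV '",
         bad$asv_id[1], "'", call. = FALSE)
  }
  n_samples <- dplyr::n_distinct(ft$sample_id)
  n_asvs <- dplyr::n_distinct(ft$asv_id)
  if (nrow(ft) != n_samples * n_asvs) {
    stop("feature table is not a dense grid: ", nrow(ft), " cells for ",
         n_samples, " samples x ", n_asvs,
         " ASVs; use complete_feature_table() to fill implicit zeros",
         call. = FALSE)
  }
  ft$count <- as.integer(round(ft$count))
  ft
}

#' Fill implicit zeros in a sparse (sample, ASV, count) table
#'
#' @param ft A data frame with columns `sample_id`, `asv_id`, `count` where
#'   absent cells mean zero reads.
#' @param sample_ids,asv_ids Optional identifier universes; defaults to the
#'   identifiers observed in `ft`.
#' @return A dense, validated feature table.
#' @export
complete_feature_table <- function(ft, sample_ids = NULL, asv_ids = NULL) {
  ft <- tibble::as_tibble(ft)
  sample_ids <- sample_ids %||% unique(as.character(ft$sample_id))
  asv_ids <- asv_ids %||% unique(as.character(ft$asv_id))
  full <- tidyr::expand_grid(sample_id = sample_ids, asv_id = asv_ids)
  out <- dplyr::left_join(full, ft, by = c("sample_id", "asv_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  validate_feature_table(out)
}

#' Feature table as a samples-by-ASVs count matrix
#'
#' @param ft A feature table (see [feature_table()]).
#' @return An integer matrix, samples as rows, ASVs as columns, dimnames set.
#' @export
ft_matrix <- function(ft) {
  wide <- ft |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "asv_id",
                       values_from = "count")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  storage.mode(m) <- "integer"
  m
}

#' Per-sample read depths
#'
#' @param ft A feature table.
#' @return A tibble with columns `sample_id`, `depth` (total reads).
#' @export
sample_depths <- function(ft) {
  ft |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(depth = sum(.data$count), .groups = "drop")
}

#' Remove shallow samples
#'
#' Retains exactly the samples whose total read count is greater than or equal
#' to `min_depth`; the comparison is "less than `min_depth` is removed", so a
#' sample at exactly the threshold survives. The default threshold of 10,500
#' reads is the quality floor used throughout the package. The ASV set is
#' never changed by this filter.
#'
#' @param ft A feature table.
#' @param min_depth Minimum total read count a sample must reach (default
#'   10500).
#' @return The filtered feature table (possibly with zero samples).
#' @examples
#' ft <- feature_table(matrix(c(9000L, 10500L), 2, 1,
#'   dimnames = list(c("a", "b"), "asv1")))
#' filter_samples_by_depth(ft, 10500)   # sample "b" survives
#' @export
filter_samples_by_depth <- function(ft, min_depth = 10500) {
  stopifnot(is.numeric(min_depth), length(min_depth) == 1, min_depth >= 0)
  keep <- sample_depths(ft) |>
    dplyr::filter(.data$depth >= min_depth)
  dplyr::semi_join(ft, keep, by = "sample_id")
}

#' Convert counts to within-sample relative abundances
#'
#' @param ft A feature table; every sample must have total count > 0.
#' @return A tibble with columns `sample_id`, `asv_id`, `count`,
#'   `rel_abundance`; relative abundances sum to 1 within each sample.
#' @export
relative_abundance <- function(ft) {
  depths <- sample_depths(ft)
  zero <- depths$sample_id[depths$depth == 0]
  if (length(zero) > 0) {
    stop("zero-depth sample(s): ", paste(zero, collapse = ", "),
         "; remove them (e.g. filter_samples_by_depth) before normalising",
         call. = FALSE)
  }
  ft |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_abundance = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Presence/absence calls per cell
#'
#' A cell is "present" when its count reaches the detection threshold of the
#' study design (default: at least 1 read).
#'
#' @param ft A feature table.
#' @param design A [study_design()] object (supplies `detection_min_count`).
#' @return The table with a logical `present` column added.
#' @export
detect_presence <- function(ft, design = study_design()) {
  dplyr::mutate(ft, present = .data$count >= design$detection_min_count)
}
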