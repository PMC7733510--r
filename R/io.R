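#' Read an ASV count table from TSV
#'
#' Accepts the two layouts in common use: a wide matrix with samples as rows
#' (first column = sample identifiers, header = ASV identifiers) or its
#' transpose with ASVs as rows. Either way the result is normalised to the
#' tidy samples-x-ASVs form. Cells must parse as non-negative integers;
#' fractional or negative values are rejected with the offending cell named.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"asvs_as_rows"`.
#' @return A dense feature table tibble (see [feature_table()]).
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), comment = "#")
  if (ncol(raw) < 2) {
    stop("feature table file needs an identifier column plus counts: ", path,
         call. = FALSE)
  }
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifier '", ids[anyDuplicated(ids)],
         "' in ", path, call. = FALSE)
  }
  m <- as.matrix(raw[-1])
  rownames(m) <- ids
  if (orientation == "asvs_as_rows") m <- t(m)
  feature_table(m)
}

#' Read a sparse triplet count table
#'
#' Each line gives one non-zero cell: `sample_id`, `asv_id`, `count`. Absent
#' cells are zero. The identifier universes default to those observed in the
#' file; pass them explicitly to include all-zero samples or ASVs.
#'
#' @param path Path to a 3-column TSV with a header.
#' @inheritParams complete_feature_table
#' @return A dense feature table tibble.
#' @export
read_feature_triplets <- function(path, sample_ids = NULL, asv_ids = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    asv_id = readr::col_character(),
    count = readr::col_double()
  ), comment = "#")
  complete_feature_table(raw, sample_ids = sample_ids, asv_ids = asv_ids)
}

#' Write a feature table to wide TSV
#'
#' @param ft A feature table.
#' @param path Output path.
#' @param orientation Row layout, as in [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path,
                                orientation = c("samples_as_rows",
                                                "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  m <- ft_matrix(validate_feature_table(ft))
  if (orientation == "asvs_as_rows") {
    id_col <- "asv_id"
    m <- t(m)
  } else {
    id_col <- "sample_id"
  }
  out <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read sample metadata
#'
#' The metadata TSV carries one row per sample with required columns
#' `sample_id`, `donor_id`, `host`, `sample_type`, `subject_id`,
#' `day_post_inoculation`. `sample_type` is `"inoculum"` (host
#' `"human_donor"`, no subject or day) or `"fecal"` (an animal host with
#' subject and day). Empty strings denote absent values. Extra columns pass
#' through untouched.
#'
#' @param path Path to the metadata TSV.
#' @return A validated metadata tibble with `day_post_inoculation` as
#'   integer (NA for inoculum samples).
#' @export
read_sample_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = c("", "NA"), comment = "#")
  raw$day_post_inoculation <- as.integer(raw$day_post_inoculation)
  validate_sample_metadata(raw)
}

#' @rdname read_sample_metadata
#' @param metadata A metadata tibble to write.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(validate_sample_metadata(metadata), path, na = "")
  invisible(path)
}

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Read a taxonomy table
#'
#' Two layouts are recognised automatically: `asv_id` plus the seven rank
#' columns (domain...species), or `asv_id` plus a single `lineage` column in
#' semicolon-delimited SILVA style (`d__...;p__...;...`). Empty lower ranks
#' are allowed; a filled rank below an empty one is rejected since lineages
#' are hierarchical.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with columns `asv_id` and the seven ranks (NA where
#'   unassigned).
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = c("", "NA"), comment = "#")
  if ("lineage" %in% names(raw)) {
    tax <- parse_lineage_strings(raw$asv_id, raw$lineage)
  } else {
    missing <- setdiff(c("asv_id", RANK_NAMES), names(raw))
    if (length(missing) > 0) {
      stop("taxonomy lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tax <- raw[c("asv_id", RANK_NAMES)]
  }
  validate_taxonomy(tax)
}

parse_lineage_strings <- function(asv_id, lineage) {
  parts <- stringr::str_split(lineage, ";")
  rows <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_remove(p, "^[a-z]__")
    p[p == ""] <- NA_character_
    length(p) <- length(RANK_NAMES)
    setNames(as.list(p), RANK_NAMES)
  })
  dplyr::bind_cols(tibble::tibble(asv_id = asv_id),
                   dplyr::bind_rows(rows))
}

validate_taxonomy <- function(tax) {
  tax <- tibble::as_tibble(tax)
  if (anyDuplicated(tax$asv_id)) {
    stop("duplicate asv_id in taxonomy", call. = FALSE)
  }
  ranks <- as.matrix(tax[RANK_NAMES])
  filled <- !is.na(ranks) & ranks != ""
  # once a rank is empty, everything below it must be empty too
  for (i in seq_len(nrow(filled))) {
    f <- filled[i, ]
    if (any(f) && any(which(f) > min(which(!f), Inf))) {
      stop("non-hierarchical lineage for ASV '", tax$asv_id[i],
           "': a rank below an empty rank is filled", call. = FALSE)
    }
  }
  tax
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy tibble to write.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(validate_taxonomy(taxonomy), path, na = "")
  invisible(path)
}

#' Read a rooted ASV phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces what unweighted UniFrac
#' needs: unique tip labels and finite, non-negative branch lengths.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_asv_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path,
                          call. = FALSE)
  validate_asv_tree(tree)
}

validate_asv_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels are not unique", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("tree branch lengths must be finite and non-negative",
         call. = FALSE)
  }
  tree
}
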