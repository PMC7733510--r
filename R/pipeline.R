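#' Run the full engraftment-quantification pipeline
#'
#' Chains every stage in analysis order -- sample-depth filtering, per-donor
#' core identification, colonization/persistence classification per
#' donor-host group, establishment summaries, cross-host contingencies,
#' taxonomic roll-ups, shared-core analysis, donor-like maintenance testing,
#' and diversity support (alpha diversity, distance matrices, PCoA, donor
#' distances) -- and optionally writes every result as a TSV bundle. All
#' intermediate artifacts are plain tables so any single stage can be
#' inspected or replaced.
#'
#' @param ft A feature table.
#' @param metadata Sample metadata.
#' @param taxonomy Optional taxonomy tibble (enables roll-ups).
#' @param tree Optional rooted phylogeny (enables unweighted UniFrac).
#' @param design A [study_design()].
#' @param test_mode Differential test mode for maintenance analysis.
#' @param rollup_ranks Ranks to roll calls up to (intersection with the
#'   taxonomy's filled ranks is used).
#' @param beta_on_core Compute beta diversity on the core-restricted table
#'   (default TRUE; alpha diversity always uses all ASVs).
#' @param out_dir Optional directory; when given, every result is written as
#'   TSV plus a `run_manifest.tsv` echoing parameters and input shapes.
#' @param force Proceed despite a failing [validate_study()] report.
#' @return A list of results: `validation`, `filtered_table`, `cores`
#'   (named list), `core_fractions`, `shared_core`, `calls`, `summary`,
#'   `contingency`, `rollups`, `union_rollups`, `maintenance`,
#'   `maintenance_results`, `alpha`, `distances`, `pcoa`,
#'   `donor_distance`.
#' @export
run_pipeline <- function(ft, metadata, taxonomy = NULL, tree = NULL,
                         design = study_design(),
                         test_mode = c("nb_wald", "rank_sum"),
                         rollup_ranks = c("phylum", "family", "genus"),
                         beta_on_core = TRUE,
                         out_dir = NULL, force = FALSE) {
  test_mode <- match.arg(test_mode)
  metadata <- validate_sample_metadata(metadata)
  ft <- validate_feature_table(ft)

  validation <- validate_study(ft, metadata, design)
  if (!validation$ok && !force) {
    stop("study validation failed (see validate_study()); ",
         "use force = TRUE to proceed", call. = FALSE)
  }

  n_before <- dplyr::n_distinct(ft$sample_id)
  ft <- filter_samples_by_depth(ft, design$min_sample_depth)
  metadata_kept <- dplyr::filter(metadata,
                                 .data$sample_id %in% unique(ft$sample_id))
  message("depth filter: ", dplyr::n_distinct(ft$sample_id), " of ",
          n_before, " samples retained at >= ", design$min_sample_depth,
          " reads")

  donors <- metadata_kept |>
    dplyr::filter(.data$sample_type == "inoculum") |>
    dplyr::pull("donor_id") |>
    unique() |>
    sort()
  hosts_by_donor <- metadata_kept |>
    dplyr::filter(.data$sample_type == "fecal") |>
    dplyr::distinct(.data$donor_id, .data$host)

  cores <- purrr::map(
    setNames(donors, donors),
    ~ identify_core_asvs(ft, metadata_kept, .x, design)
  )
  core_fractions <- purrr::map_dfr(
    donors, ~ dplyr::mutate(
      core_read_fraction(ft, metadata_kept, .x, cores[[.x]]),
      donor_id = .x, .before = 1
    )
  )
  shared_core <- if (length(cores) >= 2) shared_core_asvs(cores) else
    character()

  calls <- purrr::map_dfr(donors, function(d) {
    hosts <- hosts_by_donor$host[hosts_by_donor$donor_id == d]
    purrr::map_dfr(hosts, function(h) {
      classify_persistent(ft, metadata_kept, d, h, cores[[d]], design)
    })
  })

  summary <- calls |>
    dplyr::group_by(.data$donor_id, .data$host) |>
    dplyr::group_split() |>
    purrr::map_dfr(~ summarize_engraftment(.x, ft, metadata_kept))

  contingency <- purrr::map_dfr(donors, function(d) {
    hosts <- sort(unique(calls$host[calls$donor_id == d]))
    if (length(hosts) < 2) return(tibble::tibble())
    purrr::map_dfr(c("colonizer", "persistent_colonizer"), function(b) {
      cross_model_contingency(
        dplyr::filter(calls, .data$donor_id == d, .data$host == hosts[1]),
        dplyr::filter(calls, .data$donor_id == d, .data$host == hosts[2]),
        basis = b
      )
    })
  })

  rollups <- NULL
  union_rollups <- NULL
  if (!is.null(taxonomy)) {
    ranks <- intersect(rollup_ranks, RANK_NAMES)
    rollups <- purrr::map_dfr(
      ranks, ~ dplyr::mutate(rollup_by_taxon(calls, taxonomy, .x),
                             rank = .x, .before = 1)
    )
    union_rollups <- purrr::map_dfr(
      ranks, ~ dplyr::mutate(union_rollup(calls, taxonomy, .x),
                             rank = .x, .before = 1)
    )
  }

  maint <- calls |>
    dplyr::group_by(.data$donor_id, .data$host) |>
    dplyr::group_split() |>
    purrr::map(~ maintenance_analysis(ft, metadata_kept, .x, design,
                                      mode = test_mode))
  maintenance <- dplyr::bind_rows(purrr::map(maint, "maintenance"))
  maintenance_results <- dplyr::bind_rows(purrr::map(maint, "results"))

  alpha <- alpha_diversity(ft) |>
    dplyr::left_join(metadata_kept, by = "sample_id")

  beta_ft <- ft
  if (beta_on_core) {
    core_union <- unique(unlist(purrr::map(cores, "asv_id")))
    beta_ft <- dplyr::filter(ft, .data$asv_id %in% core_union)
    beta_ft <- filter_samples_by_depth(beta_ft, 1)  # drop empty samples
  }
  distances <- list(bray_curtis = pairwise_distances(beta_ft,
                                                     "bray_curtis"))
  if (!is.null(tree)) {
    distances$unweighted_unifrac <- pairwise_distances(
      beta_ft, "unweighted_unifrac", tree = tree, drop_missing = TRUE
    )
  }
  pcoa <- purrr::map(distances, pcoa_ordination)
  donor_distance <- distance_to_donor(beta_ft, metadata_kept,
                                      metric = "bray_curtis")

  out <- list(
    validation = validation, filtered_table = ft, cores = cores,
    core_fractions = core_fractions, shared_core = shared_core,
    calls = calls, summary = summary, contingency = contingency,
    rollups = rollups, union_rollups = union_rollups,
    maintenance = maintenance, maintenance_results = maintenance_results,
    alpha = alpha, distances = distances, pcoa = pcoa,
    donor_distance = donor_distance, design = design
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")), na = "")
  }
  w(dplyr::bind_rows(out$cores), "core_sets")
  w(out$core_fractions, "core_read_fractions")
  w(tibble::tibble(asv_id = out$shared_core), "shared_core_asvs")
  w(dplyr::select(out$calls, -dplyr::any_of("day_fraction")),
    "colonization_calls")
  w(out$summary, "engraftment_summary")
  if (nrow(out$contingency) > 0) w(out$contingency, "cross_model_contingency")
  if (!is.null(out$rollups)) w(out$rollups, "taxon_rollups")
  if (!is.null(out$union_rollups)) w(out$union_rollups,
                                     "union_taxon_rollups")
  w(out$maintenance, "maintenance_calls")
  if (nrow(out$maintenance_results) > 0) {
    w(out$maintenance_results, "maintenance_tests")
  }
  w(out$alpha, "alpha_diversity")
  for (metric in names(out$distances)) {
    m <- as.matrix(out$distances[[metric]])
    w(tibble::as_tibble(m, rownames = "sample_id"),
      paste0("distance_", metric))
    w(out$pcoa[[metric]]$coordinates, paste0("pcoa_", metric))
  }
  w(out$donor_distance, "distance_to_donor")
  manifest <- tibble::tibble(
    key = c("n_samples", "n_asvs", "min_sample_depth",
            "detection_min_count", "persistence_min_timepoints",
            "persistence_fraction", "alpha", "schedule"),
    value = c(dplyr::n_distinct(out$filtered_table$sample_id),
              dplyr::n_distinct(out$filtered_table$asv_id),
              out$design$min_sample_depth, out$design$detection_min_count,
              out$design$persistence_min_timepoints,
              out$design$persistence_fraction, out$design$alpha,
              paste(out$design$schedule, collapse = ","))
  )
  w(manifest, "run_manifest")
  invisible(out_dir)
}
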