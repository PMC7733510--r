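#' Host specification for the colonization simulator
#'
#' Describes one recipient animal model: how many animals receive the
#' inoculum, the per-phylum probability that a donor ASV establishes in an
#' individual animal, how strongly established abundances are distorted away
#' from the donor profile, the per-time-point loss rate, and the sequencing
#' depth of fecal samples.
#'
#' @param host Host label, e.g. `"mouse"` or `"piglet"`.
#' @param n_animals Number of animals in the group.
#' @param colonization_prob Named numeric vector of per-phylum probabilities
#'   that a donor ASV colonizes an individual animal; names must cover the
#'   simulated phyla. An unnamed scalar applies to all phyla.
#' @param modulation_sigma SD (log scale) of the multiplicative log-normal
#'   distortion applied to established abundances within each animal, which
#'   are then renormalised. 0 preserves donor proportions.
#' @param extinction_prob Probability that a carried ASV is lost in an animal
#'   between consecutive scheduled days (absorbing: no recolonization).
#' @param fecal_depth Reads per fecal sample (multinomial size).
#' @param dropout Optional tibble with columns `subject` (animal index) and
#'   `last_day`; samples after `last_day` are not collected, emulating animal
#'   deaths.
#' @return A `host_spec` list.
#' @export
host_spec <- function(host, n_animals, colonization_prob,
                      modulation_sigma = 1, extinction_prob = 0.05,
                      fecal_depth = 45000, dropout = NULL) {
  stopifnot(n_animals >= 1,
            all(colonization_prob >= 0), all(colonization_prob <= 1),
            modulation_sigma >= 0,
            extinction_prob >= 0, extinction_prob <= 1,
            fecal_depth > 0)
  structure(list(host = host, n_animals = as.integer(n_animals),
                 colonization_prob = colonization_prob,
                 modulation_sigma = modulation_sigma,
                 extinction_prob = extinction_prob,
                 fecal_depth = fecal_depth, dropout = dropout),
            class = "host_spec")
}

#' Simulation configuration for a complete engraftment study
#'
#' The defaults emulate the layout of a two-host gnotobiotic transplant
#' study: four donors whose inocula span roughly 25-140 ASVs, 3-4 sequenced
#' inoculum aliquots per donor at ~40,000 reads, ten mice and three piglets
#' per donor sampled on days 2, 7, 14, 21, 28, 35 and 40 at fecal depths
#' around 45,000 (mice) and 38,000 (piglets) reads, with phylum-structured
#' host selectivity (Firmicutes colonize piglets far more readily than mice
#' while Bacteroidetes colonize both).
#'
#' @param donors Tibble with columns `donor_id`, `n_asvs`, `n_aliquots`.
#' @param lognormal_mu,lognormal_sigma Log-normal parameters of the donor
#'   relative-abundance draws (mu cancels on normalisation; sigma 1.5 gives
#'   realistic rank-abundance curves spanning several orders of magnitude).
#' @param phylum_weights Named mixture weights assigning each ASV a phylum;
#'   must sum to 1.
#' @param aliquot_depth Reads per inoculum aliquot.
#' @param hosts List of [host_spec()] objects.
#' @param schedule Fecal sampling days.
#' @param pool_size Size of the shared ASV identifier pool donors draw from;
#'   overlap between donors creates ASVs shared across cores.
#' @param seed Integer seed; all randomness in [simulate_study()] flows from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(donors = tibble::tibble(
                         donor_id = paste0("D", 1:4),
                         n_asvs = c(26L, 76L, 140L, 134L),
                         n_aliquots = c(3L, 4L, 4L, 4L)
                       ),
                       lognormal_mu = 0, lognormal_sigma = 1.5,
                       phylum_weights = c(
                         Firmicutes = 0.60, Bacteroidetes = 0.25,
                         Actinobacteriota = 0.08, Proteobacteria = 0.05,
                         Desulfobacterota = 0.02
                       ),
                       aliquot_depth = 40000,
                       hosts = list(
                         host_spec("mouse", n_animals = 10,
                                   colonization_prob = c(
                                     Firmicutes = 0.15, Bacteroidetes = 0.85,
                                     Actinobacteriota = 0.50,
                                     Proteobacteria = 0.40,
                                     Desulfobacterota = 0.40),
                                   fecal_depth = 45000),
                         host_spec("piglet", n_animals = 3,
                                   colonization_prob = c(
                                     Firmicutes = 0.75, Bacteroidetes = 0.90,
                                     Actinobacteriota = 0.70,
                                     Proteobacteria = 0.60,
                                     Desulfobacterota = 0.60),
                                   fecal_depth = 38000)
                       ),
                       schedule = c(2L, 7L, 14L, 21L, 28L, 35L, 40L),
                       pool_size = 400, seed = 1L) {
  stopifnot(all(c("donor_id", "n_asvs", "n_aliquots") %in% names(donors)),
            all(donors$n_asvs >= 1), all(donors$n_aliquots >= 1),
            lognormal_sigma >= 0, aliquot_depth > 0,
            abs(sum(phylum_weights) - 1) < 1e-8, all(phylum_weights >= 0),
            pool_size >= max(donors$n_asvs), length(hosts) >= 1)
  structure(list(donors = tibble::as_tibble(donors),
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 phylum_weights = phylum_weights,
                 aliquot_depth = aliquot_depth, hosts = hosts,
                 schedule = as.integer(schedule),
                 pool_size = as.integer(pool_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw one donor's true inoculum community
#'
#' ASV identifiers are sampled from the shared pool, phyla are assigned by
#' the mixture weights, and relative abundances are independent log-normal
#' draws normalised to sum to 1 (with `lognormal_sigma = 0` every ASV gets
#' abundance 1/n). Consumes the current RNG stream; [simulate_study()] seeds
#' it.
#'
#' @param config A [sim_config()].
#' @param donor_id Donor identifier (a row of `config$donors`).
#' @return A tibble with columns `asv_id`, `phylum`, `abundance` (strictly
#'   positive, summing to 1).
#' @export
simulate_donor <- function(config, donor_id) {
  row <- config$donors[config$donors$donor_id == donor_id, ]
  if (nrow(row) != 1) stop("unknown donor '", donor_id, "'", call. = FALSE)
  n <- row$n_asvs
  if (n < 1) stop("n_asvs must be >= 1", call. = FALSE)
  pool <- sprintf("ASV_%04d", seq_len(config$pool_size))
  # Zipf-weighted draws: low-rank pool members are common to most donors,
  # emulating the heavy-tailed prevalence of gut taxa across people (and
  # hence cores shared between donors)
  ids <- sort(sample(pool, n, prob = 1 / seq_len(config$pool_size)))
  # phylum is a deterministic function of the pool identifier so that an ASV
  # shared by two donors carries one lineage
  phyla <- pool_phyla(config)[ids]
  ab <- rlnorm(n, meanlog = config$lognormal_mu,
               sdlog = config$lognormal_sigma)
  tibble::tibble(asv_id = ids, phylum = unname(phyla),
                 abundance = ab / sum(ab))
}

# Deterministic phylum assignment over the identifier pool, so an ASV shared
# by two donors carries one lineage. Phyla are interleaved by quantile across
# the pool rank order, keeping the mixture proportions stable over any rank
# range (donor draws are rank-weighted).
pool_phyla <- function(config) {
  n <- config$pool_size
  counts <- floor(config$phylum_weights * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(config$phylum_weights * n - counts, decreasing = TRUE)
    counts[top[seq_len(rem)]] <- counts[top[seq_len(rem)]] + 1
  }
  ids <- sprintf("ASV_%04d", seq_len(n))
  pos <- unlist(lapply(counts, function(k) (seq_len(k) - 0.5) / k))
  labels <- rep(names(counts), counts)
  setNames(labels[order(pos)], ids)
}

#' Sequence inoculum aliquots from a true donor community
#'
#' Each aliquot is an independent multinomial draw of `depth` reads from the
#' true abundance vector.
#'
#' @param donor A donor community ([simulate_donor()]).
#' @param donor_id Donor identifier used in sample names.
#' @param n_aliquots Number of aliquots to sequence.
#' @param depth Reads per aliquot.
#' @return A list with `table` (feature table of the aliquots) and
#'   `metadata` (inoculum metadata rows).
#' @export
sample_aliquots <- function(donor, donor_id, n_aliquots, depth) {
  stopifnot(abs(sum(donor$abundance) - 1) < 1e-8, depth > 0)
  counts <- rmultinom(n_aliquots, size = depth, prob = donor$abundance)
  sample_ids <- sprintf("%s_inoc_%d", donor_id, seq_len(n_aliquots))
  ft <- tibble::tibble(
    sample_id = rep(sample_ids, each = nrow(donor)),
    asv_id = rep(donor$asv_id, times = n_aliquots),
    count = as.integer(counts)
  )
  meta <- tibble::tibble(
    sample_id = sample_ids, donor_id = donor_id, host = "human_donor",
    sample_type = "inoculum", subject_id = NA_character_,
    day_post_inoculation = NA_integer_
  )
  list(table = validate_feature_table(ft), metadata = meta)
}

#' Simulate longitudinal colonization of one host group
#'
#' Generative model, per animal: each donor ASV colonizes independently with
#' the phylum's colonization probability; established ASVs take the donor
#' abundance times a log-normal distortion and are renormalised within the
#' animal; between consecutive scheduled days each still-carried ASV is lost
#' with the extinction probability (absorbing); each (animal, day) fecal
#' sample is a multinomial draw of `fecal_depth` reads over the currently
#' carried community. Animals carrying nothing yield all-zero samples, which
#' the standard depth filter later removes.
#'
#' @param donor A donor community ([simulate_donor()]).
#' @param donor_id Donor identifier.
#' @param spec A [host_spec()].
#' @param schedule Sampling days.
#' @param design A [study_design()] whose majority rule defines the
#'   carriage-based ground-truth persistence labels.
#' @return A list with `table`, `metadata`, and `truth` -- the latter a list
#'   of tibbles `animal` (per animal x ASV colonization flags), `carriage`
#'   (per animal x ASV x day carried flags), and `asv` (per-ASV
#'   `true_colonizer` / `true_persistent` labels computed on carriage with
#'   the same majority rule as the classifier).
#' @export
simulate_engraftment <- function(donor, donor_id, spec,
                                 schedule = c(2L, 7L, 14L, 21L, 28L, 35L,
                                              40L),
                                 design = study_design(schedule = schedule)) {
  n_asv <- nrow(donor)
  n_days <- length(schedule)
  probs <- colonization_probs(donor, spec)

  tables <- list(); carriage_rows <- list(); animal_rows <- list()
  for (j in seq_len(spec$n_animals)) {
    subject <- sprintf("%s_%s_%02d", donor_id, spec$host, j)
    colonized <- runif(n_asv) < probs
    weight <- donor$abundance *
      exp(rnorm(n_asv, 0, spec$modulation_sigma)) * colonized
    if (sum(weight) > 0) weight <- weight / sum(weight)

    last_day <- max(schedule)
    if (!is.null(spec$dropout)) {
      hit <- spec$dropout$subject == j
      if (any(hit)) last_day <- spec$dropout$last_day[hit][1]
    }

    carried <- matrix(FALSE, n_asv, n_days)
    carried[, 1] <- colonized
    if (n_days > 1) {
      for (k in 2:n_days) {
        carried[, k] <- carried[, k - 1] &
          (runif(n_asv) >= spec$extinction_prob)
      }
    }

    sampled_days <- schedule[schedule <= last_day]
    counts <- matrix(0L, n_asv, length(sampled_days))
    for (k in seq_along(sampled_days)) {
      w <- weight * carried[, match(sampled_days[k], schedule)]
      if (sum(w) > 0) {
        counts[, k] <- as.integer(
          rmultinom(1, size = spec$fecal_depth, prob = w / sum(w))
        )
      }
    }
    sample_ids <- sprintf("%s_d%02d", subject, sampled_days)
    tables[[j]] <- tibble::tibble(
      sample_id = rep(sample_ids, each = n_asv),
      asv_id = rep(donor$asv_id, times = length(sampled_days)),
      count = as.integer(counts),
      subject_id = subject,
      day_post_inoculation = rep(sampled_days, each = n_asv)
    )
    animal_rows[[j]] <- tibble::tibble(
      donor_id = donor_id, host = spec$host, subject_id = subject,
      asv_id = donor$asv_id, colonized = colonized
    )
    carriage_rows[[j]] <- tibble::tibble(
      donor_id = donor_id, host = spec$host, subject_id = subject,
      asv_id = rep(donor$asv_id, times = n_days),
      day = rep(schedule, each = n_asv),
      carried = as.vector(carried),
      sampled = rep(schedule <= last_day, each = n_asv)
    )
  }
  long <- dplyr::bind_rows(tables)
  meta <- long |>
    dplyr::distinct(.data$sample_id, .data$subject_id,
                    .data$day_post_inoculation) |>
    dplyr::mutate(donor_id = donor_id, host = spec$host,
                  sample_type = "fecal") |>
    dplyr::select("sample_id", "donor_id", "host", "sample_type",
                  "subject_id", "day_post_inoculation")
  ft <- validate_feature_table(
    long[c("sample_id", "asv_id", "count")]
  )
  carriage <- dplyr::bind_rows(carriage_rows)
  truth_asv <- carriage_truth_labels(carriage, donor_id, spec$host, design)
  list(table = ft, metadata = meta,
       truth = list(animal = dplyr::bind_rows(animal_rows),
                    carriage = carriage, asv = truth_asv))
}

colonization_probs <- function(donor, spec) {
  p <- spec$colonization_prob
  if (is.null(names(p)) && length(p) == 1) {
    return(rep(p, nrow(donor)))
  }
  missing <- setdiff(unique(donor$phylum), names(p))
  if (length(missing) > 0) {
    stop("host spec lacks colonization_prob for phylum: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(p[donor$phylum])
}

# Ground-truth labels on pre-sequencing carriage, using the same majority /
# minimum-timepoint rule as the classifier (denominator: animals with a
# sample on that day).
carriage_truth_labels <- function(carriage, donor_id, host, design) {
  frac <- carriage |>
    dplyr::filter(.data$sampled) |>
    dplyr::group_by(.data$asv_id, .data$day) |>
    dplyr::summarise(fraction = mean(.data$carried), .groups = "drop")
  frac |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(
      true_colonizer = any(.data$fraction > 0),
      true_n_majority = sum(.data$fraction > design$persistence_fraction),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      donor_id = donor_id, host = host,
      true_persistent = .data$true_colonizer &
        .data$true_n_majority >= design$persistence_min_timepoints
    ) |>
    dplyr::select("donor_id", "host", "asv_id", "true_colonizer",
                  "true_n_majority", "true_persistent")
}

#' Simulate a complete multi-donor, multi-host engraftment study
#'
#' Runs [simulate_donor()], [sample_aliquots()] and [simulate_engraftment()]
#' for every donor and host in the configuration, concatenates the results,
#' and returns them together with full ground truth. Deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (feature table over the union of donor ASVs),
#'   `metadata`, `taxonomy` (phylum-level lineage per pool ASV present),
#'   `truth` (list of tibbles: `animal`, `carriage`, `asv`), and
#'   `donor_truth` (true abundance vectors).
#' @export
simulate_study <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    tables <- list(); metas <- list(); truths <- list(); donors <- list()
    for (i in seq_len(nrow(config$donors))) {
      d_id <- config$donors$donor_id[i]
      donor <- simulate_donor(config, d_id)
      donors[[d_id]] <- dplyr::mutate(donor, donor_id = d_id)
      al <- sample_aliquots(donor, d_id, config$donors$n_aliquots[i],
                            config$aliquot_depth)
      tables <- c(tables, list(dplyr::mutate(al$table, donor_id = d_id)))
      metas <- c(metas, list(al$metadata))
      for (spec in config$hosts) {
        eng <- simulate_engraftment(
          donor, d_id, spec, schedule = config$schedule,
          design = study_design(schedule = config$schedule)
        )
        tables <- c(tables, list(dplyr::mutate(eng$table, donor_id = d_id)))
        metas <- c(metas, list(eng$metadata))
        truths <- c(truths, list(eng$truth))
      }
    }
    long <- dplyr::bind_rows(tables)
    # dense over the union of all donors' ASVs
    ft <- complete_feature_table(
      long[c("sample_id", "asv_id", "count")],
      sample_ids = unique(long$sample_id),
      asv_ids = sort(unique(long$asv_id))
    )
    metadata <- dplyr::bind_rows(metas)
    phyla <- pool_phyla(config)
    present <- sort(unique(long$asv_id))
    taxonomy <- tibble::tibble(
      asv_id = present, domain = "Bacteria",
      phylum = unname(phyla[present]),
      class = NA_character_, order = NA_character_,
      family = NA_character_, genus = NA_character_,
      species = NA_character_
    )
    list(
      table = ft, metadata = metadata, taxonomy = taxonomy,
      truth = list(
        animal = dplyr::bind_rows(purrr::map(truths, "animal")),
        carriage = dplyr::bind_rows(purrr::map(truths, "carriage")),
        asv = dplyr::bind_rows(purrr::map(truths, "asv"))
      ),
      donor_truth = dplyr::bind_rows(donors)
    )
  })
}
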