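#' Median-of-ratios size factors
#'
#' Library-size normalisation for count comparisons: the reference profile is
#' the per-ASV geometric mean over samples, restricted to ASVs with strictly
#' positive counts in every sample; each sample's factor is the median over
#' those ASVs of count / reference. With sparse tables no ASV may be
#' everywhere-positive; `pseudocount = TRUE` then adds 1 to every cell before
#' the computation.
#'
#' @param ft A feature table covering the samples to normalise (>= 2
#'   samples).
#' @param pseudocount Add 1 to all cells before computing (default FALSE).
#' @return A tibble with columns `sample_id`, `size_factor` (all > 0).
#' @export
size_factors_median_of_ratios <- function(ft, pseudocount = FALSE) {
  m <- ft_matrix(validate_feature_table(ft))
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (pseudocount) m <- m + 1L
  all_pos <- colSums(m > 0) == nrow(m)
  if (!any(all_pos)) {
    stop("no ASV has positive counts in every sample; ",
         "re-run with pseudocount = TRUE", call. = FALSE)
  }
  sub <- m[, all_pos, drop = FALSE]
  ref <- exp(colMeans(log(sub)))          # per-ASV geometric mean
  ratios <- sweep(sub, 2, ref, "/")
  factors <- apply(ratios, 1, median)
  tibble::tibble(sample_id = rownames(m), size_factor = unname(factors))
}

#' Two-group differential abundance test per ASV
#'
#' Compares animal fecal counts against donor inoculum counts for every ASV
#' in the table, in one of two modes:
#'
#' * `nb_wald` -- counts are divided by median-of-ratios size factors, group
#'   means are compared on the log scale with a Wald statistic whose
#'   standard error comes from the negative-binomial variance
#'   \eqn{\mu + \alpha \mu^2}; the per-ASV dispersion \eqn{\alpha} is a
#'   pooled method-of-moments estimate (floored at 1e-8). Because the
#'   dispersion is estimated from a handful of samples, the statistic is
#'   referred to a t distribution with `n1 + n2 - 2` degrees of freedom
#'   rather than the normal -- at these group sizes the normal reference is
#'   markedly anticonservative.
#' * `rank_sum` -- Wilcoxon rank-sum on within-sample relative abundances
#'   (normal approximation with continuity and tie correction; exact when
#'   both groups are small and untied).
#'
#' The reported `log2_fold_change` (treatment vs reference) always uses a
#' pseudocount of 0.5 on the normalised group means; the test itself never
#' uses a pseudocount except in the degenerate case where exactly one group
#' is all zero (an offset of 0.5/n is then applied to both group means to
#' keep the Wald statistic finite). ASVs with zero counts in both groups get
#' p = 1 and log2FC = 0 by convention.
#'
#' @param ft A feature table containing both groups' samples (all ASVs; for
#'   `rank_sum` the within-sample totals come from this table).
#' @param groups A tibble with columns `sample_id`, `group`; `group` must
#'   take exactly two values.
#' @param reference The `group` level used as baseline (the donor inoculum);
#'   defaults to the first level alphabetically.
#' @param mode `"nb_wald"` or `"rank_sum"`.
#' @param size_factors Optional precomputed tibble (`sample_id`,
#'   `size_factor`); computed from `ft` when absent (nb_wald only).
#' @return A tibble with one row per ASV: `asv_id`, `log2_fold_change`,
#'   `p_value`, `test_mode`, plus the normalised group means `mean_reference`
#'   and `mean_treatment`.
#' @export
differential_test <- function(ft, groups, reference = NULL,
                              mode = c("nb_wald", "rank_sum"),
                              size_factors = NULL) {
  mode <- match.arg(mode)
  groups <- tibble::as_tibble(groups)
  levels <- sort(unique(groups$group))
  if (length(levels) != 2) {
    stop("groups must define exactly two levels", call. = FALSE)
  }
  reference <- reference %||% levels[1]
  treatment <- setdiff(levels, reference)
  if (!reference %in% levels) {
    stop("reference level '", reference, "' not present", call. = FALSE)
  }
  ids_ref <- groups$sample_id[groups$group == reference]
  ids_trt <- groups$sample_id[groups$group == treatment]
  if (length(ids_ref) < 2 || length(ids_trt) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  sub <- dplyr::filter(ft, .data$sample_id %in% c(ids_ref, ids_trt))
  m <- ft_matrix(validate_feature_table(sub))

  if (mode == "nb_wald") {
    sf <- size_factors %||% size_factors_median_of_ratios(
      sub, pseudocount = !any(colSums(m > 0) == nrow(m))
    )
    fac <- setNames(sf$size_factor, sf$sample_id)[rownames(m)]
    norm <- m / fac
    res <- nb_wald_rows(norm[ids_ref, , drop = FALSE],
                        norm[ids_trt, , drop = FALSE])
  } else {
    rel <- m / rowSums(m)
    res <- purrr::map_dfr(colnames(m), function(a) {
      x <- rel[ids_ref, a]; y <- rel[ids_trt, a]
      if (all(m[, a] == 0)) {
        return(tibble::tibble(asv_id = a, log2_fold_change = 0,
                              p_value = 1,
                              mean_reference = 0, mean_treatment = 0))
      }
      p <- rank_sum_test(y, x)$p_value
      tibble::tibble(
        asv_id = a,
        log2_fold_change = log2((mean(y) + .Machine$double.eps) /
                                  (mean(x) + .Machine$double.eps)),
        p_value = p,
        mean_reference = mean(x), mean_treatment = mean(y)
      )
    })
  }
  dplyr::mutate(res, test_mode = mode)
}

# Vectorised NB Wald over the columns of two normalised count matrices
# (rows = samples). Returns one row per ASV.
nb_wald_rows <- function(ref, trt) {
  n1 <- nrow(ref); n2 <- nrow(trt)
  m1 <- colMeans(ref); m2 <- colMeans(trt)
  v1 <- apply(ref, 2, var); v2 <- apply(trt, 2, var)
  # pooled method-of-moments dispersion: excess variance over the mean,
  # relative to the squared mean, df-weighted across the two groups
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, 0)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, 0)
  w1 <- ifelse(m1 > 0, n1 - 1, 0)
  w2 <- ifelse(m2 > 0, n2 - 1, 0)
  alpha <- pmax((w1 * a1 + w2 * a2) / pmax(w1 + w2, 1), 1e-8)

  both_zero <- m1 == 0 & m2 == 0
  one_zero <- !both_zero & (m1 == 0 | m2 == 0)
  # continuity offset only when one group is entirely zero
  m1a <- ifelse(one_zero, m1 + 0.5 / n1, m1)
  m2a <- ifelse(one_zero, m2 + 0.5 / n2, m2)

  se <- sqrt((1 / m1a + alpha) / n1 + (1 / m2a + alpha) / n2)
  stat <- (log(m2a) - log(m1a)) / se
  p <- 2 * pt(-abs(stat), df = n1 + n2 - 2)
  p[both_zero] <- 1
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  lfc[both_zero] <- 0
  tibble::tibble(
    asv_id = colnames(ref),
    log2_fold_change = unname(lfc),
    p_value = unname(p),
    mean_reference = unname(m1),
    mean_treatment = unname(m2)
  )
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with
#' input validation and order preservation.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Classify donor-like abundance maintenance
#'
#' A persistent colonizer maintained a *donor-like* relative abundance when
#' its abundance in the animals was not significantly different from the
#' donor inoculum (BH-adjusted p >= alpha) on at least
#' `persistence_min_timepoints` of the scheduled days. Days without a test
#' result (e.g. no samples) count as neither significant nor
#' non-significant, which makes the rule conservative under missingness.
#'
#' @param results Per-day test results: a tibble with columns `asv_id`,
#'   `day`, `p_adjusted` (and optionally more, passed through from
#'   [maintenance_analysis()]).
#' @param design A [study_design()] (supplies `alpha` and the day
#'   threshold).
#' @return A tibble per ASV: `asv_id`, `n_nonsignificant_days`,
#'   `donor_like`.
#' @export
classify_donor_like <- function(results, design = study_design()) {
  results |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(
      n_nonsignificant_days = sum(!is.na(.data$p_adjusted) &
                                    .data$p_adjusted >= design$alpha),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      donor_like = .data$n_nonsignificant_days >=
        design$persistence_min_timepoints
    )
}

#' Donor-like abundance maintenance analysis for one donor-host group
#'
#' Orchestrates the per-time-point differential testing behind the
#' maintenance call: for every scheduled day, the fecal samples of the group
#' taken that day are compared against the donor's inoculum aliquots
#' ([differential_test()]); p values are BH-adjusted across the tested ASVs
#' within each day (the multiple-testing family is one donor x host x day
#' comparison); and the per-ASV day counts are aggregated by
#' [classify_donor_like()]. Only ASVs already called persistent colonizers
#' are tested; days where either side has fewer than two samples are skipped
#' with a message.
#'
#' @param ft The full feature table.
#' @param metadata Sample metadata.
#' @param calls Colonization calls for the donor-host group
#'   ([classify_persistent()]).
#' @param design A [study_design()].
#' @param mode Test mode passed to [differential_test()].
#' @return A list with `results` (per ASV x day: `log2_fold_change`,
#'   `p_value`, `p_adjusted`, `test_mode`) and `maintenance` (per-ASV calls:
#'   `donor_id`, `host`, `asv_id`, `n_nonsignificant_days`, `donor_like`).
#' @export
maintenance_analysis <- function(ft, metadata, calls,
                                 design = study_design(),
                                 mode = c("nb_wald", "rank_sum")) {
  mode <- match.arg(mode)
  metadata <- validate_sample_metadata(metadata)
  donor <- unique(calls$donor_id)
  host <- unique(calls$host)
  stopifnot(length(donor) == 1, length(host) == 1)
  persistent <- calls$asv_id[calls$status == "persistent_colonizer"]
  skipped <- calls$asv_id[calls$status != "persistent_colonizer"]
  if (length(skipped) > 0) {
    message(length(skipped), " non-persistent ASV(s) skipped for donor '",
            donor, "', host '", host, "'")
  }
  if (length(persistent) == 0) {
    return(list(results = tibble::tibble(), maintenance = tibble::tibble(
      donor_id = character(), host = character(), asv_id = character(),
      n_nonsignificant_days = integer(), donor_like = logical()
    )))
  }
  inoc <- metadata |>
    dplyr::filter(.data$donor_id == !!donor,
                  .data$sample_type == "inoculum",
                  .data$sample_id %in% unique(ft$sample_id))
  fecal <- fecal_samples(ft, metadata, donor, host)

  day_results <- purrr::map(design$schedule, function(d) {
    day_ids <- fecal$sample_id[fecal$day_post_inoculation == d]
    if (length(day_ids) < 2 || nrow(inoc) < 2) {
      message("day ", d, ": fewer than 2 samples on one side; not tested")
      return(NULL)
    }
    groups <- tibble::tibble(
      sample_id = c(inoc$sample_id, day_ids),
      group = rep(c("donor", "animal"),
                  c(nrow(inoc), length(day_ids)))
    )
    res <- differential_test(
      dplyr::filter(ft, .data$sample_id %in% groups$sample_id),
      groups, reference = "donor", mode = mode
    ) |>
      dplyr::filter(.data$asv_id %in% persistent) |>
      dplyr::mutate(day = d, p_adjusted = bh_adjust(.data$p_value))
    res
  })
  results <- dplyr::bind_rows(day_results)
  maintenance <- classify_donor_like(results, design) |>
    dplyr::mutate(donor_id = donor, host = host) |>
    dplyr::select("donor_id", "host", "asv_id",
                  "n_nonsignificant_days", "donor_like")
  # persistent ASVs with no tested day at all still get a (negative) call
  untested <- setdiff(persistent, maintenance$asv_id)
  if (length(untested) > 0) {
    maintenance <- dplyr::bind_rows(
      maintenance,
      tibble::tibble(donor_id = donor, host = host, asv_id = untested,
                     n_nonsignificant_days = 0L, donor_like = FALSE)
    )
  }
  list(results = results, maintenance = maintenance)
}
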