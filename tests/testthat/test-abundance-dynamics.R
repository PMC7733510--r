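test_that("size factors match the definition on hand cases and random tables", {
  # identical samples -> factors 1
  m <- matrix(c(5L, 9L, 2L, 5L, 9L, 2L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  sf <- size_factors_median_of_ratios(feature_table(m))
  expect_equal(sf$size_factor, c(1, 1))

  # exact doubling -> factor ratio 2
  m2 <- rbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  colnames(m2) <- c("a", "b", "c")
  sf2 <- size_factors_median_of_ratios(feature_table(m2))
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1], 2)

  # random tables vs brute-force enumeration and DESeq2
  set.seed(7)
  for (rep in 1:5) {
    mr <- matrix(rpois(40, 50) + 1L, 5, 8)
    dimnames(mr) <- list(paste0("s", 1:5), paste0("g", 1:8))
    got <- size_factors_median_of_ratios(feature_table(mr))
    expect_equal(got$size_factor[match(paste0("s", 1:5), got$sample_id)],
                 unname(brute_force_size_factors(mr)))
    if (requireNamespace("DESeq2", quietly = TRUE)) {
      # DESeq2 takes the median on the log scale, which differs from the
      # natural-scale median only at even-count midpoints
      ref <- DESeq2::estimateSizeFactorsForMatrix(t(mr))
      expect_equal(got$size_factor[match(names(ref), got$sample_id)],
                   unname(ref), tolerance = 2e-2)
    }
  }

  # all-zero-containing table needs the pseudocount escape hatch
  m3 <- rbind(s1 = c(0L, 5L), s2 = c(4L, 0L))
  colnames(m3) <- c("a", "b")
  expect_error(size_factors_median_of_ratios(feature_table(m3)),
               "pseudocount")
  sf3 <- size_factors_median_of_ratios(feature_table(m3),
                                       pseudocount = TRUE)
  expect_true(all(sf3$size_factor > 0))
})

test_that("BH adjustment equals the brute-force step-up on short vectors", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(31)
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9)
  for (rep in 1:50) {
    p <- sample(grid, sample(1:8, 1), replace = TRUE)
    adj <- bh_adjust(p)
    expect_equal(adj, brute_force_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("identical groups give null results; both-zero ASVs p = 1", {
  m <- rbind(a1 = c(50L, 30L, 0L), a2 = c(50L, 30L, 0L),
             b1 = c(50L, 30L, 0L), b2 = c(50L, 30L, 0L))
  colnames(m) <- c("g1", "g2", "g3")
  groups <- tibble::tibble(sample_id = rownames(m),
                           group = c("donor", "donor", "animal", "animal"))
  res <- differential_test(feature_table(m), groups, reference = "donor")
  expect_equal(res$log2_fold_change, rep(0, 3))
  expect_true(all(res$p_value > 0.99))
  expect_equal(res$p_value[res$asv_id == "g3"], 1)

  expect_error(
    differential_test(feature_table(m[1:3, ]),
                      groups[1:3, ], reference = "donor"),
    "at least 2"
  )
})

test_that("a strong enrichment is detected with high power", {
  set.seed(55)
  hits <- 0
  n_rep <- 60
  for (rep in seq_len(n_rep)) {
    m <- matrix(0L, 8, 5)
    m[1:4, ] <- rnbinom(20, mu = 150, size = 10)
    m[5:8, ] <- rnbinom(20, mu = 150, size = 10)
    m[5:8, 1] <- rnbinom(4, mu = 150 * 100, size = 10)  # 100x in animals
    dimnames(m) <- list(c(paste0("d", 1:4), paste0("an", 1:4)),
                        paste0("g", 1:5))
    groups <- tibble::tibble(sample_id = rownames(m),
                             group = rep(c("donor", "animal"), each = 4))
    res <- differential_test(feature_table(m), groups,
                             reference = "donor")
    padj <- bh_adjust(res$p_value)
    if (padj[res$asv_id == "g1"] < 0.05 &&
        res$log2_fold_change[res$asv_id == "g1"] > 0) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.9)
})

test_that("rank-sum mode matches exhaustive permutation enumeration", {
  m <- rbind(d1 = c(1L, 9L), d2 = c(2L, 8L), d3 = c(3L, 7L),
             an1 = c(4L, 6L), an2 = c(5L, 5L), an3 = c(6L, 4L))
  colnames(m) <- c("g1", "g2")
  groups <- tibble::tibble(sample_id = rownames(m),
                           group = rep(c("donor", "animal"), each = 3))
  res <- differential_test(feature_table(m), groups, reference = "donor",
                           mode = "rank_sum")
  # relative abundances of g1: donor (0.1, 0.2, 0.3), animal (0.4, 0.5,
  # 0.6) -> maximal separation; enumerate all C(6,3)=20 rank splits
  splits <- utils::combn(6, 3)
  stat <- function(idx) sum(seq_len(6)[idx])
  obs <- stat(c(4, 5, 6))
  null_stats <- apply(splits, 2, function(s) stat(seq_len(6) %in% s))
  p_exact <- mean(abs(null_stats - mean(null_stats)) >=
                    abs(obs - mean(null_stats)))
  expect_equal(res$p_value[res$asv_id == "g1"], p_exact)
  expect_equal(res$test_mode, rep("rank_sum", 2))
})

test_that("donor-like classification applies the day-count rule", {
  mk <- function(padj) tibble::tibble(
    asv_id = "a1", day = seq_along(padj), p_adjusted = padj
  )
  # non-significant on exactly 4 of 7 days -> donor-like
  r4 <- classify_donor_like(mk(c(0.2, 0.3, 0.5, 0.9, 0.01, 0.01, 0.01)))
  expect_true(r4$donor_like)
  expect_equal(r4$n_nonsignificant_days, 4)
  # 3 days -> not donor-like
  r3 <- classify_donor_like(mk(c(0.2, 0.3, 0.5, 0.01, 0.01, 0.01, 0.01)))
  expect_false(r3$donor_like)
  # missing days count as neither
  rm <- classify_donor_like(mk(c(0.2, 0.3, 0.5, NA, NA, NA, NA)))
  expect_equal(rm$n_nonsignificant_days, 3)
  expect_false(rm$donor_like)
  # boundary: adjusted p exactly alpha counts as non-significant
  rb <- classify_donor_like(mk(c(0.05, 0.05, 0.05, 0.05, 0, 0, 0)))
  expect_true(rb$donor_like)
})

test_that("lowering alpha never decreases the non-significant day count", {
  set.seed(77)
  for (rep in 1:20) {
    padj <- runif(7)
    res <- tibble::tibble(asv_id = "a", day = 1:7, p_adjusted = padj)
    counts <- purrr::map_int(
      c(0.1, 0.05, 0.01, 0.001),
      ~ classify_donor_like(res, study_design(alpha = .x))$
        n_nonsignificant_days
    )
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("maintenance analysis tests persistent ASVs per day with BH within day", {
  sim <- simulate_study(small_sim_config(seed = 13))
  ft <- filter_samples_by_depth(sim$table, 10500)
  core <- identify_core_asvs(ft, sim$metadata, "D1")
  calls <- classify_persistent(ft, sim$metadata, "D1", "piglet", core)
  out <- suppressMessages(
    maintenance_analysis(ft, sim$metadata, calls)
  )
  persistent <- calls$asv_id[calls$status == "persistent_colonizer"]
  expect_setequal(unique(out$results$asv_id), persistent)
  expect_setequal(out$maintenance$asv_id, persistent)
  # BH family is one day across ASVs
  one_day <- dplyr::filter(out$results, day == out$results$day[1])
  expect_equal(one_day$p_adjusted, bh_adjust(one_day$p_value))
  expect_true(all(out$maintenance$n_nonsignificant_days >= 0 &
                    out$maintenance$n_nonsignificant_days <= 7))
  # donor_like consistent with the threshold
  expect_equal(out$maintenance$donor_like,
               out$maintenance$n_nonsignificant_days >= 4)
})

test_that("switching the BH scope changes adjusted values (regression)", {
  # adjusting per-day differs from adjusting across the pooled family
  set.seed(5)
  res <- tibble::tibble(
    asv_id = rep(c("a", "b", "c"), times = 2),
    day = rep(1:2, each = 3),
    p_value = c(0.01, 0.04, 0.9, 0.02, 0.5, 0.03)
  )
  per_day <- res |>
    dplyr::group_by(day) |>
    dplyr::mutate(p_adjusted = bh_adjust(p_value)) |>
    dplyr::ungroup()
  pooled <- dplyr::mutate(res, p_adjusted = bh_adjust(p_value))
  expect_false(isTRUE(all.equal(per_day$p_adjusted, pooled$p_adjusted)))
})
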