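test_that("a single detection anywhere makes a colonizer", {
  tensor <- array(FALSE, c(3, 7, 2))
  tensor[2, 5, 1] <- TRUE  # one mouse, one day, ASV 1 only
  st <- study_from_tensor(tensor)
  core <- identify_core_asvs(st$table, st$metadata, "D")
  calls <- classify_colonizers(st$table, st$metadata, "D", "mouse", core)
  expect_equal(calls$status[calls$asv_id == "t01"], "colonizer")
  expect_equal(calls$status[calls$asv_id == "t02"], "non_colonizer")
})

test_that("detection only in the inoculum is not colonization", {
  toy <- toy_study()
  core <- identify_core_asvs(toy$table, toy$metadata, "D1", toy$design)
  calls <- classify_colonizers(toy$table, toy$metadata, "D1", "mouse",
                               core, toy$design)
  # asvC present in aliquots but never in a mouse
  expect_equal(calls$status[calls$asv_id == "asvC"], "non_colonizer")
  expect_error(
    classify_colonizers(toy$table, toy$metadata, "D1", "gerbil", core),
    "no fecal samples"
  )
})

test_that("the majority rule is strict and counts qualifying days", {
  # 2 of 3 animals detected on exactly 4 days -> persistent
  tensor <- array(FALSE, c(3, 7, 1))
  tensor[1:2, 1:4, 1] <- TRUE
  st <- study_from_tensor(tensor)
  core <- identify_core_asvs(st$table, st$metadata, "D")
  calls <- classify_persistent(st$table, st$metadata, "D", "mouse", core)
  row <- calls[calls$asv_id == "t01", ]
  expect_equal(row$status, "persistent_colonizer")
  expect_equal(row$n_majority_timepoints, 4)

  # exactly half of 10 animals on all 7 days -> NOT persistent (strict >)
  tensor2 <- array(FALSE, c(10, 7, 1))
  tensor2[1:5, , 1] <- TRUE
  st2 <- study_from_tensor(tensor2)
  core2 <- identify_core_asvs(st2$table, st2$metadata, "D")
  calls2 <- classify_persistent(st2$table, st2$metadata, "D", "mouse",
                                core2)
  row2 <- calls2[calls2$asv_id == "t01", ]
  expect_equal(row2$status, "colonizer")
  expect_equal(row2$n_majority_timepoints, 0)
  expect_equal(unname(row2$day_fraction[[1]]), rep(0.5, 7))

  # 2 of 3 qualifies on only 3 days -> colonizer, not persistent
  tensor3 <- array(FALSE, c(3, 7, 1))
  tensor3[1:2, 1:3, 1] <- TRUE
  st3 <- study_from_tensor(tensor3)
  calls3 <- classify_persistent(st3$table, st3$metadata, "D", "mouse",
                                identify_core_asvs(st3$table, st3$metadata,
                                                   "D"))
  expect_equal(calls3$status[calls3$asv_id == "t01"], "colonizer")
})

test_that("classifier agrees with the brute-force rule on random tensors", {
  set.seed(402)
  for (rep in 1:40) {
    n_animals <- sample(1:4, 1)
    n_asv <- sample(1:6, 1)
    tensor <- array(runif(n_animals * 7 * n_asv) < runif(1, 0.2, 0.8),
                    c(n_animals, 7, n_asv))
    st <- study_from_tensor(tensor)
    core <- identify_core_asvs(st$table, st$metadata, "D")
    calls <- classify_persistent(st$table, st$metadata, "D", "mouse", core)
    for (k in seq_len(n_asv)) {
      oracle <- brute_force_persistence(tensor[, , k, drop = FALSE][, , 1,
                                                                    drop = TRUE] |>
                                          matrix(n_animals, 7))
      row <- calls[calls$asv_id == sprintf("t%02d", k), ]
      expect_equal(row$n_majority_timepoints, oracle$n_majority)
      expect_equal(row$status == "persistent_colonizer", oracle$persistent)
      expect_equal(row$status != "non_colonizer", oracle$colonizer)
    }
  }
})

test_that("missing animals shrink the day denominator", {
  # 3 animals enrolled; animal 3 has no samples after day 14. The ASV is
  # detected in 2 animals throughout: days with 3 sampled animals give 2/3,
  # later days give 2/2.
  tensor <- array(FALSE, c(3, 7, 1))
  tensor[1:2, , 1] <- TRUE
  st <- study_from_tensor(tensor)
  dropped <- dplyr::filter(
    st$metadata,
    is.na(subject_id) | subject_id != "an03" | day_post_inoculation <= 14
  )
  ft <- dplyr::semi_join(st$table,
                         dplyr::bind_rows(dropped),
                         by = "sample_id")
  core <- identify_core_asvs(ft, dropped, "D")
  calls <- classify_persistent(ft, dropped, "D", "mouse", core)
  fr <- calls$day_fraction[calls$asv_id == "t01"][[1]]
  expect_equal(unname(fr), c(2 / 3, 2 / 3, 2 / 3, 1, 1, 1, 1))
  expect_equal(calls$status[calls$asv_id == "t01"],
               "persistent_colonizer")
})

test_that("ladder monotonicity holds on simulated studies", {
  sim <- simulate_study(small_sim_config(seed = 21))
  ft <- filter_samples_by_depth(sim$table, 10500)
  for (d in c("D1", "D2")) {
    core <- identify_core_asvs(ft, sim$metadata, d)
    for (h in c("mouse", "piglet")) {
      calls <- classify_persistent(ft, sim$metadata, d, h, core)
      expect_true(all(calls$asv_id %in% core$asv_id))
      persistent <- calls$status == "persistent_colonizer"
      expect_true(all(calls$n_fecal_detected[persistent] > 0))
      expect_true(all(calls$n_majority_timepoints[persistent] >= 4))
      # non-colonizers can never hold a majority day
      expect_true(all(calls$n_majority_timepoints[
        calls$status == "non_colonizer"] == 0))
    }
  }
})

test_that("summary percentages follow half-away-from-zero at 1 decimal", {
  mk_calls <- function(n_core, n_col, n_per) {
    tibble::tibble(
      donor_id = "D", host = "mouse",
      asv_id = sprintf("a%03d", seq_len(n_core)),
      status = c(rep("persistent_colonizer", n_per),
                 rep("colonizer", n_col - n_per),
                 rep("non_colonizer", n_core - n_col))
    )
  }
  s <- summarize_engraftment(mk_calls(26, 21, 16))
  expect_equal(s$pct_colonizers, 80.8)
  expect_equal(s$pct_persistent, 61.5)
  s2 <- summarize_engraftment(mk_calls(76, 65, 43))
  expect_equal(s2$pct_colonizers, 85.5)
  expect_equal(s2$pct_persistent, 56.6)
  s3 <- summarize_engraftment(mk_calls(10, 0, 0))
  expect_equal(s3$pct_colonizers, 0)
})

test_that("cross-model contingency partitions the core", {
  mk <- function(col) tibble::tibble(
    donor_id = "D", host = if (identical(col, col_a)) "mouse" else "piglet",
    asv_id = names(col),
    status = ifelse(col, "colonizer", "non_colonizer")
  )
  asvs <- sprintf("a%02d", 1:20)
  col_a <- setNames(c(rep(TRUE, 8), rep(FALSE, 12)), asvs)
  col_b <- setNames(c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 6),
                      rep(FALSE, 4)), asvs)
  ct <- cross_model_contingency(mk(col_a), mk(col_b))
  expect_equal(ct$both_hosts, sum(col_a & col_b))
  expect_equal(ct$host_a_only, sum(col_a & !col_b))
  expect_equal(ct$host_b_only, sum(!col_a & col_b))
  expect_equal(ct$neither, sum(!col_a & !col_b))
  expect_equal(ct$both_hosts + ct$host_a_only + ct$host_b_only +
                 ct$neither, 20)

  # identical calls concentrate on the diagonal
  ct2 <- cross_model_contingency(mk(col_a), mk(col_a) |>
                                   dplyr::mutate(host = "piglet"))
  expect_equal(ct2$host_a_only + ct2$host_b_only, 0)

  # mismatched cores error
  expect_error(
    cross_model_contingency(mk(col_a), mk(col_b)[1:10, ]),
    "different core sets"
  )
})

test_that("taxon rollups partition the summary and merge additively", {
  sim <- simulate_study(small_sim_config(seed = 8))
  ft <- filter_samples_by_depth(sim$table, 10500)
  core <- identify_core_asvs(ft, sim$metadata, "D2")
  calls <- classify_persistent(ft, sim$metadata, "D2", "mouse", core)
  roll <- rollup_by_taxon(calls, sim$taxonomy, "phylum")
  s <- summarize_engraftment(calls)
  expect_equal(sum(roll$n_core), s$n_core)
  expect_equal(sum(roll$n_colonizers), s$n_colonizers)
  expect_equal(sum(roll$n_persistent), s$n_persistent)

  # merging two phyla adds their counts
  merged_tax <- sim$taxonomy |>
    dplyr::mutate(phylum = ifelse(phylum %in% c("Firmicutes",
                                                "Bacteroidetes"),
                                  "Merged", phylum))
  roll2 <- rollup_by_taxon(calls, merged_tax, "phylum")
  expect_equal(
    roll2$n_colonizers[roll2$taxon == "Merged"],
    sum(roll$n_colonizers[roll$taxon %in% c("Firmicutes",
                                            "Bacteroidetes")])
  )
  expect_error(rollup_by_taxon(calls, sim$taxonomy, "tribe"),
               "unknown rank")
})

test_that("union rollup deduplicates ASVs across donors", {
  tax <- tibble::tibble(
    asv_id = c("a1", "a2", "a3"), domain = "Bacteria",
    phylum = "Firmicutes", class = NA, order = NA, family = NA,
    genus = NA, species = NA
  )
  calls <- dplyr::bind_rows(
    tibble::tibble(donor_id = "D1", host = "mouse",
                   asv_id = c("a1", "a2"),
                   status = c("colonizer", "non_colonizer")),
    tibble::tibble(donor_id = "D2", host = "mouse",
                   asv_id = c("a1", "a3"),
                   status = c("non_colonizer", "persistent_colonizer"))
  )
  u <- union_rollup(calls, tax, "phylum")
  expect_equal(u$n_core, 3)          # a1 counted once
  expect_equal(u$n_colonizers, 2)    # a1 (via D1) and a3
  expect_equal(u$n_persistent, 1)

  # disjoint cores reduce to per-donor sums
  calls_disjoint <- dplyr::filter(calls, !(donor_id == "D2" &
                                             asv_id == "a1"))
  u2 <- union_rollup(calls_disjoint, tax, "phylum")
  per_donor <- calls_disjoint |>
    dplyr::group_by(donor_id) |>
    dplyr::summarise(n = dplyr::n())
  expect_equal(u2$n_core, sum(per_donor$n))

  # brute-force oracle on random overlapping cores
  set.seed(99)
  for (rep in 1:10) {
    pool <- sprintf("x%02d", 1:15)
    calls_r <- purrr::map_dfr(c("D1", "D2", "D3"), function(d) {
      ids <- sample(pool, sample(5:12, 1))
      tibble::tibble(donor_id = d, host = "mouse", asv_id = ids,
                     status = sample(c("non_colonizer", "colonizer",
                                       "persistent_colonizer"),
                                     length(ids), replace = TRUE))
    })
    tax_r <- tibble::tibble(asv_id = pool, domain = "Bacteria",
                            phylum = "P", class = NA, order = NA,
                            family = NA, genus = NA, species = NA)
    u_r <- union_rollup(calls_r, tax_r, "phylum")
    expect_equal(u_r$n_core, dplyr::n_distinct(calls_r$asv_id))
    oracle_col <- calls_r |>
      dplyr::filter(status != "non_colonizer") |>
      dplyr::pull(asv_id) |>
      dplyr::n_distinct()
    expect_equal(u_r$n_colonizers, oracle_col)
  }
})
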