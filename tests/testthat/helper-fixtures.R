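# Small deterministic fixtures built in code.

# A hand-written toy study: 1 donor, 2 hosts, 2-3 animals, a 3-day schedule.
# Counts are chosen so core membership and the ladder are easy to verify by
# eye.
toy_design <- function() {
  study_design(schedule = c(2L, 7L, 14L), min_sample_depth = 0,
               persistence_min_timepoints = 2)
}

toy_study <- function() {
  asvs <- c("asvA", "asvB", "asvC", "asvD")
  samples <- c("inoc1", "inoc2",
               "m1_d2", "m1_d7", "m1_d14",
               "m2_d2", "m2_d7", "m2_d14",
               "p1_d2", "p1_d7", "p1_d14")
  counts <- rbind(
    # inoculum: A, B, C in both aliquots; D only in aliquot 1 (not core)
    inoc1 = c(50, 30, 15, 5),
    inoc2 = c(55, 25, 20, 0),
    # mouse 1: A always; B on days 2,7; C never
    m1_d2 = c(40, 10, 0, 0),
    m1_d7 = c(45, 5, 0, 0),
    m1_d14 = c(50, 0, 0, 0),
    # mouse 2: A always; B day 2 only
    m2_d2 = c(60, 8, 0, 0),
    m2_d7 = c(70, 0, 0, 0),
    m2_d14 = c(65, 0, 0, 0),
    # piglet 1: A and C always
    p1_d2 = c(30, 0, 20, 0),
    p1_d7 = c(35, 0, 25, 0),
    p1_d14 = c(28, 0, 22, 0)
  )
  colnames(counts) <- asvs
  storage.mode(counts) <- "integer"
  ft <- feature_table(counts)
  metadata <- tibble::tibble(
    sample_id = samples,
    donor_id = "D1",
    host = c("human_donor", "human_donor",
             rep("mouse", 6), rep("piglet", 3)),
    sample_type = c("inoculum", "inoculum", rep("fecal", 9)),
    subject_id = c(NA, NA, rep("m1", 3), rep("m2", 3), rep("p1", 3)),
    day_post_inoculation = c(NA, NA, rep(c(2L, 7L, 14L), 3))
  )
  list(table = ft, metadata = metadata, design = toy_design())
}

# Small simulated study configuration used across tests (fast: shallow
# depths, few animals).
small_sim_config <- function(seed = 11, ...) {
  sim_config(
    donors = tibble::tibble(donor_id = c("D1", "D2"),
                            n_asvs = c(30L, 50L),
                            n_aliquots = c(3L, 4L)),
    hosts = list(
      host_spec("mouse", 5,
                c(Firmicutes = 0.4, Bacteroidetes = 0.9,
                  Actinobacteriota = 0.6, Proteobacteria = 0.5,
                  Desulfobacterota = 0.5),
                fecal_depth = 12000),
      host_spec("piglet", 3,
                c(Firmicutes = 0.8, Bacteroidetes = 0.9,
                  Actinobacteriota = 0.7, Proteobacteria = 0.6,
                  Desulfobacterota = 0.6),
                fecal_depth = 12000)
    ),
    aliquot_depth = 15000, seed = seed, ...
  )
}

# Independent brute-force evaluation of the persistence rule on a logical
# presence array (animals x days), used as the oracle for the classifier.
brute_force_persistence <- function(presence, min_days = 4, frac = 0.5,
                                    sampled = NULL) {
  n_days <- ncol(presence)
  qualifying <- 0
  for (d in seq_len(n_days)) {
    col <- presence[, d]
    if (!is.null(sampled)) col <- col[sampled[, d]]
    if (length(col) == 0) next
    if (mean(col) > frac) qualifying <- qualifying + 1
  }
  list(n_majority = qualifying, persistent = qualifying >= min_days,
       colonizer = {
         any(if (is.null(sampled)) presence else presence & sampled)
       })
}

# Brute-force BH step-up, written independently of stats::p.adjust.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    val <- min(p[o[i]] * m / i, prev, 1)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Brute-force median-of-ratios size factors by direct enumeration.
brute_force_size_factors <- function(m) {
  all_pos <- apply(m, 2, function(col) all(col > 0))
  ref <- apply(m[, all_pos, drop = FALSE], 2,
               function(col) exp(mean(log(col))))
  apply(m[, all_pos, drop = FALSE], 1,
        function(row) median(row / ref))
}

# Build a study from an explicit presence tensor: one donor, one host,
# animals x days x ASVs logical array. Counts are 0/1; aliquots detect all
# ASVs so every ASV is core.
study_from_tensor <- function(tensor, schedule = c(2, 7, 14, 21, 28, 35,
                                                   40)) {
  n_animals <- dim(tensor)[1]
  n_days <- dim(tensor)[2]
  n_asv <- dim(tensor)[3]
  asvs <- sprintf("t%02d", seq_len(n_asv))
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (d in seq_len(n_days)) {
      sid <- sprintf("an%02d_d%02d", a, schedule[d])
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sid, asv_id = c(asvs, "filler"),
        count = c(as.integer(tensor[a, d, ]), 1L)
      )
    }
  }
  inoc <- tibble::tibble(
    sample_id = rep(c("i1", "i2"), each = n_asv + 1),
    asv_id = rep(c(asvs, "filler"), 2), count = 5L
  )
  ft <- validate_feature_table(dplyr::bind_rows(c(rows, list(inoc))))
  meta <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("i1", "i2"), donor_id = "D",
                   host = "human_donor", sample_type = "inoculum",
                   subject_id = NA_character_,
                   day_post_inoculation = NA_integer_),
    tidyr::expand_grid(a = seq_len(n_animals), d = seq_len(n_days)) |>
      dplyr::mutate(
        sample_id = sprintf("an%02d_d%02d", a, schedule[d]),
        donor_id = "D", host = "mouse", sample_type = "fecal",
        subject_id = sprintf("an%02d", a),
        day_post_inoculation = as.integer(schedule[d])
      ) |>
      dplyr::select(-a, -d)
  )
  list(table = ft, metadata = meta, asvs = asvs)
}
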