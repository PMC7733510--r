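#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log p_i} over the non-zero proportions of a count (or
#' abundance) vector. Natural log by default, matching the convention of the
#' usual community-ecology toolchain; the base is configurable.
#'
#' @param x Non-negative numeric vector with positive total.
#' @param base Logarithm base (default `exp(1)`).
#' @return The index value (scalar).
#' @examples
#' shannon_index(rep(1, 4))   # log(4)
#' @export
shannon_index <- function(x, base = exp(1)) {
  stopifnot(all(x >= 0))
  if (sum(x) <= 0) stop("total count must be positive", call. = FALSE)
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Per-sample alpha diversity
#'
#' Computes the Shannon index for every sample of a feature table. All ASVs
#' (not only core ASVs) should be present in the table, since the index is
#' sensitive to rare taxa.
#'
#' @param ft A feature table (positive-depth samples).
#' @param base Logarithm base.
#' @return A tibble with columns `sample_id`, `shannon`.
#' @export
alpha_diversity <- function(ft, base = exp(1)) {
  m <- ft_matrix(validate_feature_table(ft))
  if (any(rowSums(m) <= 0)) {
    stop("zero-depth sample(s); filter before computing diversity",
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = rownames(m),
    shannon = as.numeric(vegan::diversity(m, index = "shannon",
                                          base = base))
  )
}

#' Bray-Curtis dissimilarity between two vectors
#'
#' \eqn{d = 1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)}. By default the
#' inputs are first converted to relative abundances so sequencing depth
#' cancels; set `relative = FALSE` to compare raw counts.
#'
#' @param x,y Non-negative numeric vectors of equal length with positive
#'   totals.
#' @param relative Normalise to proportions first (default TRUE).
#' @return A dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y, relative = TRUE) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  stopifnot(all(x >= 0), all(y >= 0), sum(x) > 0, sum(y) > 0)
  if (relative) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Unweighted UniFrac distance between two communities
#'
#' Presence-based phylogenetic dissimilarity: the fraction of total branch
#' length (over branches leading to any tip present in either community)
#' that leads exclusively to tips of one community. Computed by classifying
#' every branch of the rooted tree by the communities found among the tips
#' it subtends.
#'
#' @param presence_x,presence_y Character vectors of present tip labels
#'   (non-empty).
#' @param tree A rooted [ape::phylo] tree with branch lengths whose tips
#'   cover the presence sets.
#' @param drop_missing Drop presence labels absent from the tree (with a
#'   warning) instead of erroring.
#' @return A distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(presence_x, presence_y, tree,
                               drop_missing = FALSE) {
  tree <- validate_asv_tree(tree)
  presence_x <- resolve_tips(presence_x, tree, drop_missing)
  presence_y <- resolve_tips(presence_y, tree, drop_missing)
  pm <- matrix(FALSE, 2, length(tree$tip.label),
               dimnames = list(c("x", "y"), tree$tip.label))
  pm["x", presence_x] <- TRUE
  pm["y", presence_y] <- TRUE
  d <- unifrac_from_presence(pm, tree)
  d["x", "y"]
}

resolve_tips <- function(labels, tree, drop_missing) {
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing) > 0) {
    if (!drop_missing) {
      stop("tips absent from the tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping ", length(missing), " label(s) absent from the tree")
    labels <- setdiff(labels, missing)
  }
  if (length(labels) == 0) {
    stop("community has no tips on the tree", call. = FALSE)
  }
  labels
}

# Branch-incidence unweighted UniFrac for a logical presence matrix
# (communities x tips). For each edge, the set of tips below it is computed
# once; an edge "belongs" to a community when any subtended tip is present.
unifrac_from_presence <- function(pm, tree) {
  inc <- edge_tip_incidence(tree)      # edges x tips, logical
  below <- pm %*% t(inc) > 0           # communities x edges
  n <- nrow(pm)
  len <- tree$edge.length
  out <- matrix(0, n, n, dimnames = list(rownames(pm), rownames(pm)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      either <- below[i, ] | below[j, ]
      shared <- below[i, ] & below[j, ]
      tot <- sum(len[either])
      out[i, j] <- out[j, i] <-
        if (tot == 0) 0 else sum(len[either & !shared]) / tot
    }
  }
  out
}

edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  # tips subtended by each node, by postorder accumulation
  below <- matrix(FALSE, n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    below[edges[k, 1], ] <- below[edges[k, 1], ] | below[edges[k, 2], ]
  }
  inc <- below[tree$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

#' All pairwise community distances
#'
#' @param ft A feature table (for `bray_curtis`) whose positive-depth
#'   samples are compared, or any table for `unweighted_unifrac` (presence
#'   is taken at the design detection threshold of 1 read).
#' @param metric `"bray_curtis"` or `"unweighted_unifrac"`.
#' @param tree Rooted phylogeny, required for UniFrac.
#' @param relative For Bray-Curtis, compare relative abundances (default
#'   TRUE).
#' @param drop_missing For UniFrac, drop table ASVs absent from the tree.
#' @return A symmetric [stats::dist] object labelled by sample.
#' @export
pairwise_distances <- function(ft, metric = c("bray_curtis",
                                              "unweighted_unifrac"),
                               tree = NULL, relative = TRUE,
                               drop_missing = FALSE) {
  metric <- match.arg(metric)
  m <- ft_matrix(validate_feature_table(ft))
  if (metric == "bray_curtis") {
    if (any(rowSums(m) <= 0)) {
      stop("zero-depth sample(s); filter before Bray-Curtis", call. = FALSE)
    }
    if (relative) m <- m / rowSums(m)
    return(vegan::vegdist(m, method = "bray"))
  }
  if (is.null(tree)) stop("UniFrac requires a tree", call. = FALSE)
  tree <- validate_asv_tree(tree)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing) > 0) {
    if (!drop_missing) {
      stop("table ASVs absent from the tree: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...", call. = FALSE)
    }
    warning("dropping ", length(missing), " ASV(s) absent from the tree")
    m <- m[, setdiff(colnames(m), missing), drop = FALSE]
  }
  pm <- m > 0
  if (any(rowSums(pm) == 0)) {
    stop("sample(s) with no present ASVs on the tree", call. = FALSE)
  }
  sub <- ape::keep.tip(tree, colnames(m))
  full <- matrix(FALSE, nrow(pm), length(sub$tip.label),
                 dimnames = list(rownames(pm), sub$tip.label))
  full[, colnames(pm)[colnames(pm) %in% sub$tip.label]] <-
    pm[, colnames(pm) %in% sub$tip.label]
  stats::as.dist(unifrac_from_presence(full, sub))
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centres \eqn{-D^2/2}, eigendecomposes, and embeds the samples on
#' the leading positive eigenvectors scaled by the square roots of their
#' eigenvalues. Negative eigenvalues (arising from non-Euclidean
#' dissimilarities such as Bray-Curtis) are dropped and counted, never
#' corrected; explained proportions are relative to the positive-eigenvalue
#' total.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @param n_axes Number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return An object of class `engraft_pcoa`: list with `coordinates` (a
#'   tibble: `sample_id`, `axis_1`, ...), `explained` (proportion per
#'   returned axis), `eigenvalues` (all), and `n_negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d, n_axes = 2) {
  stopifnot(n_axes >= 1)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  labels <- rownames(dm) %||% paste0("sample_", seq_len(n))
  # cmdscale warns when fewer than k eigenvalues are positive; the axis
  # count is handled explicitly below
  fit <- suppressWarnings(cmdscale(stats::as.dist(dm), k = n - 1,
                                   eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-10]
  k <- min(n_axes, length(pos))
  if (k < 1) stop("no positive eigenvalues; distances are degenerate",
                  call. = FALSE)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis_", seq_len(k))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble::tibble(sample_id = labels),
                                     tibble::as_tibble(coords)),
      explained = pos[seq_len(k)] / sum(pos),
      eigenvalues = eig,
      n_negative_eigenvalues = sum(eig < -1e-10)
    ),
    class = "engraft_pcoa"
  )
}

#' @export
print.engraft_pcoa <- function(x, ...) {
  cat("PCoA of", nrow(x$coordinates), "samples;",
      length(x$explained), "axes kept (",
      paste0(round(100 * x$explained, 1), "%", collapse = ", "),
      ");", x$n_negative_eigenvalues, "negative eigenvalue(s) dropped\n")
  invisible(x)
}

#' Distance from each animal sample to its donor's inoculum
#'
#' For every fecal sample, the mean of its distances to each surviving
#' inoculum aliquot of its own donor -- a per-sample measure of how
#' donor-like the established community is, comparable across hosts and
#' days.
#'
#' @param ft A feature table holding both fecal and inoculum samples.
#' @param metadata Sample metadata.
#' @param metric,tree,relative,drop_missing Passed to
#'   [pairwise_distances()].
#' @return A tibble with columns `sample_id`, `donor_id`, `host`,
#'   `subject_id`, `day_post_inoculation`, `distance_to_donor`.
#' @export
distance_to_donor <- function(ft, metadata,
                              metric = c("bray_curtis",
                                         "unweighted_unifrac"),
                              tree = NULL, relative = TRUE,
                              drop_missing = FALSE) {
  metric <- match.arg(metric)
  metadata <- validate_sample_metadata(metadata)
  dm <- as.matrix(pairwise_distances(ft, metric, tree = tree,
                                     relative = relative,
                                     drop_missing = drop_missing))
  fecal <- dplyr::filter(metadata, .data$sample_type == "fecal",
                         .data$sample_id %in% rownames(dm))
  inoc <- dplyr::filter(metadata, .data$sample_type == "inoculum",
                        .data$sample_id %in% rownames(dm))
  purrr::map_dfr(seq_len(nrow(fecal)), function(i) {
    row <- fecal[i, ]
    aliquots <- inoc$sample_id[inoc$donor_id == row$donor_id]
    if (length(aliquots) == 0) {
      stop("donor '", row$donor_id, "' has no inoculum aliquots in the ",
           "distance matrix", call. = FALSE)
    }
    tibble::tibble(
      sample_id = row$sample_id, donor_id = row$donor_id, host = row$host,
      subject_id = row$subject_id,
      day_post_inoculation = row$day_post_inoculation,
      distance_to_donor = mean(dm[row$sample_id, aliquots])
    )
  })
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wrapper over [stats::wilcox.test()] used for all group comparisons of
#' diversity values and donor distances: exact enumeration when the combined
#' sample size is at most 10 and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param a,b Numeric vectors; both non-empty and not both of size 1.
#' @return A one-row tibble: `statistic` (rank-sum W), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(a) == 1 && length(b) == 1) {
    stop("cannot test two single observations", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 10) && !ties
  fit <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(fit$statistic),
    p_value = min(fit$p.value, 1),
    method = if (exact) "exact" else "normal_approximation"
  )
}
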