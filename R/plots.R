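#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PCoA ordination
#'
#' @param x An `engraft_pcoa` object.
#' @param ... Unused.
#' @return The coordinate tibble, one row per sample.
#' @method tidy engraft_pcoa
#' @export
tidy.engraft_pcoa <- function(x, ...) {
  x$coordinates
}

#' @rdname tidy.engraft_pcoa
#' @return For `glance()`: a one-row tibble with `n_samples`, `n_axes`,
#'   `prop_explained` (cumulative over returned axes) and
#'   `n_negative_eigenvalues`.
#' @method glance engraft_pcoa
#' @export
glance.engraft_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = length(x$explained),
    prop_explained = sum(x$explained),
    n_negative_eigenvalues = x$n_negative_eigenvalues
  )
}

#' Ordination scatter plot
#'
#' @param object An `engraft_pcoa` object.
#' @param metadata Optional sample metadata joined on `sample_id`; when
#'   given, points are coloured by `colour` and shaped by `shape`.
#' @param colour,shape Metadata column names (defaults `donor_id`, `host`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot engraft_pcoa
#' @export
autoplot.engraft_pcoa <- function(object, metadata = NULL,
                                  colour = "donor_id", shape = "host",
                                  ...) {
  df <- object$coordinates
  mapping <- ggplot2::aes(x = .data$axis_1, y = .data$axis_2)
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
    mapping <- ggplot2::aes(
      x = .data$axis_1, y = .data$axis_2,
      colour = .data[[colour]], shape = .data[[shape]]
    )
  }
  pct <- round(100 * object$explained[1:2], 1)
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = paste0("PCo1 (", pct[1], "%)"),
                  y = paste0("PCo2 (", pct[2], "%)")) +
    ggplot2::theme_bw()
}

#' Establishment summary bar plot
#'
#' Side-by-side colonizer and persistent-colonizer percentages per
#' donor-host group, mirroring the study's establishment table.
#'
#' @param summary Output of [summarize_engraftment()] (any number of rows).
#' @return A ggplot.
#' @export
plot_engraftment_summary <- function(summary) {
  long <- summary |>
    dplyr::select("donor_id", "host", "pct_colonizers",
                  "pct_persistent") |>
    tidyr::pivot_longer(c("pct_colonizers", "pct_persistent"),
                        names_to = "measure", values_to = "pct") |>
    dplyr::mutate(measure = dplyr::recode(
      .data$measure, pct_colonizers = "colonizers",
      pct_persistent = "persistent colonizers"
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$donor_id, y = .data$pct,
                                     fill = .data$host)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "% of core donor ASVs") +
    ggplot2::theme_bw()
}

#' Alpha-diversity box plot by group
#'
#' @param alpha Output of [alpha_diversity()] joined with metadata (needs
#'   `shannon` plus the grouping column).
#' @param group Grouping column name (default `donor_id`).
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(alpha, group = "donor_id") {
  ggplot2::ggplot(alpha, ggplot2::aes(x = .data[[group]],
                                      y = .data$shannon)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "Shannon index") +
    ggplot2::theme_bw()
}

#' Donor-distance trajectories
#'
#' Mean community distance to the donor inoculum over days post-inoculation,
#' one line per host, facetted by donor.
#'
#' @param donor_distance Output of [distance_to_donor()].
#' @return A ggplot.
#' @export
plot_donor_distance <- function(donor_distance) {
  ggplot2::ggplot(donor_distance,
                  ggplot2::aes(x = .data$day_post_inoculation,
                               y = .data$distance_to_donor,
                               colour = .data$host)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(~donor_id) +
    ggplot2::labs(x = "day post-inoculation",
                  y = "distance to donor inoculum") +
    ggplot2::theme_bw()
}
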