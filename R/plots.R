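# ggplot2 visual summaries for result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot an NMDS ordination
#'
#' @param object A `smdiv_nmds` object.
#' @param metadata Optional metadata joined on `sample` = `sample_id` to
#'   colour points by `site` and shape by `stage`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot smdiv_nmds
#' @export
autoplot.smdiv_nmds <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  if (!is.null(metadata)) {
    df <- left_join(df, metadata, by = c(sample = "sample_id"))
  }
  p <- ggplot(df, aes(x = .data$NMDS1, y = .data$NMDS2))
  p <- if (!is.null(metadata) && all(c("site", "stage") %in% names(df))) {
    p + geom_point(aes(colour = .data$site, shape = .data$stage), size = 3)
  } else {
    p + geom_point(size = 3)
  }
  p + labs(title = sprintf("NMDS (stress = %.3f)", object$stress)) +
    theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param curve Output of [rarefy_curve()], optionally with a `sample`
#'   column when curves from several samples are row-bound.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curve) {
  p <- ggplot(curve, aes(x = .data$depth, y = .data$mean_observed))
  if ("sample" %in% names(curve)) {
    p <- p + geom_line(aes(colour = .data$sample)) +
      geom_point(aes(colour = .data$sample))
  } else {
    p <- p + geom_line() + geom_point()
  }
  p + labs(x = "Sequencing depth", y = "Mean observed OTUs") + theme_minimal()
}

#' Shepard diagram of an NMDS fit
#'
#' @param object A `smdiv_nmds` object.
#' @param D The dissimilarities the ordination was fitted to.
#' @return A ggplot object.
#' @export
plot_shepard <- function(object, D) {
  D <- stats::as.dist(D)
  coords <- as.matrix(object$coordinates[, -1])
  df <- tibble(dissimilarity = as.vector(D),
               ordination_distance = as.vector(stats::dist(coords)))
  ggplot(df, aes(x = .data$dissimilarity, y = .data$ordination_distance)) +
    geom_point(alpha = 0.6) +
    labs(title = sprintf("Shepard diagram (r = %.3f)", object$shepard_r)) +
    theme_minimal()
}
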