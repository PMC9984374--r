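#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one or more grid spectra
#'
#' @param ... named grid spectrum tibbles (names become legend labels).
#' @param normalize scale each spectrum to unit maximum before plotting.
#' @return a ggplot object.
#' @export
plot_spectra <- function(..., normalize = TRUE) {
  specs <- list(...)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- paste0("spectrum_", seq_along(specs))
  }
  df <- purrr::imap_dfr(specs, function(s, nm) {
    i <- s$intensity
    if (normalize && max(i) > 0) i <- i / max(i)
    tibble::tibble(wavenumber = s$wavenumber, intensity = i, spectrum = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   colour = .data$spectrum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "intensity (arb.)") +
    ggplot2::theme_minimal()
}

#' Conformer map in the leading principal components
#'
#' @param report a `run_report` (or pass `projection` and `clusters`).
#' @return a ggplot object of the PCA plane colored by cluster.
#' @export
plot_cluster_map <- function(report) {
  df <- tibble::tibble(pc1 = report$pca$projected[, 1],
                       pc2 = report$pca$projected[, 2],
                       cluster = factor(report$clusters$labels))
  reps <- df[report$clusters$representative, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = reps, shape = 17, size = 3, colour = "black") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Free-energy surface / profile plot
#'
#' @param object a `prob_surface`.
#' @param ... unused.
#' @return a ggplot object: a line for 1D surfaces, a filled tile map for 2D.
#' @export
autoplot.prob_surface <- function(object, ...) {
  centers <- lapply(object$edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  if (object$ndim == 1) {
    df <- tibble::tibble(s = centers[[1]], F = object$F - min(object$F, na.rm = TRUE))
    ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$F)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::labs(x = "s", y = "F (kcal/mol)") +
      ggplot2::theme_minimal()
  } else {
    df <- expand.grid(s_A = centers[[1]], s_D = centers[[2]])
    df$F <- as.vector(object$F) - min(object$F, na.rm = TRUE)
    ggplot2::ggplot(df, ggplot2::aes(.data$s_A, .data$s_D, fill = .data$F)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(na.value = "white", name = "F (kcal/mol)") +
      ggplot2::theme_minimal()
  }
}

#' Dendrogram of a merge tree
#'
#' @param tree a `merge_tree`.
#' @return a ggplot object drawing the merge hierarchy.
#' @export
plot_merge_tree <- function(tree) {
  k <- tree$n_leaves
  xpos <- c(seq_len(k), rep(NA_real_, nrow(tree$merges)))
  h <- c(rep(0, k), rep(NA_real_, nrow(tree$merges)))
  # order leaves by recursive traversal for a planar drawing
  segs <- list()
  for (i in seq_len(nrow(tree$merges))) {
    a <- tree$merges$a[i]; b <- tree$merges$b[i]; id <- k + i
    xpos[id] <- (xpos[a] + xpos[b]) / 2
    h[id] <- tree$merges$height[i]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(xpos[a], xpos[a], xpos[b]),
      xend = c(xpos[a], xpos[b], xpos[b]),
      y = c(h[a], h[id], h[id]),
      yend = c(h[id], h[id], h[b]))
  }
  df <- dplyr::bind_rows(segs)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(k),
                                labels = as.character(seq_len(k))) +
    ggplot2::labs(x = "cluster", y = "Ward merge height") +
    ggplot2::theme_minimal()
}
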