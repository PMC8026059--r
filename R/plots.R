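# ggplot2 graphics for score maps, distograms and training curves.

.map_to_tibble <- function(M, value_name = "value") {
  df <- tibble::tibble(i = rep(seq_len(nrow(M)), times = ncol(M)),
                       j = rep(seq_len(ncol(M)), each = nrow(M)),
                       value = as.vector(M))
  names(df)[3L] <- value_name
  df
}

#' Plot a pair-score map
#'
#' @param object A `coev_pairscore`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coev_pairscore <- function(object, ...) {
  df <- .map_to_tibble(object$scores, "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s pair scores%s", toupper(object$method),
                      if (object$apc_applied) " (APC-corrected)" else ""),
      x = "position j", y = "position i", fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot the contact-probability map of a distogram prediction
#'
#' @param object A `coev_distogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coev_distogram <- function(object, ...) {
  plot_contact_map(contact_probability(object))
}

#' Predicted contact map, optionally overlaid with native contacts
#'
#' Native contacts (upper triangle) are drawn as open circles over the
#' predicted probability raster.
#'
#' @param P L x L contact-probability matrix.
#' @param native Optional L x L logical native contact map.
#' @return A ggplot object.
#' @export
plot_contact_map <- function(P, native = NULL) {
  df <- .map_to_tibble(P, "probability")
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$probability)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "midnightblue",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i",
                  fill = "P(contact)") +
    ggplot2::theme_minimal()
  if (!is.null(native)) {
    if (inherits(native, "coev_labels")) native <- native$contacts
    nd <- which(native & upper.tri(native), arr.ind = TRUE)
    g <- g + ggplot2::geom_point(
      data = tibble::tibble(i = nd[, 1L], j = nd[, 2L]),
      shape = 1, size = 1, colour = "red")
  }
  g
}

#' Plot the training history of a network fit
#'
#' @param object A `coev_fit`.
#' @param ... Unused.
#' @return A ggplot object (loss curve; validation precision as a second
#'   panel when logged).
#' @export
autoplot.coev_fit <- function(object, ...) {
  h <- object$history
  df <- tidyr_pivot(h)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

# reshape history without importing tidyr
tidyr_pivot <- function(h) {
  metrics <- setdiff(names(h), "epoch")
  dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(epoch = h$epoch, metric = m, value = h[[m]])
  }))
}
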