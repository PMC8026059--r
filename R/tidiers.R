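# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Potts model into per-pair coupling scores
#'
#' One row per unordered position pair (i < j) with the Frobenius norm of
#' the coupling block (gap state excluded) and its APC-corrected score.
#'
#' @param x A `coev_potts_fit` (or any `coev_potts`).
#' @param ... Unused.
#' @return Tibble: `i`, `j`, `separation`, `coupling_norm`, `apc_score`.
#' @export
tidy.coev_potts <- function(x, ...) {
  raw <- frobenius_score(x)
  apc <- apc_correct(raw)
  idx <- which(upper.tri(raw$scores), arr.ind = TRUE)
  tibble::tibble(
    i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]),
    separation = as.integer(idx[, 2L] - idx[, 1L]),
    coupling_norm = raw$scores[idx],
    apc_score = apc$scores[idx]
  ) |> dplyr::arrange(dplyr::desc(.data$apc_score))
}

#' One-row summary of a pseudolikelihood fit
#'
#' @param x A `coev_potts_fit`.
#' @param ... Unused.
#' @return Tibble: `L`, `nll`, `converged`, `iterations`, `lambda_h`,
#'   `lambda_J`.
#' @export
glance.coev_potts_fit <- function(x, ...) {
  tibble::tibble(L = x$L, nll = x$nll, converged = x$converged,
                 iterations = x$iterations, lambda_h = x$lambda_h,
                 lambda_J = x$lambda_J)
}

#' Per-epoch training history of a network fit
#'
#' @param x A `coev_fit` from [train_model()].
#' @param ... Unused.
#' @return The history tibble (epoch, loss, optional validation precision).
#' @export
tidy.coev_fit <- function(x, ...) x$history

#' One-row summary of a network fit
#'
#' @param x A `coev_fit`.
#' @param ... Unused.
#' @return Tibble: `loss_type`, `epochs`, `final_loss`, `n_parameters`,
#'   `features`, `seed`.
#' @export
glance.coev_fit <- function(x, ...) {
  tibble::tibble(
    loss_type = x$loss,
    epochs = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1),
    n_parameters = n_parameters(x$model),
    features = paste(x$model$cfg$features, collapse = "+"),
    seed = x$seed
  )
}
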