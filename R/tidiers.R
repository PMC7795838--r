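# broom-style tidiers for fitted objects.

#' Tidy an admixture fit into long format
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble `individual`, `population`, `cluster`, `proportion`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$q), times = ncol(x$q)),
    population = rep(x$populations, times = ncol(x$q)),
    cluster = rep(colnames(x$q), each = nrow(x$q)),
    proportion = as.vector(x$q)
  )
}

#' One-row summary of an admixture fit
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble with `k`, `ln_prob_data`, `mean_max_q` (mean dominant
#'   assignment), `alpha_mean` (posterior mean of the concentration),
#'   `n_individuals`, `sweeps`.
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    ln_prob_data = x$ln_prob_data,
    mean_max_q = mean(apply(x$q, 1, max)),
    alpha_mean = if (length(x$alpha_trace)) mean(x$alpha_trace) else NA_real_,
    n_individuals = nrow(x$q),
    sweeps = x$burn_in + x$reps
  )
}

#' Tidy a lip annotation into a vertex table
#'
#' @param x A `lip_annotation`.
#' @param ... Unused.
#' @return Long tibble of lip and left-wing vertices (see
#'   [contour_table()]).
#' @export
tidy.lip_annotation <- function(x, ...) {
  contour_table(list(shape_1 = x))
}
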