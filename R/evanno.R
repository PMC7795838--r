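# Evanno delta-K model choice across an admixture K scan.

#' Evanno delta-K table and optimal K
#'
#' From per-run ln P(D) values across a K grid: per K the mean and SD over
#' runs, the first-order difference `L'(K) = mean(K) - mean(K-1)`, the
#' second-order curvature `L''(K) = |L'(K+1) - L'(K)|`, and
#' `delta K = L''(K) / sd(K)`. Delta K is defined only for interior K with
#' positive SD; the optimal K is the interior K maximizing delta K, ties
#' broken toward smaller K. When every defined delta K is zero (no
#' curvature) the choice is inconclusive and `optimal_k` is `NA`.
#'
#' @param x An `admixture_scan`, its `table`, or any data frame with
#'   columns `k` and `ln_prob_data` (one row per run).
#' @return An `evanno_table` tibble: `k`, `n_runs`, `mean_lnp`, `sd_lnp`,
#'   `l_prime`, `l_double_prime`, `delta_k`; attribute `optimal_k`.
#' @export
#' @examples
#' runs <- expand.grid(k = 1:4, run = 1:3)
#' runs$ln_prob_data <- c(-5000, -3000, -2950, -2940)[runs$k] +
#'   rep(c(-10, 0, 10), each = 4)
#' ev <- evanno_delta_k(runs)
#' optimal_k(ev)
evanno_delta_k <- function(x) {
  if (inherits(x, "admixture_scan")) x <- x$table
  if (!is.data.frame(x) || !all(c("k", "ln_prob_data") %in% names(x))) {
    abort("Need a data frame with columns `k` and `ln_prob_data`.")
  }
  agg <- x |>
    dplyr::group_by(k = .data$k) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_lnp = mean(.data$ln_prob_data),
      sd_lnp = if (dplyr::n() > 1L) stats::sd(.data$ln_prob_data) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$k)
  if (nrow(agg) < 3L) {
    abort("Evanno's delta K needs at least 3 K values.")
  }
  if (any(agg$n_runs < 2L)) {
    abort("Evanno's delta K needs at least 2 runs per K.")
  }
  K <- nrow(agg)
  l_prime <- c(NA_real_, diff(agg$mean_lnp))
  l_dprime <- rep(NA_real_, K)
  l_dprime[2:(K - 1)] <- abs(l_prime[3:K] - l_prime[2:(K - 1)])
  delta_k <- ifelse(
    !is.na(l_dprime) & agg$sd_lnp > 0,
    l_dprime / agg$sd_lnp,
    NA_real_
  )
  out <- dplyr::mutate(agg, l_prime = l_prime, l_double_prime = l_dprime,
                       delta_k = delta_k)
  defined <- which(!is.na(delta_k))
  optimal <- if (length(defined) == 0L || max(delta_k[defined]) <= 0) {
    NA_integer_
  } else {
    as.integer(out$k[defined[which.max(delta_k[defined])]])
  }
  class(out) <- c("evanno_table", class(out))
  attr(out, "optimal_k") <- optimal
  out
}

#' @describeIn evanno_delta_k Extract the optimal K (`NA` when
#'   inconclusive).
#' @param evanno An `evanno_table`.
#' @export
optimal_k <- function(evanno) {
  stopifnot(inherits(evanno, "evanno_table"))
  attr(evanno, "optimal_k")
}

#' Glance at an Evanno table
#'
#' @param x An `evanno_table`.
#' @param ... Unused.
#' @return One-row tibble: `optimal_k`, `max_delta_k`, `k_min`, `k_max`.
#' @export
glance.evanno_table <- function(x, ...) {
  tibble::tibble(
    optimal_k = attr(x, "optimal_k"),
    max_delta_k = if (all(is.na(x$delta_k))) NA_real_
                  else max(x$delta_k, na.rm = TRUE),
    k_min = min(x$k),
    k_max = max(x$k)
  )
}

#' @export
print.evanno_table <- function(x, ...) {
  NextMethod()
  ok <- attr(x, "optimal_k")
  cat(if (is.na(ok)) "Optimal K: inconclusive (no curvature)\n"
      else sprintf("Optimal K: %d\n", ok))
  invisible(x)
}
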