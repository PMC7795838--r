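# Cross-run label alignment (the label-switching problem) and the
# stacked-bar membership table.

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

extract_q <- function(x) {
  if (inherits(x, "admixture_fit")) x$q else as.matrix(x)
}

#' Align admixture runs across label switching
#'
#' Cluster labels are arbitrary per run; alignment permutes each run's
#' columns to best agree with the first run. `"exhaustive"` (default)
#' searches all k! column permutations (k <= 8, at most 40,320) minimizing
#' the total absolute difference from the reference; `"greedy"` matches
#' columns one at a time by the same criterion. Deterministic.
#'
#' @param runs List of `admixture_fit` objects or q matrices sharing the
#'   same k and individuals.
#' @param method `"exhaustive"` or `"greedy"`.
#' @return List with `aligned` (list of permuted q matrices),
#'   `permutations` (list of integer vectors: new column j was the run's
#'   column `perm[j]`), and `mean_q` (element-wise mean of the aligned
#'   matrices).
#' @export
align_runs <- function(runs, method = c("exhaustive", "greedy")) {
  method <- match.arg(method)
  qs <- lapply(runs, extract_q)
  k <- ncol(qs[[1]])
  dims_ok <- vapply(qs, function(m) {
    nrow(m) == nrow(qs[[1]]) && ncol(m) == k
  }, logical(1))
  if (!all(dims_ok)) abort("All runs must share the same individuals and k.")
  ref <- qs[[1]]
  perms <- if (method == "exhaustive") all_permutations(k) else NULL
  align_one <- function(q) {
    if (k == 1L) return(list(q = q, perm = 1L))
    if (method == "exhaustive") {
      costs <- vapply(perms, function(p) sum(abs(q[, p] - ref)), numeric(1))
      best <- perms[[which.min(costs)]]
    } else {
      best <- integer(k)
      used <- logical(k)
      for (j in seq_len(k)) {
        cost <- vapply(seq_len(k), function(c) {
          if (used[c]) Inf else sum(abs(q[, c] - ref[, j]))
        }, numeric(1))
        best[j] <- which.min(cost)
        used[best[j]] <- TRUE
      }
    }
    qa <- q[, best, drop = FALSE]
    colnames(qa) <- colnames(ref)
    list(q = qa, perm = best)
  }
  aligned <- lapply(qs, align_one)
  mats <- lapply(aligned, `[[`, "q")
  list(
    aligned = mats,
    permutations = lapply(aligned, `[[`, "perm"),
    mean_q = Reduce(`+`, mats) / length(mats)
  )
}

#' Stacked-bar membership table
#'
#' Long-format, plotting-ready per-individual cluster memberships:
#' individuals are ordered by population and, within population, by their
#' dominant-cluster fraction (descending), the conventional ordering of
#' admixture bar plots with populations separated by vertical lines.
#'
#' @param q Individuals x k matrix of (aligned mean) admixture
#'   proportions with individual row names, or an `admixture_fit`.
#' @param populations Population label per individual (named vector or in
#'   the same order as `q` rows; defaults to the fit's populations).
#' @return Tibble `individual`, `population`, `cluster`, `proportion`,
#'   `order` (plotting position). Class `membership_table`.
#' @export
membership_table <- function(q, populations = NULL) {
  if (inherits(q, "admixture_fit")) {
    populations <- populations %||% q$populations
    q <- q$q
  }
  q <- as.matrix(q)
  if (is.null(populations)) abort("Supply `populations` for the q matrix.")
  if (!is.null(names(populations))) {
    populations <- populations[rownames(q)]
    if (anyNA(populations)) abort("Unknown population label for some individual.")
  }
  if (length(populations) != nrow(q)) {
    abort("`populations` must have one label per individual.")
  }
  if (is.null(colnames(q))) colnames(q) <- paste0("cluster_", seq_len(ncol(q)))
  dominant <- apply(q, 1, max)
  dom_cluster <- apply(q, 1, which.max)
  # block order from factor levels when supplied, else alphabetical, so the
  # layout does not depend on the input row order
  lev <- if (is.factor(populations)) levels(populations)
         else sort(unique(as.character(populations)))
  populations <- as.character(populations)
  ord <- order(
    match(populations, lev),
    dom_cluster,
    -dominant,
    rownames(q) %||% seq_len(nrow(q))
  )
  pos <- integer(nrow(q))
  pos[ord] <- seq_len(nrow(q))
  out <- tibble::tibble(
    individual = rep(rownames(q), times = ncol(q)),
    population = rep(populations, times = ncol(q)),
    cluster = rep(colnames(q), each = nrow(q)),
    proportion = as.vector(q),
    order = rep(pos, times = ncol(q))
  )
  class(out) <- c("membership_table", class(out))
  out
}
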