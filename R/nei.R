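# Nei's standard genetic distance between populations or individuals.

# Precompute per-locus frequency cross-products so the bootstrap can
# re-average over resampled loci with a single matrix multiply.
# Returns list(labels, n, L, S = n^2 x L cross-products, diagS = n x L,
# typed = L x n logical).
nei_cache <- function(genotypes, unit = c("individual", "population")) {
  unit <- match.arg(unit)
  assert_genotype_tibble(genotypes)
  typed_tbl <- drop_missing_calls(genotypes)
  if (nrow(typed_tbl) == 0L) abort("No typed calls in the dataset.")
  loci <- unique(genotypes$locus)
  if (unit == "population") {
    labels <- unique(genotypes$population)
    unit_of <- typed_tbl$population
  } else {
    labels <- unique(genotypes$individual)
    unit_of <- typed_tbl$individual
  }
  n <- length(labels)
  L <- length(loci)
  S <- matrix(0, n * n, L)
  diagS <- matrix(0, n, L)
  typed <- matrix(FALSE, L, n)
  for (l in seq_len(L)) {
    d <- typed_tbl[typed_tbl$locus == loci[l], ]
    if (nrow(d) == 0L) next
    alleles <- sort(unique(c(d$allele_1, d$allele_2)))
    U <- matrix(0, n, length(alleles))
    ui <- match(if (unit == "population") d$population else d$individual,
                labels)
    for (r in seq_len(nrow(d))) {
      U[ui[r], match(d$allele_1[r], alleles)] <-
        U[ui[r], match(d$allele_1[r], alleles)] + 1
      U[ui[r], match(d$allele_2[r], alleles)] <-
        U[ui[r], match(d$allele_2[r], alleles)] + 1
    }
    tot <- rowSums(U)
    has <- tot > 0
    U[has, ] <- U[has, , drop = FALSE] / tot[has]
    Sl <- U %*% t(U)
    S[, l] <- as.vector(Sl)
    diagS[, l] <- diag(Sl)
    typed[l, ] <- has
  }
  mask <- matrix(0, n * n, L)
  for (l in seq_len(L)) {
    mask[, l] <- as.vector(outer(typed[l, ] * 1, typed[l, ] * 1))
  }
  list(labels = labels, n = n, L = L, S = S * mask, diagS = diagS,
       typed = typed)
}

# Distance matrix from a cache under locus weights w (bootstrap counts or
# all-ones). Returns NULL if some pair shares no typed locus or has
# J_XY <= 0 and no cap is supplied.
nei_from_cache <- function(cache, w, cap = NULL) {
  n <- cache$n
  Tm <- cache$typed * 1 # L x n
  wT <- Tm * w
  pair_count <- t(Tm) %*% wT # n x n weighted shared-locus counts
  if (any(pair_count == 0)) return(NULL)
  # per-pair mean J_XY over shared loci
  Jxy <- matrix(cache$S %*% w, n, n) / pair_count
  A <- cache$diagS * t(Tm) # n x L
  Jx <- (A %*% wT) / pair_count # mean J_X over loci shared with each partner
  D <- -log(Jxy / sqrt(Jx * t(Jx)))
  diag(D) <- 0
  bad <- !is.finite(D) | Jxy <= 0
  diag(bad) <- FALSE
  if (any(bad)) {
    if (is.null(cap)) return(NULL)
    D[bad] <- cap
  }
  D <- pmax(D, 0)
  dimnames(D) <- list(cache$labels, cache$labels)
  D
}

#' Nei's standard genetic distance
#'
#' For units X, Y with per-locus allele frequencies x, y:
#' `J_X = mean_l sum_i x_i^2`, `J_Y` likewise,
#' `J_XY = mean_l sum_i x_i y_i`, and
#' `D = -ln(J_XY / sqrt(J_X * J_Y))`. Means are taken over the loci typed
#' in both units. In `individual` mode each plant is a unit with allele
#' frequencies 0, 0.5 or 1. D is non-negative and symmetric but not a
#' metric.
#'
#' @inheritParams allele_frequencies
#' @param unit `"individual"` (default; each plant one unit) or
#'   `"population"`.
#' @param cap Optional finite distance substituted when a pair shares no
#'   alleles (`J_XY = 0`, D infinite); without it such pairs are an error.
#' @return A `nei_dist` object: symmetric matrix with unit labels.
#' @export
nei_standard_distance <- function(genotypes,
                                  unit = c("individual", "population"),
                                  cap = NULL) {
  unit <- match.arg(unit)
  cache <- nei_cache(genotypes, unit)
  D <- nei_from_cache(cache, rep(1, cache$L), cap = cap)
  if (is.null(D)) {
    abort("Some pair of units shares no alleles (or no typed locus): Nei's D is infinite. Supply `cap` for a finite substitute.")
  }
  structure(D, class = c("nei_dist", "matrix"), unit = unit)
}

#' @export
print.nei_dist <- function(x, ...) {
  cat(sprintf("<nei_dist> %d %ss\n", nrow(x), attr(x, "unit") %||% "unit"))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Tidy a Nei distance matrix into long format
#'
#' @param x A `nei_dist` matrix.
#' @param ... Unused.
#' @return Tibble `unit_1`, `unit_2`, `distance` (lower triangle).
#' @export
tidy.nei_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    unit_1 = rownames(m)[idx[, 2]],
    unit_2 = rownames(m)[idx[, 1]],
    distance = m[idx]
  )
}
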