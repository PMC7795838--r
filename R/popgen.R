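# Per-locus and per-population SSR diversity statistics: allele
# frequencies, observed/expected heterozygosity, fixation index, null
# alleles, and the per-population summary table.

drop_missing_calls <- function(genotypes) {
  dplyr::filter(genotypes, !is.na(.data$allele_1) & !is.na(.data$allele_2))
}

#' Allele frequencies per population and locus
#'
#' Each typed individual contributes its two allele copies; individuals
#' with a missing call at a locus are excluded entirely at that locus.
#'
#' @param genotypes Genotype tibble (`population`, `individual`, `locus`,
#'   `allele_1`, `allele_2`; `NA` = missing).
#' @param population,locus Optional filters; when both are given and the
#'   selection holds no non-missing call, an error names the locus.
#' @return Tibble `population`, `locus`, `allele`, `count`, `freq`
#'   (frequencies sum to 1 within each population x locus).
#' @export
allele_frequencies <- function(genotypes, population = NULL, locus = NULL) {
  assert_genotype_tibble(genotypes)
  g <- genotypes
  if (!is.null(population)) g <- g[g$population %in% population, ]
  if (!is.null(locus)) g <- g[g$locus %in% locus, ]
  typed <- drop_missing_calls(g)
  if (nrow(typed) == 0L) {
    abort(sprintf(
      "No non-missing calls for locus %s.",
      paste(unique(g$locus) %||% "(none)", collapse = ", ")
    ))
  }
  typed |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::count(.data$population, .data$locus, .data$allele,
                 name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

# Per population x locus: typed count, Ho, unbiased He, allele count.
locus_stats <- function(genotypes) {
  typed <- drop_missing_calls(genotypes)
  base <- typed |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n_typed = dplyr::n(),
      ho = mean(.data$allele_1 != .data$allele_2),
      .groups = "drop"
    )
  sump2 <- typed |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::count(.data$population, .data$locus, .data$allele) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n_alleles = dplyr::n(),
      sum_p2 = sum((.data$n / sum(.data$n))^2),
      .groups = "drop"
    )
  dplyr::left_join(base, sump2, by = c("population", "locus")) |>
    dplyr::mutate(
      he = dplyr::if_else(
        .data$n_typed >= 2L,
        (2 * .data$n_typed) / (2 * .data$n_typed - 1) * (1 - .data$sum_p2),
        NA_real_
      )
    )
}

#' Observed heterozygosity at one locus in one population
#'
#' Fraction of typed individuals whose two alleles differ.
#'
#' @inheritParams allele_frequencies
#' @return Proportion in \[0, 1\].
#' @export
observed_heterozygosity <- function(genotypes, population, locus) {
  assert_genotype_tibble(genotypes)
  g <- drop_missing_calls(
    genotypes[genotypes$population == population & genotypes$locus == locus, ]
  )
  if (nrow(g) == 0L) {
    abort(sprintf("No non-missing calls for locus %s in %s.", locus,
                  population))
  }
  mean(g$allele_1 != g$allele_2)
}

#' Unbiased expected heterozygosity (Nei's gene diversity)
#'
#' `He = (2n / (2n - 1)) * (1 - sum(p_i^2))` with `n` the number of typed
#' individuals; requires `n >= 2`.
#'
#' @inheritParams allele_frequencies
#' @return Gene diversity in \[0, 1\].
#' @export
expected_heterozygosity <- function(genotypes, population, locus) {
  assert_genotype_tibble(genotypes)
  g <- drop_missing_calls(
    genotypes[genotypes$population == population & genotypes$locus == locus, ]
  )
  n <- nrow(g)
  if (n < 2L) {
    abort("At least 2 typed individuals are needed for unbiased He.")
  }
  p <- allele_frequencies(genotypes, population, locus)$freq
  (2 * n) / (2 * n - 1) * (1 - sum(p^2))
}

#' Fixation index from locus-averaged heterozygosities
#'
#' `F = 1 - Ho / He = (He - Ho) / He`: positive under heterozygote deficit
#' (inbreeding), negative under heterozygote excess (e.g. clonal
#' propagation of heterozygous founders). Undefined (`NA`) when `He = 0`.
#'
#' @param he_mean,ho_mean Locus-averaged expected and observed
#'   heterozygosities (vectorized).
#' @return Fixation index.
#' @export
fixation_index <- function(he_mean, ho_mean) {
  dplyr::if_else(he_mean > 0, 1 - ho_mean / he_mean, NA_real_)
}

#' Null-allele frequency estimate
#'
#' Chakraborty-style estimator `r = (He - Ho) / (He + Ho)`; negative values
#' (heterozygote excess) are reported as-is. Undefined when `He + Ho = 0`.
#'
#' @param he,ho Expected and observed heterozygosity (vectorized).
#' @return Estimated null-allele frequency.
#' @export
null_allele_frequency <- function(he, ho) {
  dplyr::if_else(he + ho > 0, (he - ho) / (he + ho), NA_real_)
}

#' Per-locus summary table
#'
#' Typed sample size, allele count, observed and unbiased expected
#' heterozygosity, exact Hardy-Weinberg p-value and null-allele frequency
#' for every population x locus combination with data.
#'
#' @inheritParams allele_frequencies
#' @param hwe Compute exact HWE p-values (see [hwe_exact_test()]).
#' @param method,reps HWE test settings.
#' @param seed Seed for Monte-Carlo HWE p-values.
#' @return Tibble with one row per population x locus.
#' @export
locus_table <- function(genotypes, hwe = TRUE, method = "auto",
                        reps = 10000, seed = 1L) {
  assert_genotype_tibble(genotypes)
  out <- locus_stats(genotypes) |>
    dplyr::mutate(null_freq = null_allele_frequency(.data$he, .data$ho))
  if (hwe) {
    out$hwe_p <- purrr::pmap_dbl(
      list(out$population, out$locus),
      function(p, l) {
        calls <- drop_missing_calls(
          genotypes[genotypes$population == p & genotypes$locus == l, ]
        )
        hwe_exact_test(calls, method = method, reps = reps,
                       seed = derive_seed(seed, paste(p, l, "hwe")))
      }
    )
  }
  dplyr::select(out, -"sum_p2")
}

#' Per-population diversity summary (Table-1-shaped)
#'
#' For each population: sample size N, mean unbiased He and mean Ho across
#' loci with data (unweighted), fixation index
#' `F = 1 - mean(Ho) / mean(He)`, and a permutation p-value for deviation
#' from Hardy-Weinberg expectation ([f_significance_test()]).
#'
#' @inheritParams allele_frequencies
#' @param reps Permutation replicates for the F test (>= 100).
#' @param seed Integer seed.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05, no multiple-testing correction).
#' @param adjust `"none"` (default) or `"bonferroni"` across populations.
#' @return Tibble `population`, `n`, `he_mean`, `ho_mean`, `f`, `f_p`,
#'   `significant`, ordered as in the input.
#' @export
population_table <- function(genotypes, reps = 1000, seed = 1L,
                             alpha = 0.05, adjust = c("none", "bonferroni")) {
  assert_genotype_tibble(genotypes)
  adjust <- match.arg(adjust)
  pops <- unique(genotypes$population)
  if (length(pops) == 0L || nrow(genotypes) == 0L) {
    abort("Empty genotype table.")
  }
  st <- locus_stats(genotypes)
  out <- purrr::map_dfr(pops, function(p) {
    sp <- st[st$population == p, ]
    if (nrow(sp) == 0L) abort(sprintf("Population %s has no typed calls.", p))
    he_mean <- mean(sp$he, na.rm = TRUE)
    ho_mean <- mean(sp$ho)
    tibble::tibble(
      population = p,
      n = dplyr::n_distinct(
        genotypes$individual[genotypes$population == p]
      ),
      he_mean = he_mean,
      ho_mean = ho_mean,
      f = fixation_index(he_mean, ho_mean),
      f_p = f_significance_test(genotypes, p, reps = reps,
                                seed = derive_seed(seed, paste("fperm", p)))
    )
  })
  out$f_p <- stats::p.adjust(out$f_p, method = adjust)
  out$significant <- !is.na(out$f_p) & out$f_p < alpha
  out
}

#' SSR library screening percentage
#'
#' Percentage of screened clones that contained an SSR, rounded to one
#' decimal (e.g. 107 of 144 -> 74.3).
#'
#' @param positive Number of SSR-containing clones.
#' @param total Number of screened clones (> 0).
#' @return Percentage rounded to one decimal.
#' @export
marker_screening_summary <- function(positive, total) {
  if (length(total) != 1L || !is.finite(total) || total <= 0) {
    abort("`total` must be a positive count.")
  }
  if (positive < 0 || positive > total) {
    abort("`positive` must lie between 0 and `total`.")
  }
  round(100 * positive / total, 1)
}
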