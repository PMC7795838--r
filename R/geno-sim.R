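# Synthetic diploid SSR genotype datasets with known ground truth.

#' Parameters for the SSR genotype simulator
#'
#' Defaults mirror the sampling design of the field study the package
#' models: eight populations with 5-18 plants each, 21 SSR loci, allele
#' fragment sizes on a dinucleotide ladder (100, 102, ...).
#'
#' @param n_populations Number of populations.
#' @param n_individuals_per_pop Integer vector of sample sizes (recycled to
#'   `n_populations`).
#' @param n_loci Number of SSR loci.
#' @param alleles_per_locus Number of distinct alleles segregating per
#'   locus.
#' @param freq_concentration Symmetric Dirichlet concentration used to draw
#'   per-population allele frequencies (small values give skewed spectra).
#' @param f_is_per_pop Within-population inbreeding coefficient(s) in
#'   \[-1, 1\] (recycled); positive values deplete heterozygotes, negative
#'   values enrich them.
#' @param admixture_alpha Optional symmetric Dirichlet parameter for
#'   per-individual admixture proportions across `n_populations` ancestral
#'   clusters. Mutually exclusive with non-zero `f_is_per_pop`.
#' @param clonal_founders Optional founder count for
#'   [simulate_clonal_population()] (recycled per population).
#' @param missing_rate Per-call missing probability in \[0, 1).
#' @param seed Root integer seed; all component streams derive from it.
#' @param population_names Optional population names.
#' @return A list of class `pop_sim_params`.
#' @export
#' @examples
#' sim <- simulate_genotypes(pop_sim_params(n_populations = 2,
#'   n_individuals_per_pop = 10, n_loci = 5, seed = 42))
#' sim$genotypes
pop_sim_params <- function(n_populations = 8,
                           n_individuals_per_pop = c(9, 9, 9, 7, 10, 9, 5, 18),
                           n_loci = 21,
                           alleles_per_locus = 5,
                           freq_concentration = 1,
                           f_is_per_pop = 0,
                           admixture_alpha = NULL,
                           clonal_founders = NULL,
                           missing_rate = 0,
                           seed = 1L,
                           population_names = NULL) {
  stopifnot(n_populations >= 1, n_loci >= 1, alleles_per_locus >= 1)
  n_ind <- as.integer(rep_len(n_individuals_per_pop, n_populations))
  if (any(n_ind < 1L)) abort("Sample sizes must be >= 1.")
  f <- rep_len(f_is_per_pop, n_populations)
  if (any(abs(f) > 1)) abort("`f_is_per_pop` values must lie in [-1, 1].")
  assert_scalar_number(freq_concentration, "freq_concentration",
                       lower = 0, open_lower = TRUE)
  assert_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1,
                       open_upper = TRUE)
  if (!is.null(admixture_alpha)) {
    assert_scalar_number(admixture_alpha, "admixture_alpha",
                         lower = 0, open_lower = TRUE)
    if (any(f != 0)) {
      abort("Admixture and non-zero F_IS are mutually exclusive simulation regimes.")
    }
  }
  if (!is.null(clonal_founders)) {
    cf <- as.integer(rep_len(clonal_founders, n_populations))
    if (any(cf < 1L)) abort("`clonal_founders` must be >= 1.")
    if (any(cf > n_ind)) {
      abort("`clonal_founders` cannot exceed the population sample size.")
    }
  } else {
    cf <- NULL
  }
  pops <- population_names %||% paste0("pop", seq_len(n_populations))
  if (length(pops) != n_populations) {
    abort("`population_names` must have length `n_populations`.")
  }
  structure(
    list(
      n_populations = n_populations,
      n_individuals_per_pop = n_ind,
      n_loci = n_loci,
      alleles_per_locus = as.integer(alleles_per_locus),
      freq_concentration = freq_concentration,
      f_is_per_pop = f,
      admixture_alpha = admixture_alpha,
      clonal_founders = cf,
      missing_rate = missing_rate,
      seed = as.integer(seed),
      population_names = pops
    ),
    class = "pop_sim_params"
  )
}

# Allele fragment sizes: even integers from 100, mimicking dinucleotide SSRs.
allele_sizes <- function(n) 100L + 2L * (seq_len(n) - 1L)

# Draw per-population (or per-cluster) allele frequencies.
draw_freqs <- function(params) {
  A <- params$alleles_per_locus
  lapply(seq_len(params$n_populations), function(p) {
    matrix(
      vapply(seq_len(params$n_loci), function(l) {
        rdirichlet1(rep(params$freq_concentration, A))
      }, numeric(A)),
      nrow = A
    )
  }) # list over pops; each A x L matrix
}

# Genotype (unordered allele pair) probabilities under inbreeding F.
genotype_probs_f <- function(p, f) {
  A <- length(p)
  idx <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
  prob <- ifelse(
    idx[, 1] == idx[, 2],
    p[idx[, 1]]^2 + f * p[idx[, 1]] * (1 - p[idx[, 1]]),
    2 * p[idx[, 1]] * p[idx[, 2]] * (1 - f)
  )
  if (any(prob < -1e-12)) {
    abort(sprintf(
      "F = %g makes a genotype probability negative for these allele frequencies; choose F >= -p/(1-p) for every allele.",
      f
    ))
  }
  list(a1 = idx[, 1], a2 = idx[, 2], prob = pmax(prob, 0))
}

#' Simulate diploid SSR genotypes with known ground truth
#'
#' Per population and locus, allele frequencies are drawn from a symmetric
#' Dirichlet; genotypes are then drawn with inbreeding coefficient F
#' (`P(homozygote i) = p_i^2 + F p_i (1 - p_i)`,
#' `P(heterozygote ij) = 2 p_i p_j (1 - F)`). With `admixture_alpha` set,
#' each individual instead receives admixture proportions
#' `q ~ Dirichlet(alpha, ...)` over `n_populations` ancestral clusters and
#' every allele copy is drawn from a cluster chosen by `q`. Missing calls
#' are inserted at `missing_rate`. Fully reproducible from the root seed.
#'
#' @param params A [pop_sim_params()] object.
#' @return List with `genotypes` (tibble: `population`, `individual`,
#'   `locus`, `allele_1`, `allele_2`; alleles are fragment sizes, `NA` =
#'   missing) and `truth` (list: `allele_freqs` tibble, `q` tibble,
#'   `f_is` tibble).
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "pop_sim_params"))
  with_seed(derive_seed(params$seed, "genotypes"), {
    simulate_genotypes_impl(params)
  })
}

simulate_genotypes_impl <- function(params) {
  A <- params$alleles_per_locus
  L <- params$n_loci
  sizes <- allele_sizes(A)
  loci <- sprintf("locus_%02d", seq_len(L))
  pops <- params$population_names
  freqs <- draw_freqs(params)
  admixed <- !is.null(params$admixture_alpha)

  rows <- vector("list", params$n_populations)
  qrows <- vector("list", params$n_populations)
  for (p in seq_len(params$n_populations)) {
    n <- params$n_individuals_per_pop[p]
    f <- params$f_is_per_pop[p]
    ind <- sprintf("%s_%02d", pops[p], seq_len(n))
    a1 <- matrix(0L, n, L)
    a2 <- matrix(0L, n, L)
    if (admixed) {
      K <- params$n_populations
      qm <- t(vapply(seq_len(n), function(i) {
        rdirichlet1(rep(params$admixture_alpha, K))
      }, numeric(K)))
      qrows[[p]] <- tibble::tibble(
        population = pops[p],
        individual = rep(ind, each = K),
        cluster = rep(seq_len(K), times = n),
        q = as.vector(t(qm))
      )
      for (l in seq_len(L)) {
        for (copy in 1:2) {
          z <- vapply(seq_len(n), function(i) {
            sample.int(K, 1L, prob = qm[i, ])
          }, integer(1))
          al <- vapply(seq_len(n), function(i) {
            sample.int(A, 1L, prob = freqs[[z[i]]][, l])
          }, integer(1))
          if (copy == 1L) a1[, l] <- al else a2[, l] <- al
        }
      }
    } else {
      qm <- matrix(0, n, params$n_populations)
      qm[, p] <- 1
      qrows[[p]] <- tibble::tibble(
        population = pops[p],
        individual = rep(ind, each = params$n_populations),
        cluster = rep(seq_len(params$n_populations), times = n),
        q = as.vector(t(qm))
      )
      for (l in seq_len(L)) {
        gp <- genotype_probs_f(freqs[[p]][, l], f)
        g <- sample.int(length(gp$prob), n, replace = TRUE, prob = gp$prob)
        a1[, l] <- gp$a1[g]
        a2[, l] <- gp$a2[g]
      }
    }
    tbl <- tibble::tibble(
      population = pops[p],
      individual = rep(ind, times = L),
      locus = rep(loci, each = n),
      allele_1 = sizes[as.vector(a1)],
      allele_2 = sizes[as.vector(a2)]
    )
    rows[[p]] <- tbl
  }
  geno <- dplyr::bind_rows(rows) |>
    dplyr::arrange(
      match(.data$population, pops), .data$individual,
      match(.data$locus, loci)
    )
  # alleles within a call stored unordered; canonicalize low/high
  swap <- !is.na(geno$allele_1) & geno$allele_1 > geno$allele_2
  tmp <- geno$allele_1[swap]
  geno$allele_1[swap] <- geno$allele_2[swap]
  geno$allele_2[swap] <- tmp
  if (params$missing_rate > 0) {
    miss <- runif(nrow(geno)) < params$missing_rate
    geno$allele_1[miss] <- NA_integer_
    geno$allele_2[miss] <- NA_integer_
  }
  truth_freqs <- purrr::imap_dfr(freqs, function(fm, p) {
    tibble::tibble(
      population = pops[p],
      cluster = p,
      locus = rep(loci, each = A),
      allele = rep(sizes, times = L),
      freq = as.vector(fm)
    )
  })
  list(
    genotypes = geno,
    truth = list(
      allele_freqs = truth_freqs,
      q = dplyr::bind_rows(qrows),
      f_is = tibble::tibble(population = pops, f = params$f_is_per_pop)
    )
  )
}

#' Simulate clonally propagated populations
#'
#' Draws `clonal_founders` distinct multilocus genotypes at Hardy-Weinberg
#' equilibrium per population, then fills the sample by copying founders
#' uniformly at random -- the bulb-propagation regime in which observed
#' heterozygosity exceeds expectation and the fixation index goes negative
#' whenever founders happen to be heterozygous.
#'
#' @param params A [pop_sim_params()] with `clonal_founders` set.
#' @return As [simulate_genotypes()]; `truth` additionally carries a
#'   `founders` tibble mapping individuals to founder genotypes.
#' @export
simulate_clonal_population <- function(params) {
  stopifnot(inherits(params, "pop_sim_params"))
  if (is.null(params$clonal_founders)) {
    abort("`clonal_founders` must be set for a clonal simulation.")
  }
  with_seed(derive_seed(params$seed, "clonal"), {
    A <- params$alleles_per_locus
    L <- params$n_loci
    sizes <- allele_sizes(A)
    loci <- sprintf("locus_%02d", seq_len(L))
    pops <- params$population_names
    freqs <- draw_freqs(params)
    rows <- vector("list", params$n_populations)
    frows <- vector("list", params$n_populations)
    for (p in seq_len(params$n_populations)) {
      n <- params$n_individuals_per_pop[p]
      nf <- params$clonal_founders[p]
      # founder multilocus genotypes at HWE (F = 0), forced distinct
      draw_founder <- function() {
        g <- vapply(seq_len(L), function(l) {
          pr <- freqs[[p]][, l]
          c(sample.int(A, 1L, prob = pr), sample.int(A, 1L, prob = pr))
        }, integer(2))
        rbind(pmin(g[1, ], g[2, ]), pmax(g[1, ], g[2, ]))
      }
      founders <- list()
      tries <- 0L
      while (length(founders) < nf) {
        cand <- draw_founder()
        key <- paste(cand, collapse = ",")
        if (!key %in% names(founders)) founders[[key]] <- cand
        tries <- tries + 1L
        if (tries > 100L * nf) {
          abort("Could not draw distinct founder genotypes; increase diversity.")
        }
      }
      founders <- unname(founders)
      assign_f <- sample.int(nf, n, replace = TRUE)
      ind <- sprintf("%s_%02d", pops[p], seq_len(n))
      a1 <- t(vapply(assign_f, function(fi) founders[[fi]][1, ], integer(L)))
      a2 <- t(vapply(assign_f, function(fi) founders[[fi]][2, ], integer(L)))
      rows[[p]] <- tibble::tibble(
        population = pops[p],
        individual = rep(ind, times = L),
        locus = rep(loci, each = n),
        allele_1 = sizes[as.vector(a1)],
        allele_2 = sizes[as.vector(a2)]
      )
      frows[[p]] <- tibble::tibble(
        population = pops[p], individual = ind, founder = assign_f
      )
    }
    geno <- dplyr::bind_rows(rows)
    if (params$missing_rate > 0) {
      miss <- runif(nrow(geno)) < params$missing_rate
      geno$allele_1[miss] <- NA_integer_
      geno$allele_2[miss] <- NA_integer_
    }
    list(
      genotypes = geno,
      truth = list(
        allele_freqs = purrr::imap_dfr(freqs, function(fm, p) {
          tibble::tibble(
            population = pops[p], cluster = p,
            locus = rep(loci, each = A),
            allele = rep(sizes, times = L),
            freq = as.vector(fm)
          )
        }),
        founders = dplyr::bind_rows(frows)
      )
    )
  })
}
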