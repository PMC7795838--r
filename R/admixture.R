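# Model-based admixture clustering: Gibbs sampler over the standard
# admixture model with independent allele frequencies, ln P(D) scoring.

# Flatten a genotype tibble into allele-copy vectors for the sampler.
prep_admixture_data <- function(genotypes) {
  assert_genotype_tibble(genotypes)
  inds <- unique(genotypes$individual)
  pops <- genotypes$population[match(inds, genotypes$individual)]
  loci <- unique(genotypes$locus)
  typed <- drop_missing_calls(genotypes)
  if (nrow(typed) == 0L) abort("Empty dataset: no typed allele copies.")
  allele_sets <- lapply(loci, function(l) {
    sort(unique(c(typed$allele_1[typed$locus == l],
                  typed$allele_2[typed$locus == l])))
  })
  n_alleles <- lengths(allele_sets)
  offset <- c(0L, cumsum(n_alleles))[seq_along(loci)]
  li <- match(typed$locus, loci)
  col1 <- offset[li] + vapply(seq_len(nrow(typed)), function(r) {
    match(typed$allele_1[r], allele_sets[[li[r]]])
  }, integer(1))
  col2 <- offset[li] + vapply(seq_len(nrow(typed)), function(r) {
    match(typed$allele_2[r], allele_sets[[li[r]]])
  }, integer(1))
  list(
    individuals = inds,
    populations = pops,
    loci = loci,
    allele_sets = allele_sets,
    locus_of_col = rep(seq_along(loci), n_alleles),
    n_cols = sum(n_alleles),
    copy_ind = rep(match(typed$individual, inds), 2L),
    copy_col = c(col1, col2)
  )
}

#' Gibbs sampler for the admixture model
#'
#' Standard admixture model with independent allele frequencies: each
#' individual i has admixture proportions `q_i` over `k` clusters, each
#' cluster a frequency vector per locus, and every allele copy originates
#' from a latent cluster Z drawn proportional to `q_ik * p_k(allele)`.
#' Updates per sweep: P ~ Dirichlet(lambda + copy counts),
#' Q ~ Dirichlet(alpha + copy counts), Z given (P, Q), and alpha by a
#' Metropolis step under a Uniform(0, `alpha_prior_max`) prior. Missing
#' calls are skipped in counts and likelihood. Fully seeded and
#' reproducible.
#'
#' Default chain lengths are desk-scale; field-scale settings (burn-in
#' 50,000, 1,000,000 replications) are available through the arguments.
#'
#' @inheritParams allele_frequencies
#' @param k Number of clusters (>= 1).
#' @param burn_in Burn-in sweeps.
#' @param reps Post-burn-in sweeps.
#' @param thin Trace thinning interval.
#' @param seed Integer seed.
#' @param lambda Dirichlet parameter for allele frequencies.
#' @param alpha_init,alpha_prior_max,alpha_proposal_sd Admixture
#'   concentration: initial value, uniform-prior upper bound, Metropolis
#'   proposal SD.
#' @param update_alpha Sample alpha (TRUE) or keep it fixed.
#' @return An `admixture_fit`: posterior-mean `q` (individuals x k,
#'   rows sum to 1), posterior-mean cluster frequencies `p` (list per
#'   locus of k x alleles matrices), thinned `lnL_trace` and
#'   `alpha_trace`, `ln_prob_data` (mean minus half variance of the
#'   trace), plus bookkeeping fields.
#' @export
run_admixture_mcmc <- function(genotypes, k, burn_in = 5000, reps = 20000,
                               thin = 10, seed = 1L, lambda = 1,
                               alpha_init = 1, alpha_prior_max = 10,
                               alpha_proposal_sd = 0.05,
                               update_alpha = TRUE) {
  if (k < 1) abort("`k` must be >= 1.")
  stopifnot(burn_in >= 1, reps >= 1, thin >= 1, lambda > 0)
  dat <- prep_admixture_data(genotypes)
  n <- length(dat$individuals)
  A <- dat$n_cols
  L <- length(dat$loci)
  nc <- length(dat$copy_ind)
  locus_of_col <- dat$locus_of_col
  copy_ind <- dat$copy_ind
  copy_col <- dat$copy_col
  k <- as.integer(k)

  with_seed(derive_seed(seed, paste0("admixture_k", k)), {
    Z <- sample.int(k, nc, replace = TRUE)
    alpha <- alpha_init
    Q <- matrix(1 / k, n, k)
    qsum <- matrix(0, n, k)
    psum <- matrix(0, k, A)
    n_sweeps <- burn_in + reps
    keep_idx <- seq(burn_in + thin, n_sweeps, by = thin)
    lnL_trace <- numeric(length(keep_idx))
    alpha_trace <- numeric(length(keep_idx))
    kept <- 0L
    accept <- 0L
    slog <- function(x) log(pmax(x, 1e-300))

    for (sweep in seq_len(n_sweeps)) {
      # P | Z
      cnt <- tabulate(Z + k * (copy_col - 1L), nbins = k * A)
      G <- matrix(rgamma(k * A, shape = lambda + cnt), k, A)
      blocksum <- t(rowsum(t(G), group = locus_of_col)) # k x L
      P <- G / blocksum[, locus_of_col, drop = FALSE]

      # Q | Z, alpha
      if (k > 1L) {
        cm <- tabulate(copy_ind + n * (Z - 1L), nbins = n * k)
        QG <- matrix(rgamma(n * k, shape = alpha + cm), n, k)
        Q <- QG / pmax(rowSums(QG), 1e-300)
      }

      # Z | P, Q (and the data log-likelihood at the current P, Q)
      W <- Q[copy_ind, , drop = FALSE] * t(P)[copy_col, , drop = FALSE]
      tot <- rowSums(W)
      lnL <- sum(slog(tot))
      if (k > 1L) {
        u <- runif(nc) * tot
        cntv <- integer(nc)
        acc <- numeric(nc)
        for (kk in seq_len(k - 1L)) {
          acc <- acc + W[, kk]
          cntv <- cntv + (u > acc)
        }
        Z <- 1L + cntv
      }

      # alpha | Q (Metropolis, uniform prior)
      if (update_alpha && k > 1L) {
        prop <- alpha + rnorm(1, sd = alpha_proposal_sd)
        if (prop > 0 && prop < alpha_prior_max) {
          slq <- sum(slog(Q))
          logr <- n * (lgamma(k * prop) - k * lgamma(prop)) +
            (prop - 1) * slq -
            (n * (lgamma(k * alpha) - k * lgamma(alpha)) +
               (alpha - 1) * slq)
          if (is.finite(logr) && log(runif(1)) < logr) {
            alpha <- prop
            accept <- accept + 1L
          }
        } else {
          runif(1) # keep the stream aligned regardless of proposal validity
        }
      }

      if (sweep > burn_in) {
        qsum <- qsum + Q
        psum <- psum + P
        if (kept < length(keep_idx) && sweep == keep_idx[kept + 1L]) {
          kept <- kept + 1L
          lnL_trace[kept] <- lnL
          alpha_trace[kept] <- alpha
        }
      }
    }

    qbar <- qsum / reps
    pbar <- psum / reps
    p_list <- lapply(seq_len(L), function(l) {
      cols <- which(locus_of_col == l)
      m <- pbar[, cols, drop = FALSE]
      colnames(m) <- as.character(dat$allele_sets[[l]])
      rownames(m) <- paste0("cluster_", seq_len(k))
      m
    })
    names(p_list) <- dat$loci
    rownames(qbar) <- dat$individuals
    colnames(qbar) <- paste0("cluster_", seq_len(k))
    structure(
      list(
        k = k,
        q = qbar,
        p = p_list,
        lnL_trace = lnL_trace[seq_len(kept)],
        alpha_trace = alpha_trace[seq_len(kept)],
        ln_prob_data = estimate_ln_prob_data(lnL_trace[seq_len(kept)]),
        individuals = dat$individuals,
        populations = dat$populations,
        alpha_accept_rate = if (update_alpha && k > 1L) accept / n_sweeps
                            else NA_real_,
        burn_in = burn_in, reps = reps, thin = thin, seed = seed
      ),
      class = "admixture_fit"
    )
  })
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "<admixture_fit> k = %d, %d individuals, ln P(D) = %.1f\n",
    x$k, nrow(x$q), x$ln_prob_data
  ))
  invisible(x)
}

#' Admixture-model data log-likelihood
#'
#' Sum over non-missing allele copies of
#' `ln(sum_k q_ik * p_k(allele))`. A copy whose allele has zero
#' probability under every cluster makes the result `-Inf` (with a
#' warning naming the number of such copies).
#'
#' @inheritParams allele_frequencies
#' @param p List per locus of k x alleles frequency matrices with allele
#'   codes as column names (as in an `admixture_fit`).
#' @param q Individuals x k matrix of admixture proportions with
#'   individual names as row names.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(genotypes, p, q) {
  assert_genotype_tibble(genotypes)
  typed <- drop_missing_calls(genotypes)
  k <- ncol(q)
  total <- 0
  n_zero <- 0L
  for (l in names(p)) {
    d <- typed[typed$locus == l, ]
    if (nrow(d) == 0L) next
    pm <- p[[l]]
    for (al in c("allele_1", "allele_2")) {
      ci <- match(as.character(d[[al]]), colnames(pm))
      qi <- match(d$individual, rownames(q))
      if (anyNA(qi)) abort("Individuals in `genotypes` and `q` disagree.")
      pr <- numeric(nrow(d))
      known <- !is.na(ci)
      if (any(known)) {
        pr[known] <- rowSums(
          q[qi[known], , drop = FALSE] * t(pm)[ci[known], , drop = FALSE]
        )
      }
      n_zero <- n_zero + sum(pr <= 0)
      total <- total + sum(log(pr))
    }
  }
  if (n_zero > 0L) {
    warn(sprintf(
      "%d allele copies have zero probability under every cluster; log-likelihood is -Inf.",
      n_zero
    ))
  }
  total
}

#' ln P(D) estimate from a log-likelihood trace
#'
#' The model-choice score used for K selection:
#' `mean(trace) - var(trace) / 2` with the sample variance (n - 1
#' denominator).
#'
#' @param lnL_trace Numeric trace of data log-likelihoods (length >= 2).
#' @return ln P(D) estimate.
#' @export
estimate_ln_prob_data <- function(lnL_trace) {
  if (length(lnL_trace) < 2L) {
    abort("Need a trace of length >= 2 to estimate ln P(D).")
  }
  mean(lnL_trace) - stats::var(lnL_trace) / 2
}

#' Run the admixture sampler over a grid of K
#'
#' Repeated seeded runs per K (the protocol behind Evanno's delta-K: the
#' field default is K = 1..8 with 10 runs each); each run's seed derives
#' deterministically from the root seed, K and the run index.
#'
#' @inheritParams run_admixture_mcmc
#' @param k_values Integer vector of cluster counts.
#' @param runs_per_k Independent runs per K (>= 2 for Evanno).
#' @param ... Further arguments to [run_admixture_mcmc()].
#' @return An `admixture_scan`: list with `fits` (nested list by K then
#'   run) and `table` (tibble `k`, `run`, `seed`, `ln_prob_data`).
#' @export
run_admixture_scan <- function(genotypes, k_values = 1:8, runs_per_k = 10,
                               seed = 1L, ...) {
  fits <- lapply(k_values, function(kv) {
    lapply(seq_len(runs_per_k), function(r) {
      run_admixture_mcmc(
        genotypes, k = kv,
        seed = derive_seed(seed, sprintf("scan_k%d_run%d", kv, r)), ...
      )
    })
  })
  names(fits) <- paste0("k", k_values)
  tab <- purrr::map2_dfr(fits, k_values, function(runs, kv) {
    tibble::tibble(
      k = kv,
      run = seq_along(runs),
      seed = vapply(runs, function(f) f$seed, numeric(1)),
      ln_prob_data = vapply(runs, function(f) f$ln_prob_data, numeric(1))
    )
  })
  structure(list(fits = fits, table = tab, k_values = k_values),
            class = "admixture_scan")
}

#' @export
print.admixture_scan <- function(x, ...) {
  cat(sprintf("<admixture_scan> K in {%s}, %d runs per K\n",
              paste(x$k_values, collapse = ", "),
              max(x$table$run)))
  invisible(x)
}
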