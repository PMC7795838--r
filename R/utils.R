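# Internal helpers shared across modules.

# Deterministic child seed derived from a root seed and a component label, so
# each pipeline stage gets its own reproducible stream. 32-bit FNV-1a style
# mix kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).",
      name, if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

# Draw one sample from Dirichlet(alpha); alpha a numeric vector.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) { # numerically degenerate tiny alpha
    g[sample.int(length(alpha), 1L)] <- 1
  }
  g / sum(g)
}

is_genotype_tibble <- function(x) {
  is.data.frame(x) &&
    all(c("population", "individual", "locus", "allele_1", "allele_2")
        %in% names(x))
}

assert_genotype_tibble <- function(x, name = "genotypes") {
  if (!is_genotype_tibble(x)) {
    abort(sprintf(
      paste0("`%s` must be a genotype table with columns population, ",
             "individual, locus, allele_1, allele_2."), name))
  }
  bad <- (is.na(x$allele_1) != is.na(x$allele_2))
  if (any(bad)) {
    abort("Half-missing genotype calls found: both allele columns must be NA or neither.")
  }
  if (any(!is.na(x$allele_1) & (x$allele_1 <= 0 | x$allele_2 <= 0))) {
    abort("Allele codes must be positive integers (0 is reserved as the file missing sentinel).")
  }
  dup <- dplyr::distinct(x, .data$population, .data$individual)
  if (anyDuplicated(dup$individual) > 0L) {
    abort("Each individual must belong to exactly one population.")
  }
  invisible(x)
}
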