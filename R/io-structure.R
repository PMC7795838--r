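# STRUCTURE text format: whitespace-separated, one or two rows per
# individual, -9 for missing, optional population column.

#' Read a STRUCTURE-format genotype file
#'
#' Supports both layouts: one row per individual with two columns per
#' locus, or two rows per individual (one allele per locus per row, the
#' individual label repeated). The first line is a header of locus names;
#' `-9` encodes missing. The population column, when present, may hold
#' names or integers (read as labels).
#'
#' @param path Input file.
#' @param format `"one_row"` (default) or `"two_row"`.
#' @param pop_column Whether a population column follows the individual
#'   label (default `TRUE`; without it all individuals land in population
#'   `"pop1"`).
#' @return Genotype tibble.
#' @export
read_structure <- function(path, format = c("one_row", "two_row"),
                           pop_column = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) abort("STRUCTURE file too short.")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  body <- lines[-1]
  n_meta <- 1L + as.integer(pop_column)
  parse_row <- function(i, expect_alleles) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != n_meta + expect_alleles) {
      abort(sprintf(
        "Row %d: expected %d fields (%d metadata + %d alleles), found %d.",
        i + 1L, n_meta + expect_alleles, n_meta, expect_alleles, length(f)
      ))
    }
    alleles <- suppressWarnings(as.integer(f[(n_meta + 1):length(f)]))
    if (anyNA(alleles)) abort(sprintf("Row %d: non-integer allele code.", i + 1L))
    list(
      individual = f[1],
      population = if (pop_column) f[2] else "pop1",
      alleles = alleles
    )
  }
  if (format == "one_row") {
    recs <- lapply(seq_along(body), parse_row, expect_alleles = 2L * L)
    rows <- lapply(recs, function(r) {
      a1 <- r$alleles[seq(1, 2 * L, by = 2)]
      a2 <- r$alleles[seq(2, 2 * L, by = 2)]
      tibble::tibble(
        population = r$population, individual = r$individual, locus = loci,
        allele_1 = a1, allele_2 = a2
      )
    })
  } else {
    if (length(body) %% 2L != 0L) {
      abort("Two-row format requires an even number of data rows.")
    }
    rows <- lapply(seq_len(length(body) / 2L), function(j) {
      r1 <- parse_row(2L * j - 1L, expect_alleles = L)
      r2 <- parse_row(2L * j, expect_alleles = L)
      if (r1$individual != r2$individual) {
        abort(sprintf(
          "Rows %d/%d: the two rows of an individual must repeat its label.",
          2L * j, 2L * j + 1L
        ))
      }
      tibble::tibble(
        population = r1$population, individual = r1$individual, locus = loci,
        allele_1 = r1$alleles, allele_2 = r2$alleles
      )
    })
  }
  out <- dplyr::bind_rows(rows)
  miss <- out$allele_1 == -9L | out$allele_2 == -9L
  out$allele_1[miss] <- NA_integer_
  out$allele_2[miss] <- NA_integer_
  swap <- !is.na(out$allele_1) & out$allele_1 > out$allele_2
  tmp <- out$allele_1[swap]
  out$allele_1[swap] <- out$allele_2[swap]
  out$allele_2[swap] <- tmp
  if (any(!is.na(out$allele_1) & out$allele_1 <= 0)) {
    abort("Allele codes must be positive (only -9 encodes missing).")
  }
  out
}

#' Write a STRUCTURE-format genotype file
#'
#' @inheritParams read_structure
#' @inheritParams allele_frequencies
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(genotypes, path,
                            format = c("one_row", "two_row"),
                            pop_column = TRUE) {
  format <- match.arg(format)
  assert_genotype_tibble(genotypes)
  loci <- unique(genotypes$locus)
  inds <- unique(genotypes$individual)
  pop_of <- genotypes$population[match(inds, genotypes$individual)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci, collapse = "\t"), con)
  for (ix in seq_along(inds)) {
    d <- genotypes[genotypes$individual == inds[ix], ]
    d <- d[match(loci, d$locus), ]
    a1 <- ifelse(is.na(d$allele_1), -9L, d$allele_1)
    a2 <- ifelse(is.na(d$allele_2), -9L, d$allele_2)
    meta <- if (pop_column) c(inds[ix], pop_of[ix]) else inds[ix]
    if (format == "one_row") {
      inter <- as.vector(rbind(a1, a2))
      writeLines(paste(c(meta, inter), collapse = "\t"), con)
    } else {
      writeLines(paste(c(meta, a1), collapse = "\t"), con)
      writeLines(paste(c(meta, a2), collapse = "\t"), con)
    }
  }
  invisible(path)
}
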