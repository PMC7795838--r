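# Genepop text format: title line, locus names, `Pop` separators,
# "name ,  a1a2 a1a2 ..." individual lines with 2- or 3-digit alleles.

#' Read a Genepop file
#'
#' Parses the classic dialect: a title line; locus names either
#' comma-separated on one line or one per line; `Pop` / `POP` / `pop`
#' separators; individual lines `name ,  granules` where each genotype
#' token concatenates two fixed-width allele codes. The allele width (2 or
#' 3 digits) is auto-detected from the token length; `00` / `000` encode
#' missing. Population names are taken from the prefix of each Pop's last
#' individual's label (the part before the final underscore). Malformed
#' input is rejected with the offending line number, never repaired.
#'
#' @param path Genepop file.
#' @return Genotype tibble (`population`, `individual`, `locus`,
#'   `allele_1`, `allele_2`).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort("Genepop file too short.")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("Genepop file has no `Pop` line.")
  header <- lines[2:(first_pop - 1)]
  loci <- unlist(strsplit(paste(header, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[loci != ""]
  if (length(loci) == 0L) abort("No locus names before the first `Pop` line.")

  digits <- NULL
  pop_id <- cumsum(is_pop)
  rows <- list()
  pop_members <- list()
  for (i in seq_along(lines)) {
    if (i < first_pop || is_pop[i]) next
    line <- lines[i]
    if (grepl("^\\s*$", line)) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) {
      abort(sprintf("Line %d: expected `name , genotypes`.", i))
    }
    name <- trimws(parts[1])
    tokens <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "\\s+")[[1]]
    tokens <- tokens[tokens != ""]
    if (length(tokens) != length(loci)) {
      abort(sprintf(
        "Line %d: %d genotype tokens for %d loci.", i, length(tokens),
        length(loci)
      ))
    }
    if (!all(grepl("^[0-9]+$", tokens))) {
      abort(sprintf("Line %d: non-numeric genotype token.", i))
    }
    w <- unique(nchar(tokens))
    if (length(w) != 1L || !(w %in% c(4L, 6L))) {
      abort(sprintf(
        "Line %d: genotype tokens must all be 4 (2-digit) or 6 (3-digit) characters.",
        i
      ))
    }
    d <- w / 2L
    if (is.null(digits)) {
      digits <- d
    } else if (d != digits) {
      abort(sprintf("Line %d: inconsistent allele width.", i))
    }
    a1 <- as.integer(substr(tokens, 1, d))
    a2 <- as.integer(substr(tokens, d + 1, 2 * d))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    pid <- pop_id[i]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pop_index = pid, individual = name, locus = loci,
      allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2)
    )
    pop_members[[as.character(pid)]] <- name
  }
  if (length(rows) == 0L) abort("Genepop file contains no individuals.")
  out <- dplyr::bind_rows(rows)
  pop_name <- vapply(pop_members, function(last) {
    sub("_[^_]*$", "", last)
  }, character(1))
  out$population <- unname(pop_name[as.character(out$pop_index)])
  dplyr::select(out, "population", "individual", "locus",
                "allele_1", "allele_2")
}

#' Write a Genepop file
#'
#' Canonical 3-digit dialect by default; missing calls render as all-zero
#' tokens. Allele codes that do not fit the chosen width are an error
#' naming the locus and allele.
#'
#' @inheritParams allele_frequencies
#' @param path Output file.
#' @param digits Allele code width, 2 or 3 (default 3: SSR fragment sizes
#'   exceed 99).
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, path, digits = 3,
                          title = "sagisou genotype export") {
  assert_genotype_tibble(genotypes)
  if (!digits %in% c(2, 3)) abort("`digits` must be 2 or 3.")
  maxcode <- 10^digits - 1
  over <- !is.na(genotypes$allele_1) &
    (genotypes$allele_1 > maxcode | genotypes$allele_2 > maxcode)
  if (any(over)) {
    bad <- genotypes[which(over)[1], ]
    abort(sprintf(
      "Allele %d at locus %s does not fit in %d digits.",
      max(bad$allele_1, bad$allele_2), bad$locus, digits
    ))
  }
  loci <- unique(genotypes$locus)
  pops <- unique(genotypes$population)
  fmt <- sprintf("%%0%dd%%0%dd", digits, digits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  for (p in pops) {
    writeLines("Pop", con)
    g <- genotypes[genotypes$population == p, ]
    for (ind in unique(g$individual)) {
      d <- g[g$individual == ind, ]
      d <- d[match(loci, d$locus), ]
      tok <- ifelse(
        is.na(d$allele_1),
        sprintf(fmt, 0L, 0L),
        sprintf(fmt, d$allele_1, d$allele_2)
      )
      writeLines(paste0(ind, " ,  ", paste(tok, collapse = " ")), con)
    }
  }
  invisible(path)
}
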