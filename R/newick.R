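# Newick serialization with fixed-precision branch lengths and integer
# bootstrap supports as internal node labels.

quote_newick_label <- function(x) {
  needs <- grepl("[][ ,:;()']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree to a Newick string
#'
#' Branch lengths are written with 6 decimals and internal node labels
#' (e.g. bootstrap supports) as-is; labels containing spaces or other
#' Newick metacharacters are single-quoted per the Newick convention.
#'
#' @param tree A `phylo` tree.
#' @param digits Decimals for branch lengths (default 6).
#' @return A single Newick string (terminated by `;`).
#' @export
newick_string <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  tips <- quote_newick_label(tree$tip.label)
  node_lab <- tree$node.label %||% rep("", tree$Nnode)
  node_lab[is.na(node_lab)] <- ""
  fmt <- paste0("%.", digits, "f")
  recurse <- function(node) {
    if (node <= n) return(tips[node])
    parts <- vapply(kids[[as.character(node)]], function(e) {
      child <- tree$edge[e, 2]
      sub <- recurse(child)
      if (!is.null(tree$edge.length)) {
        paste0(sub, ":", sprintf(fmt, tree$edge.length[e]))
      } else {
        sub
      }
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")",
           quote_newick_label(node_lab[node - n]))
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  paste0(recurse(root), ";")
}

#' Write a tree to a Newick file
#'
#' @inheritParams newick_string
#' @param path Output file.
#' @return `path`, invisibly. The file round-trips through
#'   [read_newick()] to an isomorphic tree with branch lengths equal to
#'   the written precision.
#' @export
write_newick <- function(tree, path, digits = 6) {
  writeLines(newick_string(tree, digits = digits), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()], additionally supporting single-quoted labels
#' (quotes are resolved before parsing and the verbatim labels restored).
#'
#' @param path Newick file (or use `text`).
#' @param text Newick string instead of a file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  txt <- text %||% paste(readLines(path, warn = FALSE), collapse = "")
  # protect quoted labels from the parser
  stash <- character(0)
  repeat {
    m <- regexpr("'([^']|'')*'", txt)
    if (m == -1L) break
    raw <- regmatches(txt, m)
    lab <- gsub("''", "'", substr(raw, 2, nchar(raw) - 1))
    stash <- c(stash, lab)
    placeholder <- sprintf("SAGISOUQ%dQ", length(stash))
    regmatches(txt, m) <- placeholder
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort("Could not parse Newick input.")
  restore <- function(x) {
    hit <- regmatches(x, regexpr("^SAGISOUQ([0-9]+)Q$", x))
    for (i in seq_along(x)) {
      mm <- regmatches(x[i], regexec("^SAGISOUQ([0-9]+)Q$", x[i]))[[1]]
      if (length(mm) == 2L) x[i] <- stash[as.integer(mm[2])]
    }
    x
  }
  tree$tip.label <- restore(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- restore(tree$node.label)
  tree
}
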