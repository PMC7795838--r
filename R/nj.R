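# Neighbor-joining tree construction and locus-bootstrap supports.

as_dist_matrix <- function(dm) {
  m <- unclass(dm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Distance input must be a square matrix.")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("u", seq_len(nrow(m)))
  }
  if (any(!is.finite(m))) abort("Distances must be finite.")
  if (max(abs(m - t(m))) > 1e-12) abort("Distance matrix must be symmetric.")
  if (any(m < 0)) abort("Distances must be non-negative.")
  storage.mode(m) <- "double"
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q_ij = (n - 2) d_ij - r_i - r_j` and the usual two-point branch-length
#' formulas; negative estimated branch lengths are clamped to zero. Ties in
#' Q are broken deterministically by taking the first minimal pair in
#' column-major order of the active matrix, so the result is reproducible
#' given the input label order.
#'
#' @param dm Symmetric distance matrix with labels (e.g. a
#'   [nei_standard_distance()] result); at least 3 units.
#' @return An unrooted `phylo` tree (tips = matrix labels).
#' @export
neighbor_joining <- function(dm) {
  D <- as_dist_matrix(dm)
  n <- nrow(D)
  if (n < 3L) abort("Neighbor-joining needs at least 3 units.")
  labels <- rownames(D)
  # active node ids in ape convention: tips 1..n, internals from n+1
  active <- seq_len(n)
  next_id <- n + 1L
  edge <- matrix(0L, 0, 2)
  length_of <- numeric(0) # parallel to edge rows
  add_edge <- function(parent, child, len) {
    edge <<- rbind(edge, c(parent, child))
    length_of <<- c(length_of, max(0, len))
  }
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- ij[1]; j <- ij[2]
    dij <- D[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, active[i], vi)
    add_edge(u, active[j], vj)
    duk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    active <- c(active[keep], u)
  }
  # final three nodes join at the unrooted center
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  u <- next_id
  add_edge(u, active[1], (dab + dac - dbc) / 2)
  add_edge(u, active[2], (dab + dbc - dac) / 2)
  add_edge(u, active[3], (dac + dbc - dab) / 2)

  # renumber internals in preorder from the center so ape sees a canonical
  # cladewise tree with root n+1
  n_internal <- u - n
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  new_id <- integer(u)
  new_id[seq_len(n)] <- seq_len(n)
  order_edges <- integer(0)
  counter <- n
  visit <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      order_edges <<- c(order_edges, e)
      child <- edge[e, 2]
      if (child > n) visit(child)
    }
  }
  visit(u)
  phy <- list(
    edge = cbind(new_id[edge[order_edges, 1]], new_id[edge[order_edges, 2]]),
    edge.length = length_of[order_edges],
    tip.label = labels,
    Nnode = n_internal
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# Canonical bipartition keys for the internal nodes of an unrooted phylo.
# The side not containing the alphabetically first tip label identifies
# each split; the trivial all-tips split maps to NA.
bipartition_keys <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  ref <- sort(labs)[1]
  vapply(seq_along(parts), function(i) {
    side <- labs[parts[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) == 0L) return(NA_character_) # trivial all-tips split
    paste(sort(side), collapse = "\r")
  }, character(1))
}

#' Neighbor-joining tree with locus-bootstrap supports
#'
#' Builds the full-data Nei-distance NJ tree, then resamples loci with
#' replacement (same locus count) `replicates` times, recomputing distances
#' and the NJ tree per replicate. The support of each internal edge of the
#' original tree is the percentage of replicate trees containing the same
#' bipartition. Replicates with undefined distances (a pair sharing no
#' typed locus or no alleles) are redrawn, up to 10x `replicates` redraws.
#'
#' @inheritParams nei_standard_distance
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param support_display_threshold Percentage below which supports are
#'   hidden when plotting (they are always retained in the data model).
#' @return A `phylo` tree whose `node.label` holds integer percentage
#'   supports ("" on the trivial central node); attributes `bootstrap`
#'   (tibble of node/support), `replicates`, `redraws`,
#'   `support_display_threshold`.
#' @export
bootstrap_tree <- function(genotypes, unit = c("individual", "population"),
                           replicates = 1000, seed = 1L,
                           support_display_threshold = 50, cap = NULL) {
  unit <- match.arg(unit)
  if (replicates < 1) abort("`replicates` must be >= 1.")
  cache <- nei_cache(genotypes, unit)
  if (cache$L < 2L && replicates > 1L) {
    # resampling a single locus always returns the same distances
  }
  D0 <- nei_from_cache(cache, rep(1, cache$L), cap = cap)
  if (is.null(D0)) {
    abort("Full-data Nei distances are undefined for some pair; supply `cap`.")
  }
  dimnames(D0) <- list(cache$labels, cache$labels)
  tree <- neighbor_joining(D0)
  keys0 <- bipartition_keys(tree)
  counts <- setNames(rep(0L, length(keys0)), seq_along(keys0))
  redraws <- 0L
  with_seed(derive_seed(seed, "bootstrap"), {
    b <- 0L
    while (b < replicates) {
      w <- tabulate(sample.int(cache$L, cache$L, replace = TRUE), cache$L)
      Db <- nei_from_cache(cache, w, cap = cap)
      if (is.null(Db)) {
        redraws <- redraws + 1L
        if (redraws > 10L * replicates) {
          abort("Too many bootstrap replicates with undefined distances; supply `cap` or more loci.")
        }
        next
      }
      bt <- neighbor_joining(Db)
      bk <- bipartition_keys(bt)
      hit <- keys0 %in% bk[!is.na(bk)]
      counts[hit] <- counts[hit] + 1L
      b <- b + 1L
    }
  })
  support <- ifelse(is.na(keys0), NA_real_, 100 * counts / replicates)
  tree$node.label <- ifelse(is.na(support), "",
                            as.character(as.integer(round(support))))
  attr(tree, "bootstrap") <- tibble::tibble(
    node = length(tree$tip.label) + seq_along(support),
    support = support
  )
  attr(tree, "replicates") <- replicates
  attr(tree, "redraws") <- redraws
  attr(tree, "support_display_threshold") <- support_display_threshold
  tree
}

#' Plot a bootstrap NJ tree
#'
#' Thin wrapper over [ape::plot.phylo()] that draws internal-edge supports
#' at or above the display threshold (Fig-3 style: supports below the
#' threshold are suppressed at rendering only).
#'
#' @param tree A [bootstrap_tree()] result.
#' @param support_display_threshold Percentage threshold; defaults to the
#'   one stored on the tree (50 if absent).
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_tree <- function(tree, support_display_threshold = NULL, ...) {
  thr <- support_display_threshold %||%
    attr(tree, "support_display_threshold") %||% 50
  ape::plot.phylo(tree, type = "unrooted", ...)
  bs <- attr(tree, "bootstrap")
  if (!is.null(bs)) {
    show <- !is.na(bs$support) & bs$support >= thr
    if (any(show)) {
      ape::nodelabels(
        text = as.character(as.integer(round(bs$support[show]))),
        node = bs$node[show], frame = "none", adj = c(1.1, -0.3), cex = 0.8
      )
    }
  }
  invisible(tree)
}
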