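# Neighbour-joining phylogeny of V genes with bootstrap support.
#
# The NJ itself is implemented here so that tie-breaking (lexicographic
# taxon pair in the Q matrix) and the negative-branch policy (clamp to zero,
# transfer the deficit to the sister branch at the same join) are explicit
# and deterministic; ape::nj serves as an independent cross-check in the
# test suite. Distances: p-distance (aa or nt) with pairwise deletion of
# ambiguous sites, or Kimura 2-parameter (nt) with optional gamma rate
# correction via ape::dist.dna.

aln_to_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (methods::is(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.character(alignment)) {
    if (is.null(names(alignment))) abort("alignment sequences must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) {
      abort("alignment columns must be of equal length across taxa")
    }
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
    return(m)
  }
  abort("alignment must be a named character vector, XStringSet or matrix")
}

is_nt_alignment <- function(m) {
  mean(m %in% c("A", "C", "G", "T", "U", "N", "-")) > 0.9
}

#' Pairwise p-distances with pairwise deletion
#'
#' Proportion of differing sites among the sites where both sequences carry
#' an unambiguous residue (gaps, `N`/`X`/`?`/`*` are deleted pairwise).
#'
#' @param alignment named character vector (or matrix/XStringSet) of
#'   equal-length aligned sequences, nucleotide or amino acid.
#' @return a symmetric distance matrix.
#' @export
p_distance <- function(alignment) {
  m <- aln_to_matrix(alignment)
  ambiguous <- if (is_nt_alignment(m)) c("N", "-", "?") else
    c("X", "-", "?", "*")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      keep <- !(m[i, ] %in% ambiguous) & !(m[j, ] %in% ambiguous)
      d[i, j] <- d[j, i] <- if (!any(keep)) NA_real_ else
        mean(m[i, keep] != m[j, keep])
    }
  }
  d
}

k2p_distance <- function(alignment, shape = NULL) {
  m <- aln_to_matrix(alignment)
  if (!is_nt_alignment(m)) abort("K2P distances require a nucleotide alignment")
  bin <- ape::as.DNAbin(m)
  gamma <- if (is.null(shape)) FALSE else shape
  d <- as.matrix(ape::dist.dna(bin, model = "K80", gamma = gamma,
                               pairwise.deletion = TRUE))
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    abort(sprintf("K2P distance undefined (saturated) for pair %s / %s",
                  rownames(d)[bad[[1]]], colnames(d)[bad[[2]]]))
  }
  d
}

# classic NJ on a distance matrix; lexicographic tie-break on the pair of
# current node labels; negative branch lengths clamped at each join with
# the deficit transferred to the sister branch
nj_from_dist <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) abort("NJ needs at least 3 taxa")
  n_tip <- n
  # ape edge bookkeeping
  node_ids <- seq_len(n_tip)          # current working nodes -> phylo ids
  next_internal <- 2L * n_tip - 2L    # root gets n_tip + 1 at the end
  edges <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  active <- seq_len(n)
  D <- d
  lab <- labels
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, as.integer(c(parent, child)))
    edge_len <<- c(edge_len, len)
  }
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (length(active) > 3) {
    nn <- length(active)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(lab[ij[1]], lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- D[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (nn - 2))
    lj <- D[i, j] - li
    lens <- clamp_pair(li, lj)
    u_id <- next_internal
    next_internal <- next_internal - 1L
    add_edge(u_id, node_ids[[i]], lens[[1]])
    add_edge(u_id, node_ids[[j]], lens[[2]])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    new_lab <- paste0("(", paste(sort(c(lab[[i]], lab[[j]])),
                                 collapse = ","), ")")
    lab <- c(lab[keep], new_lab)
    rownames(D) <- colnames(D) <- lab
    node_ids <- c(node_ids[keep], u_id)
    active <- seq_len(nn - 1)
  }
  # final 3-star joined at the root
  root <- n_tip + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (k in 1:3) {
    lk <- c(l1, l2, l3)[[k]]
    add_edge(root, node_ids[[k]], max(lk, 0))
  }
  phy <- list(edge = edges, edge.length = edge_len,
              tip.label = labels, Nnode = n_tip - 2L)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

tree_distance <- function(alignment, model, shape) {
  switch(model,
    "p" = p_distance(alignment),
    "k2p" = k2p_distance(alignment, shape = NULL),
    "k2p-gamma" = k2p_distance(alignment, shape = shape)
  )
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds an unrooted NJ tree from an alignment (or directly from a
#' distance matrix) and, optionally, computes bootstrap support by
#' resampling alignment columns with replacement. Support values are the
#' percentage of replicates containing each internal bipartition and are
#' stored in `node.label`. Deterministic given `seed`.
#'
#' @param alignment named character vector, `XStringSet` or character
#'   matrix of equal-length aligned sequences; alternatively a symmetric
#'   distance matrix (then `model` is ignored and bootstrap is
#'   unavailable).
#' @param model `"p"` (p-distance, aa or nt), `"k2p"` or `"k2p-gamma"`
#'   (nt only).
#' @param shape gamma shape parameter for `"k2p-gamma"`.
#' @param n_bootstrap number of bootstrap replicates (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return an [ape::phylo] object of class `c("tr_nj", "phylo")` with
#'   `node.label` holding bootstrap percentages (`NA` for the root when no
#'   bootstrap was run).
#' @export
tr_nj_tree <- function(alignment, model = c("p", "k2p", "k2p-gamma"),
                       shape = 5, n_bootstrap = 0L, seed = 1L) {
  model <- match.arg(model)
  from_dist <- is.matrix(alignment) && is.numeric(alignment) &&
    nrow(alignment) == ncol(alignment) && isSymmetric(unname(alignment))
  if (from_dist) {
    d <- alignment
    if (is.null(rownames(d))) abort("distance matrix must have row names")
    aln <- NULL
  } else {
    aln <- aln_to_matrix(alignment)
    if (nrow(aln) < 3) abort("NJ needs at least 3 taxa")
    d <- tree_distance(aln, model, shape)
  }
  phy <- nj_from_dist(d)
  if (n_bootstrap > 0) {
    if (is.null(aln)) abort("bootstrap requires an alignment, not a distance matrix")
    reps <- with_seed(seed, {
      lapply(seq_len(n_bootstrap), function(b) {
        cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
        nj_from_dist(tree_distance(aln[, cols, drop = FALSE], model, shape))
      })
    })
    counts <- ape::prop.clades(phy, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- round(100 * counts / n_bootstrap)
    support[1] <- NA  # root of the unrooted representation
    phy$node.label <- as.character(support)
  }
  attr(phy, "model") <- model
  attr(phy, "n_bootstrap") <- as.integer(n_bootstrap)
  class(phy) <- c("tr_nj", "phylo")
  phy
}

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an NJ tree into an edge table
#'
#' @param x a `tr_nj` tree.
#' @param ... unused.
#' @return a tibble with one row per edge: `parent`, `node`, `length`,
#'   `tip_label` (for edges ending in a tip) and `support` (bootstrap
#'   percentage of the child node, internal edges only).
#' @export
tidy.tr_nj <- function(x, ...) {
  n_tip <- length(x$tip.label)
  support <- rep(NA_real_, n_tip + x$Nnode)
  if (!is.null(x$node.label)) {
    support[n_tip + seq_len(x$Nnode)] <-
      suppressWarnings(as.numeric(x$node.label))
  }
  tibble(
    parent = x$edge[, 1],
    node = x$edge[, 2],
    length = x$edge.length,
    tip_label = ifelse(x$edge[, 2] <= n_tip, x$tip.label[x$edge[, 2]],
                       NA_character_),
    support = support[x$edge[, 2]]
  )
}

#' One-line summary of an NJ tree
#'
#' @param x a `tr_nj` tree.
#' @param ... unused.
#' @return a one-row tibble: number of taxa, model, bootstrap replicates,
#'   total branch length, minimum bootstrap support.
#' @export
glance.tr_nj <- function(x, ...) {
  sup <- suppressWarnings(as.numeric(x$node.label))
  tibble(
    n_taxa = length(x$tip.label),
    model = attr(x, "model") %||% NA_character_,
    n_bootstrap = attr(x, "n_bootstrap") %||% 0L,
    total_length = sum(x$edge.length),
    min_support = if (length(sup)) suppressWarnings(min(sup, na.rm = TRUE))
      else NA_real_
  )
}
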