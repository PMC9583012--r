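## Neighbor-joining tree construction from K2P distances and
## monophyly-based species-discrimination scoring. Trees are ape
## "phylo" objects throughout; externally inferred trees (e.g. ML
## trees) can be read with ape::read.tree and scored the same way.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`. Ties in Q are
#' broken by the lexicographically smallest `(i, j)` pair over the
#' current node ordering, so the result is deterministic for a given
#' input order. Negative branch-length estimates are clamped to zero in
#' the output (internal distance updates use the unclamped values). On
#' an additive distance matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param dm a `k2p_dist` from [distance_matrix()], or any list with
#'   `accessions` and a symmetric `d` matrix; all pairwise distances
#'   must be defined.
#' @return an unrooted `phylo` object (ape).
#' @export
nj_tree <- function(dm) {
  D <- dm$d
  labels <- dm$accessions
  n <- length(labels)
  if (n < 3L) stopf("need at least 3 accessions for a tree")
  if (any(is.na(D[upper.tri(D)]))) {
    idx <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)[1L, ]
    stopf("undefined distance between '%s' and '%s'",
          labels[idx[1L]], labels[idx[2L]])
  }
  ## node bookkeeping: each active node holds a newick fragment
  frag <- sprintf("'%s'", gsub("'", "", labels))
  active <- seq_len(n)
  Dw <- D
  clamp <- function(x) max(x, 0)
  blen <- function(x) sprintf("%.17g", clamp(x))
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(Dw)
    Q <- (m - 2) * Dw - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- 0.5 * Dw[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dw[i, j] - vi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], blen(vi), frag[j], blen(vj))
    dnew <- 0.5 * (Dw[i, ] + Dw[j, ] - Dw[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    active <- seq_len(m - 1L)
  }
  ## resolve the final three nodes around the central vertex
  la <- (Dw[1, 2] + Dw[1, 3] - Dw[2, 3]) / 2
  lb <- (Dw[1, 2] + Dw[2, 3] - Dw[1, 3]) / 2
  lc <- (Dw[1, 3] + Dw[2, 3] - Dw[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1L], blen(la), frag[2L], blen(lb), frag[3L], blen(lc))
  tree <- ape::read.tree(text = newick)
  ## labels are quoted in the newick fragment (they may contain spaces
  ## or underscores); ape keeps the quotes, so strip them
  tree$tip.label <- sub("^'(.*)'$", "\\1", tree$tip.label)
  tree
}

## Canonical key for the bipartition induced by a leaf subset: the side
## not containing the alphabetically first leaf, sorted and pasted.
split_key <- function(side, all_leaves) {
  ref <- sort(all_leaves)[1L]
  if (ref %in% side) side <- setdiff(all_leaves, side)
  paste(sort(side), collapse = "\r")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One entry per internal edge: the set of leaves on one side of the
#' edge, in canonical form (the side not containing the first leaf).
#'
#' @param tree a `phylo` object.
#' @return character vector of canonical split keys.
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  ## postorder guarantees children are resolved before parents
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- n + 1L
  internal_children <- ord$edge[ord$edge[, 2L] > n, 2L]
  keys <- vapply(internal_children, function(node)
    split_key(desc[[node]], tree$tip.label), "")
  unique(keys[vapply(internal_children, function(node) {
    s <- length(desc[[node]]); s >= 2L && s <= n - 2L
  }, TRUE)])
}

#' Monophyly-based species discrimination score
#'
#' A species is discriminated when all of its accessions form a single
#' clade on some rooting of the tree, i.e. its leaf set is one side of
#' a bipartition (unrooted convention). Species with one accession are
#' trivially monophyletic by convention and are flagged; the default
#' rate counts all species, and the rate restricted to species with
#' >= 2 accessions is reported alongside.
#'
#' @param tree a `phylo` object (NJ from [nj_tree()] or an external ML
#'   tree read with `ape::read.tree`).
#' @param species_of named character vector leaf -> species label.
#' @return object of class `discrimination_score`: list with
#'   `per_species` (data.frame: species, n_accessions, monophyletic,
#'   singleton), `species_total`, `species_monophyletic`, `rate`
#'   (percent, all species), `rate_multi` (percent, species with >= 2
#'   accessions, `NA` when none).
#' @export
monophyly_rate <- function(tree, species_of) {
  leaves <- tree$tip.label
  missing_sp <- setdiff(leaves, names(species_of))
  if (length(missing_sp) > 0L)
    stopf("leaves without species label: %s", paste(missing_sp, collapse = ", "))
  sp <- species_of[leaves]
  keys <- tree_bipartitions(tree)
  n <- length(leaves)
  per <- lapply(unique(sp), function(s) {
    set <- leaves[sp == s]
    mono <- if (length(set) %in% c(1L, n - 1L, n)) TRUE
      else split_key(set, leaves) %in% keys
    data.frame(species = s, n_accessions = length(set),
               monophyletic = mono, singleton = length(set) == 1L)
  })
  per <- do.call(rbind, per)
  multi <- per[!per$singleton, , drop = FALSE]
  structure(list(
    per_species = per,
    species_total = nrow(per),
    species_monophyletic = sum(per$monophyletic),
    rate = 100 * sum(per$monophyletic) / nrow(per),
    rate_multi = if (nrow(multi) == 0L) NA_real_
      else 100 * sum(multi$monophyletic) / nrow(multi)),
    class = "discrimination_score")
}

#' @export
print.discrimination_score <- function(x, ...) {
  cat(sprintf("Species discrimination: %d/%d monophyletic (%.2f%%)\n",
              x$species_monophyletic, x$species_total, x$rate))
  if (!is.na(x$rate_multi))
    cat(sprintf("  restricted to species with >=2 accessions: %.2f%%\n",
                x$rate_multi))
  invisible(x)
}

#' Section-level clustering verdicts
#'
#' The same bipartition machinery as [monophyly_rate()], applied to
#' taxonomic section labels instead of species labels (do the
#' accessions of each section aggregate into one clade?).
#'
#' @param tree a `phylo` object.
#' @param section_of named character vector leaf -> section.
#' @return a `discrimination_score` over sections.
#' @export
section_clustering <- function(tree, section_of) {
  monophyly_rate(tree, section_of)
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P NJ
#' tree for each replicate, and scores each internal edge of the
#' original tree by the percentage of replicates containing the same
#' bipartition. Replicates in which some pairwise distance becomes
#' undefined are dropped and counted.
#'
#' @param aln a [locus_alignment()] with >= 3 accessions.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return list with `tree` (the original NJ `phylo` with `node.label`
#'   holding supports in `[0,100]`; the root label is empty), `support`
#'   (named vector: split key -> support) and `dropped` (failed
#'   replicates).
#' @export
bootstrap_support <- function(aln, replicates = 100L, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (replicates < 1L) stopf("need at least 1 replicate")
  set.seed(seed)
  tree <- nj_tree(distance_matrix(aln))
  keys <- tree_bipartitions(tree)
  hits <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(aln$seqs)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- locus_alignment(aln$seqs[, cols, drop = FALSE], aln$species,
                            aln$locus_name)
    btree <- tryCatch(nj_tree(distance_matrix(baln)), error = function(e) NULL)
    if (is.null(btree)) { dropped <- dropped + 1L; next }
    bk <- tree_bipartitions(btree)
    hits[keys %in% bk] <- hits[keys %in% bk] + 1
  }
  used <- replicates - dropped
  support <- if (used > 0L) 100 * hits / used else hits * NA
  ## attach supports as node labels on the original tree
  n <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  labs <- character(tree$Nnode)
  for (node in (n + 1L):(n + tree$Nnode)) {
    s <- length(desc[[node]])
    if (node == n + 1L || s < 2L || s > n - 2L) { labs[node - n] <- ""; next }
    key <- split_key(desc[[node]], tree$tip.label)
    labs[node - n] <- if (key %in% names(support))
      formatC(support[[key]], format = "fg") else ""
  }
  tree$node.label <- labs
  list(tree = tree, support = support, dropped = dropped)
}
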