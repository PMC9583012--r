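## Shared fixtures and independent oracle implementations. Oracles are
## deliberately written as plain loops, separate from the package code
## paths they check.

## Random aligned sequences with optional gap/N contamination.
random_alignment <- function(n, L, gap_frac = 0, species = NULL,
                             locus = "rand") {
  chars <- sample(c("A", "C", "G", "T"), n * L, replace = TRUE)
  if (gap_frac > 0) {
    k <- rbinom(1, n * L, gap_frac)
    if (k > 0)
      chars[sample.int(n * L, k)] <- sample(c("-", "N"), k, replace = TRUE)
  }
  m <- matrix(chars, nrow = n,
              dimnames = list(sprintf("t%02d", seq_len(n)), NULL))
  if (is.null(species))
    species <- setNames(sprintf("sp%02d", seq_len(n)), rownames(m))
  locus_alignment(m, species, locus)
}

## A small two-species alignment with a clean barcoding gap.
gap_alignment <- function() {
  locus_alignment(
    c(a1 = "AAAAAAAAAAAAAAAAAAAA", a2 = "AAAAAAAAAAAAAAAAAAAA",
      b1 = "GGGGGAAAAAAAAAAAAAAA", b2 = "GGGGGAAAAAAAAAAAAAAA"),
    species = c(a1 = "sp_a", a2 = "sp_a", b1 = "sp_b", b2 = "sp_b"),
    "toy")
}

## Oracle: K2P distance through ape's reference implementation.
oracle_k2p_ape <- function(aln) {
  dna <- ape::as.DNAbin(tolower(aln$seqs))
  as.matrix(ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE))
}

## Oracle: per-pair p-distance and comparable sites by explicit loop.
oracle_pair_counts <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  comp <- 0L; diff <- 0L
  for (s in seq_along(a)) {
    if (a[s] %in% bases && b[s] %in% bases) {
      comp <- comp + 1L
      if (a[s] != b[s]) diff <- diff + 1L
    }
  }
  c(comp = comp, diff = diff)
}

## Oracle: segregating sites by direct column scan.
oracle_segregating <- function(aln) {
  bases <- c("A", "C", "G", "T")
  s <- 0L
  for (j in seq_len(ncol(aln$seqs))) {
    col <- aln$seqs[, j]
    obs <- unique(col[col %in% bases])
    if (length(obs) >= 2L) s <- s + 1L
  }
  s
}

## Oracle: nucleotide diversity by explicit double loop.
oracle_pi <- function(aln) {
  n <- nrow(aln$seqs)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pc <- oracle_pair_counts(aln$seqs[i, ], aln$seqs[j, ])
    if (pc[["comp"]] > 0L) vals <- c(vals, pc[["diff"]] / pc[["comp"]])
  }
  mean(vals)
}

## Oracle: Tajima's D evaluated directly from the 1989 constants on a
## complete (no gap/N) alignment.
oracle_tajima <- function(aln) {
  n <- nrow(aln$seqs)
  S <- oracle_segregating(aln)
  if (S == 0L || n < 4L) return(NA_real_)
  Pi_vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    Pi_vals <- c(Pi_vals, oracle_pair_counts(aln$seqs[i, ], aln$seqs[j, ])[["diff"]])
  Pi <- mean(Pi_vals)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (Pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

## Oracle: best-match verdicts by exhaustive nearest-neighbour scan.
oracle_best_match <- function(dm, species_of, threshold = Inf) {
  acc <- dm$accessions
  out <- character(length(acc))
  for (i in seq_along(acc)) {
    best <- Inf; nn <- character(0)
    for (j in seq_along(acc)) {
      if (i == j || is.na(dm$d[i, j])) next
      if (dm$d[i, j] < best) { best <- dm$d[i, j]; nn <- acc[j] }
      else if (dm$d[i, j] == best) nn <- c(nn, acc[j])
    }
    if (length(nn) == 0L) { out[i] <- "undefined"; next }
    sps <- unique(species_of[nn])
    out[i] <- if (best > threshold) "no_match"
      else if (length(sps) > 1L) "ambiguous"
      else if (sps == species_of[acc[i]]) "correct" else "incorrect"
  }
  setNames(out, acc)
}

## Oracle: species monophyly by rooting at an outside leaf and asking
## ape whether the set is a rooted clade.
oracle_monophyletic <- function(tree, leaf_set) {
  leaves <- tree$tip.label
  if (length(leaf_set) %in% c(1L, length(leaves))) return(TRUE)
  out <- setdiff(leaves, leaf_set)[1L]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, leaf_set)
}

## Oracle: three-predicate site-filter scan.
oracle_filter_keep <- function(gm, max_af, max_miss, max_het) {
  bases <- c("A", "C", "G", "T")
  het <- c("R", "Y", "S", "W", "K", "M")
  keep <- logical(ncol(gm$calls))
  for (j in seq_along(keep)) {
    col <- gm$calls[, j]
    n_miss <- sum(col == "."); n_het <- sum(col %in% het)
    hom <- col[col %in% bases]
    if (length(hom) == 0L) next
    af <- max(table(hom)) / length(hom)
    keep[j] <- af <= max_af &&
      n_miss / length(col) <= max_miss &&
      n_het / (length(col) - n_miss) <= max_het
  }
  keep
}

## Random genotype matrix over a given species design.
random_genotype <- function(n_sites, species = c("A", "B"),
                            acc_per_species = c(4L, 4L),
                            missing_rate = 0.05, het_rate = 0.05) {
  acc <- unlist(lapply(seq_along(species), function(s)
    paste0(species[s], seq_len(acc_per_species[s]))))
  sp <- setNames(rep(species, acc_per_species), acc)
  het <- c("R", "Y", "S", "W", "K", "M")
  pool <- c("A", "C", "G", "T", ".", het)
  prob <- c(rep((1 - missing_rate - het_rate) / 4, 4), missing_rate,
            rep(het_rate / 6, 6))
  calls <- matrix(sample(pool, length(acc) * n_sites, TRUE, prob),
                  nrow = length(acc), dimnames = list(acc, NULL))
  sites <- data.frame(chromosome = "1X", position = seq_len(n_sites),
                      site_id = paste0("1X:", seq_len(n_sites)))
  genotype_matrix(calls, sites, sp)
}
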