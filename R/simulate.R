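## Synthetic multi-species barcode alignments and GBS-like genotype
## matrices with controllable gene flow, for end-to-end testing of the
## discrimination pipeline without external sequence downloads.

#' Configuration for the multi-species barcode simulator
#'
#' Defaults emulate the shape of a genus-wide barcoding survey:
#' 17 species with 2-9 accessions each (84 in total), four loci with
#' aligned lengths 437, 712, 582 and 688 bp, expected intraspecific
#' pairwise divergence 0.002 and interspecific divergence 0.01
#' substitutions/site, transition/transversion rate ratio kappa = 2,
#' and no admixture.
#'
#' @param n_species number of species.
#' @param accessions_per_species integer vector (recycled) of accession
#'   counts per species.
#' @param locus_lengths named integer vector of locus lengths (bp).
#' @param intra_divergence expected pairwise divergence between
#'   conspecific accessions (substitutions/site).
#' @param inter_divergence expected pairwise divergence between
#'   heterospecific accessions; must be >= `intra_divergence`.
#' @param kappa transition/transversion rate ratio (alpha/beta).
#' @param m admixture proportion in `[0, 1]`: per locus, the
#'   probability that an accession's sequence is drawn from a uniformly
#'   chosen other species' lineage (whole-locus horizontal transfer).
#' @param seed integer random seed (mandatory).
#' @return a list of class `species_sim_config`.
#' @export
species_sim_config <- function(
    n_species = 17L,
    accessions_per_species = c(9L, 8L, 7L, 6L, 6L, 6L, 5L, 5L, 5L, 4L, 4L,
                               4L, 4L, 3L, 3L, 3L, 2L),
    locus_lengths = c(ITS2 = 437L, matK = 712L, rbcL = 582L,
                      psbM_petN = 688L),
    intra_divergence = 0.002,
    inter_divergence = 0.01,
    kappa = 2,
    m = 0,
    seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (m < 0 || m > 1) stopf("admixture proportion m must be in [0, 1]")
  if (intra_divergence < 0 || inter_divergence < intra_divergence)
    stopf("need 0 <= intra_divergence <= inter_divergence")
  if (kappa <= 0) stopf("kappa must be positive")
  structure(list(
    n_species = n_species,
    accessions_per_species = rep_len(accessions_per_species, n_species),
    locus_lengths = locus_lengths,
    intra_divergence = intra_divergence,
    inter_divergence = inter_divergence,
    kappa = kappa, m = m, seed = as.integer(seed)),
    class = "species_sim_config")
}

## Evolve each site of `seq` along a branch of expected length t
## (substitutions/site) under the K2P process with rate ratio kappa.
## Rates scaled so alpha + 2*beta = 1.
evolve_k2p <- function(seq, t, kappa) {
  L <- length(seq)
  if (t == 0 || L == 0L) return(seq)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv_each <- 0.25 - 0.25 * exp(-4 * beta * t)
  u <- stats::runif(L)
  out <- seq
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  idx_ts <- u < p_ts
  idx_tv1 <- !idx_ts & u < p_ts + p_tv_each
  idx_tv2 <- !idx_ts & !idx_tv1 & u < p_ts + 2 * p_tv_each
  out[idx_ts] <- ts_partner[seq[idx_ts]]
  out[idx_tv1] <- tv1[seq[idx_tv1]]
  out[idx_tv2] <- tv2[seq[idx_tv2]]
  out
}

#' Simulate multi-species barcode alignments
#'
#' Evolves each locus along a star-of-stars genealogy: a root sequence
#' (uniform bases) diverges into `n_species` species ancestors along
#' branches of length `(inter - intra)/2`, and each accession diverges
#' from its species ancestor along a branch of `intra/2`, under the
#' K2P substitution process, so the expected pairwise divergence is
#' `intra_divergence` within and `inter_divergence` between species
#' (below saturation). With probability `m` an accession's sequence at
#' a locus is instead drawn from a uniformly chosen other species'
#' ancestor (admixture); events are recorded in the `"admixture"`
#' attribute.
#'
#' @param cfg a [species_sim_config()].
#' @return named list of [locus_alignment()] objects, one per locus,
#'   with attributes `"admixture"` (data.frame of events) and
#'   `"config"`.
#' @export
simulate_barcode_alignments <- function(cfg) {
  stopifnot(inherits(cfg, "species_sim_config"))
  set.seed(cfg$seed)
  sp_names <- sprintf("species_%02d", seq_len(cfg$n_species))
  acc_names <- unlist(lapply(seq_len(cfg$n_species), function(s)
    sprintf("%s_acc%d", sp_names[s], seq_len(cfg$accessions_per_species[s]))))
  species <- stats::setNames(
    rep(sp_names, cfg$accessions_per_species), acc_names)
  b_inter <- (cfg$inter_divergence - cfg$intra_divergence) / 2
  b_intra <- cfg$intra_divergence / 2
  events <- list()
  out <- lapply(names(cfg$locus_lengths), function(locus) {
    L <- cfg$locus_lengths[[locus]]
    root <- sample(BASES, L, replace = TRUE)
    ancestors <- lapply(sp_names, function(s) evolve_k2p(root, b_inter, cfg$kappa))
    names(ancestors) <- sp_names
    seqs <- matrix("N", nrow = length(acc_names), ncol = L,
                   dimnames = list(acc_names, NULL))
    for (a in acc_names) {
      src <- species[[a]]
      if (cfg$m > 0 && stats::runif(1) < cfg$m && cfg$n_species > 1L) {
        src <- sample(setdiff(sp_names, species[[a]]), 1L)
        events[[length(events) + 1L]] <<- data.frame(
          locus = locus, accession = a, donor_species = src)
      }
      seqs[a, ] <- evolve_k2p(ancestors[[src]], b_intra, cfg$kappa)
    }
    locus_alignment(seqs, species, locus)
  })
  names(out) <- names(cfg$locus_lengths)
  attr(out, "admixture") <- if (length(events)) do.call(rbind, events) else
    data.frame(locus = character(0), accession = character(0),
               donor_species = character(0))
  attr(out, "config") <- cfg
  out
}

#' Simulate a neutral coalescent sample
#'
#' Standard Kingman coalescent for `n` haploid sequences with mutation
#' parameter `theta` (= 4Nu per locus): exponential coalescence times,
#' Poisson mutations placed on branches in proportion to length, each
#' at a uniformly chosen site (transition from the ancestral base).
#' Used for calibration checks of the diversity statistics; under
#' neutrality Tajima's D is centred near zero.
#'
#' @param n sample size.
#' @param theta scaled mutation rate per locus.
#' @param L number of sites in the emitted alignment.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [locus_alignment()] with all sequences labeled as one
#'   species.
#' @export
simulate_coalescent_alignment <- function(n, theta, L = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lineages <- lapply(seq_len(n), identity)  # tip index sets
  seqs <- matrix("A", nrow = n, ncol = L,
                 dimnames = list(sprintf("seq_%02d", seq_len(n)), NULL))
  free_sites <- sample.int(L, L)  # shuffled so mutated sites are scattered
  used <- 0L
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  while (length(lineages) > 1L) {
    k <- length(lineages)
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    n_mut <- stats::rpois(1, theta / 2 * k * t_k)
    if (n_mut > 0L) {
      for (mu in seq_len(n_mut)) {
        if (used >= L) break  # finite-sites overflow; exceedingly rare
        used <- used + 1L
        site <- free_sites[used]
        hit <- sample.int(k, 1L)
        tips <- lineages[[hit]]
        seqs[tips, site] <- ts_partner[seqs[tips, site][1L]]
      }
    }
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages <- c(lineages[-pair], list(merged))
  }
  locus_alignment(seqs, stats::setNames(rep("pop", n), rownames(seqs)),
                  "coalescent")
}

#' Simulate a GBS-like genotype matrix with planted diagnostic sites
#'
#' Builds an accessions-by-sites call matrix with three site classes:
#' diagnostic sites carry a private allele in one species (with an
#' optional per-site exception: a third allele in one accession of a
#' non-diagnosed species, leaving the site diagnostic); background
#' sites draw per-species allele frequencies from the Balding-Nichols
#' beta model around a shared ancestral frequency with differentiation
#' `background_fst`, mixed toward the across-species mean by the
#' migration proportion `m`, and are forced to share the global major
#' allele across all species so they are never diagnostic; monomorphic
#' sites are uniform. Missing and heterozygous calls are then injected
#' at the given rates.
#'
#' @param n_diagnostic,n_background,n_monomorphic site counts per class
#'   (defaults emulate a filtered GBS panel: 30 diagnostic + 2378
#'   background = 2408 polymorphic sites).
#' @param species character vector of species names (default 3).
#' @param accessions_per_species integer vector (default `c(5, 3, 6)`).
#' @param background_fst Balding-Nichols differentiation parameter for
#'   background sites, in (0, 1).
#' @param m migration proportion in `[0, 1]` mixing species allele
#'   frequencies toward their mean (0 = none, 1 = panmixia).
#' @param exception_rate per-diagnostic-site probability of a
#'   third-allele exception.
#' @param missing_rate,het_rate per-call injection rates of missing and
#'   heterozygous codes (applied to background and monomorphic sites;
#'   diagnostic sites stay clean so the planted truth is exact).
#' @param seed integer seed (mandatory).
#' @return list with `genotype` (a [genotype_matrix()]) and `truth`
#'   (data.frame: site_id, class, diagnosed_species).
#' @export
simulate_genotype_matrix <- function(n_diagnostic = 30L,
                                     n_background = 2378L,
                                     n_monomorphic = 0L,
                                     species = c("species_A", "species_B",
                                                 "species_C"),
                                     accessions_per_species = c(5L, 3L, 6L),
                                     background_fst = 0.13,
                                     m = 0,
                                     exception_rate = 0,
                                     missing_rate = 0,
                                     het_rate = 0,
                                     seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (any(c(n_diagnostic, n_background, n_monomorphic) < 0))
    stopf("site counts must be >= 0")
  if (m < 0 || m > 1) stopf("m must be in [0, 1]")
  set.seed(seed)
  accessions_per_species <- rep_len(accessions_per_species, length(species))
  acc <- unlist(lapply(seq_along(species), function(s)
    sprintf("%s_acc%d", species[s], seq_len(accessions_per_species[s]))))
  sp_of <- stats::setNames(rep(species, accessions_per_species), acc)
  n_acc <- length(acc)
  n_sites <- n_diagnostic + n_background + n_monomorphic
  calls <- matrix(".", nrow = n_acc, ncol = n_sites,
                  dimnames = list(acc, NULL))
  truth <- data.frame(site_id = sprintf("sim:%d", seq_len(n_sites)),
                      class = rep(c("diagnostic", "background", "monomorphic"),
                                  c(n_diagnostic, n_background, n_monomorphic)),
                      diagnosed_species = NA_character_)
  j <- 0L
  for (k in seq_len(n_diagnostic)) {
    j <- j + 1L
    target <- sample(species, 1L)
    pair <- sample(BASES, 2L)
    col <- ifelse(sp_of == target, pair[1L], pair[2L])
    if (exception_rate > 0 && stats::runif(1) < exception_rate) {
      third <- sample(setdiff(BASES, pair), 1L)
      cand <- which(sp_of != target)
      col[sample(cand, 1L)] <- third
    }
    calls[, j] <- col
    truth$diagnosed_species[j] <- target
  }
  for (k in seq_len(n_background)) {
    j <- j + 1L
    pair <- sample(BASES, 2L)
    p0 <- stats::runif(1, 0.1, 0.9)
    fbg <- background_fst
    p_s <- stats::rbeta(length(species), p0 * (1 - fbg) / fbg,
                        (1 - p0) * (1 - fbg) / fbg)
    p_s <- (1 - m) * p_s + m * mean(p_s)
    col <- character(n_acc)
    for (s in seq_along(species)) {
      idx <- which(sp_of == species[s])
      col[idx] <- ifelse(stats::runif(length(idx)) < p_s[s], pair[1L], pair[2L])
    }
    ## force the global major allele into every species so the site can
    ## never satisfy the diagnostic disjointness rule
    major <- names(which.max(table(col)))
    for (s in species) col[which(sp_of == s)[1L]] <- major
    calls[, j] <- col
  }
  if (n_monomorphic > 0L) {
    for (k in seq_len(n_monomorphic)) {
      j <- j + 1L
      calls[, j] <- sample(BASES, 1L)
    }
  }
  ## noise injection on non-diagnostic sites
  if ((missing_rate > 0 || het_rate > 0) && n_sites > n_diagnostic) {
    cols <- (n_diagnostic + 1L):n_sites
    for (jj in cols) {
      for (i in seq_len(n_acc)) {
        u <- stats::runif(1)
        if (u < missing_rate) {
          calls[i, jj] <- "."
        } else if (u < missing_rate + het_rate) {
          other <- sample(setdiff(BASES, calls[i, jj]), 1L)
          calls[i, jj] <- iupac_from_pair(calls[i, jj], other)
        }
      }
    }
  }
  sites <- data.frame(chromosome = "sim",
                      position = seq_len(n_sites),
                      site_id = truth$site_id)
  list(genotype = genotype_matrix(calls, sites, sp_of), truth = truth)
}
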