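## Pairwise Fst between species from a genotype matrix, treating GBS
## calls as haploid alleles (inbred, homozygote-coded accessions).
## Heterozygous calls are excluded at that accession and locus.

## Per-locus allele frequency table for one species (haploid calls).
species_freqs <- function(calls) {
  hom <- calls[calls %in% BASES]
  if (length(hom) == 0L) return(NULL)
  tab <- table(factor(hom, levels = BASES))
  list(n = length(hom), p = as.numeric(tab) / length(hom))
}

#' Pairwise Fst between two species
#'
#' Per-locus and multi-locus Fst from haploid allele frequencies, with
#' either the Nei Gst estimator (`Fst = (Ht - Hs)/Ht`, where `Ht` is
#' the expected heterozygosity of the unweighted pooled allele
#' frequencies and `Hs` the mean within-species expected
#' heterozygosity) or the Weir-Cockerham theta variance-components
#' estimator for haploid data. Multi-locus values combine loci by ratio
#' of sums (the mean of per-locus ratios is also reported). Loci where
#' the estimator is undefined (no calls in a species, or `Ht = 0`) are
#' excluded and counted.
#'
#' Values in (0.05, 0.15) are conventionally read as small/moderate
#' differentiation.
#'
#' @param gm a [genotype_matrix()].
#' @param species_a,species_b the two species labels.
#' @param estimator `"nei_gst"` or `"weir_cockerham"`.
#' @return object of class `fst_result`: list with `pair`, `estimator`,
#'   `per_locus` (named numeric, raw values, may be negative for
#'   weir_cockerham), `fst` (multi-locus, ratio of sums, clamped to
#'   `[0,1]`), `fst_raw`, `fst_mean_of_ratios`, `loci_used`,
#'   `loci_undefined`.
#' @export
pairwise_fst <- function(gm, species_a, species_b,
                         estimator = c("nei_gst", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  acc_a <- gm$accessions[gm$species == species_a]
  acc_b <- gm$accessions[gm$species == species_b]
  if (length(acc_a) == 0L || length(acc_b) == 0L)
    stopf("species not present in the genotype matrix")
  per_num <- per_den <- per <- numeric(0)
  undefined <- 0L
  for (j in seq_len(ncol(gm$calls))) {
    fa <- species_freqs(gm$calls[acc_a, j])
    fb <- species_freqs(gm$calls[acc_b, j])
    if (is.null(fa) || is.null(fb)) { undefined <- undefined + 1L; next }
    if (estimator == "nei_gst") {
      pbar <- (fa$p + fb$p) / 2
      Ht <- 1 - sum(pbar^2)
      Hs <- mean(c(1 - sum(fa$p^2), 1 - sum(fb$p^2)))
      if (Ht <= 0) { undefined <- undefined + 1L; next }
      num <- Ht - Hs; den <- Ht
    } else {
      n1 <- fa$n; n2 <- fb$n; r <- 2
      nbar <- (n1 + n2) / r
      nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
      pw <- (n1 * fa$p + n2 * fb$p) / (n1 + n2)
      MSP <- (n1 * (fa$p - pw)^2 + n2 * (fb$p - pw)^2) / (r - 1)
      MSG <- if (n1 + n2 - r > 0)
        (n1 * fa$p * (1 - fa$p) + n2 * fb$p * (1 - fb$p)) / (n1 + n2 - r)
      else rep(0, length(pw))
      num <- sum(MSP - MSG)
      den <- sum(MSP + (nc - 1) * MSG)
      if (den <= 0) { undefined <- undefined + 1L; next }
    }
    per_num <- c(per_num, num); per_den <- c(per_den, den)
    per <- c(per, stats::setNames(num / den, gm$sites$site_id[j]))
  }
  if (length(per) == 0L)
    stopf("Fst undefined at every locus for %s vs %s", species_a, species_b)
  fst_raw <- sum(per_num) / sum(per_den)
  structure(list(pair = c(species_a, species_b), estimator = estimator,
                 per_locus = per, fst = min(max(fst_raw, 0), 1),
                 fst_raw = fst_raw, fst_mean_of_ratios = mean(per),
                 loci_used = length(per), loci_undefined = undefined),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  lab <- if (x$fst > 0.05 && x$fst < 0.15) " (small/moderate differentiation)"
    else ""
  cat(sprintf("Fst[%s] %s vs %s = %.3f over %d loci%s\n", x$estimator,
              x$pair[1L], x$pair[2L], x$fst, x$loci_used, lab))
  invisible(x)
}

#' Pairwise Fst matrix over all species pairs
#' @param gm a [genotype_matrix()].
#' @param estimator passed to [pairwise_fst()].
#' @return data.frame with one row per species pair: `species_a`,
#'   `species_b`, `fst`, `loci_used`.
#' @export
fst_matrix <- function(gm, estimator = "nei_gst") {
  sps <- unique(unname(gm$species))
  if (length(sps) < 2L) stopf("need at least 2 species")
  pairs <- utils::combn(sps, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    f <- pairwise_fst(gm, pairs[1L, k], pairs[2L, k], estimator)
    data.frame(species_a = pairs[1L, k], species_b = pairs[2L, k],
               fst = f$fst, loci_used = f$loci_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Island-model gene-flow equivalent of an Fst value
#'
#' The naive Wright island-model equilibrium identity
#' `Nm = (1 - Fst) / (4 Fst)`. This is a back-of-envelope diagnostic
#' for how much gene flow would produce the observed differentiation at
#' equilibrium; it is not a coalescent-based migration estimate.
#'
#' @param fst an Fst value in (0, 1), or an `fst_result`.
#' @return effective number of migrants Nm (`NA` for Fst of exactly 0
#'   or 1).
#' @export
fst_migration_consistency <- function(fst) {
  if (inherits(fst, "fst_result")) fst <- fst$fst
  if (is.na(fst) || fst <= 0 || fst >= 1) return(NA_real_)
  (1 - fst) / (4 * fst)
}
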