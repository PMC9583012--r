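## GBS site statistics, Tassel-style site filtering, and construction
## of a species-diagnostic SNP key with sample classification.

#' Per-site allele statistics
#'
#' For each SNP site: distinct alleles in descending frequency order,
#' the major allele and its frequency, the missing fraction and the
#' heterozygous fraction. Allele counts are taken over non-missing,
#' non-ambiguous calls; the heterozygous fraction is the share of IUPAC
#' ambiguity calls among non-missing calls; the missing fraction is
#' over all accessions. Sites with no usable calls get `NA` statistics.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with one row per site: `site_id`, `chromosome`,
#'   `position`, `alleles` (slash-joined, frequency order),
#'   `major_allele`, `major_allele_freq`, `missing_frac`, `het_frac`,
#'   `n_called`.
#' @export
site_stats <- function(gm) {
  n_acc <- length(gm$accessions)
  if (n_acc < 1L) stopf("need at least 1 accession")
  rows <- lapply(seq_len(ncol(gm$calls)), function(j) {
    calls <- gm$calls[, j]
    n_missing <- sum(calls == ".")
    n_het <- sum(is_het_call(calls))
    hom <- calls[calls %in% BASES]
    if (length(hom) == 0L) {
      return(data.frame(site_id = gm$sites$site_id[j],
                        chromosome = gm$sites$chromosome[j],
                        position = gm$sites$position[j],
                        alleles = NA_character_, major_allele = NA_character_,
                        major_allele_freq = NA_real_,
                        missing_frac = n_missing / n_acc,
                        het_frac = if (n_acc - n_missing > 0)
                          n_het / (n_acc - n_missing) else NA_real_,
                        n_called = 0L))
    }
    counts <- sort(table(hom), decreasing = TRUE)
    data.frame(site_id = gm$sites$site_id[j],
               chromosome = gm$sites$chromosome[j],
               position = gm$sites$position[j],
               alleles = paste(names(counts), collapse = "/"),
               major_allele = names(counts)[1L],
               major_allele_freq = as.numeric(counts[1L]) / length(hom),
               missing_frac = n_missing / n_acc,
               het_frac = n_het / (n_acc - n_missing),
               n_called = length(hom))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter SNP sites on frequency, missingness and heterozygosity
#'
#' Tassel-style site filter: retain sites whose major allele frequency,
#' missing fraction and heterozygous fraction do not exceed the given
#' thresholds (defaults as used for GBS quality control: 0.95, 0.05,
#' 0.20). Sites with undefined statistics are removed. The accession
#' set is unchanged and the filter is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param max_major_af maximum major allele frequency.
#' @param max_missing maximum fraction of missing calls.
#' @param max_het maximum fraction of heterozygous calls.
#' @return a [genotype_matrix()] with the retained sites, with a
#'   `"filter_summary"` attribute (sites in / out / removed per rule).
#' @export
filter_sites <- function(gm, max_major_af = 0.95, max_missing = 0.05,
                         max_het = 0.20) {
  thr <- c(max_major_af, max_missing, max_het)
  if (any(thr < 0 | thr > 1)) stopf("thresholds must be in [0, 1]")
  st <- site_stats(gm)
  ok_af <- !is.na(st$major_allele_freq) & st$major_allele_freq <= max_major_af
  ok_miss <- st$missing_frac <= max_missing
  ok_het <- !is.na(st$het_frac) & st$het_frac <= max_het
  keep <- ok_af & ok_miss & ok_het
  out <- subset_sites(gm, keep)
  attr(out, "filter_summary") <- data.frame(
    sites_in = nrow(st), sites_out = sum(keep),
    fail_major_af = sum(!ok_af), fail_missing = sum(!ok_miss),
    fail_het = sum(!ok_het, na.rm = TRUE))
  out
}

## Observed allele set per species at one site (het calls expanded to
## both alleles, missing ignored).
species_allele_sets <- function(calls, species) {
  lapply(split(calls, species), function(v) sort(unique(expand_alleles(v))))
}

#' Screen species-diagnostic SNP sites
#'
#' A site is diagnostic when at least one species' observed allele set
#' (over non-missing calls, heterozygous calls expanded to both
#' alleles) is disjoint from the union of all other species' allele
#' sets — that species can then be recognized from this site alone.
#' This is the weakest rule consistent with a printed classification
#' key that allows within-species polymorphism at some sites.
#'
#' @param gm a [genotype_matrix()] with >= 2 species.
#' @param species optional character vector restricting/ordering the
#'   species considered; defaults to all species in `gm`.
#' @return object of class `diagnostic_key`: list with `sites`
#'   (data.frame: site_id, chromosome, position, major_allele_freq,
#'   alleles, diagnoses — comma-joined species separated at that site),
#'   `allele_sets` (per retained site, named list species -> allele
#'   vector), `species`, and `genotype` (the retained sub-matrix).
#' @export
screen_diagnostic <- function(gm, species = NULL) {
  if (is.null(species)) species <- unique(unname(gm$species))
  if (length(species) < 2L) stopf("need at least 2 species")
  keep_acc <- gm$accessions[gm$species %in% species]
  sp <- gm$species[keep_acc]
  st <- site_stats(gm)
  retained <- integer(0)
  diagnoses <- character(0)
  allele_sets <- list()
  for (j in seq_len(ncol(gm$calls))) {
    sets <- species_allele_sets(gm$calls[keep_acc, j], sp)
    sets <- sets[species[species %in% names(sets)]]
    diag_sp <- character(0)
    for (s in names(sets)) {
      others <- unique(unlist(sets[setdiff(names(sets), s)]))
      if (length(sets[[s]]) > 0L && length(intersect(sets[[s]], others)) == 0L)
        diag_sp <- c(diag_sp, s)
    }
    if (length(diag_sp) > 0L) {
      retained <- c(retained, j)
      diagnoses <- c(diagnoses, paste(diag_sp, collapse = ","))
      allele_sets[[gm$sites$site_id[j]]] <- sets
    }
  }
  sites <- data.frame(site_id = gm$sites$site_id[retained],
                      chromosome = gm$sites$chromosome[retained],
                      position = gm$sites$position[retained],
                      major_allele_freq = st$major_allele_freq[retained],
                      alleles = st$alleles[retained],
                      diagnoses = diagnoses)
  structure(list(sites = sites, allele_sets = allele_sets,
                 species = species,
                 genotype = subset_sites(gm, retained)),
            class = "diagnostic_key")
}

#' @export
print.diagnostic_key <- function(x, ...) {
  cat(sprintf("Diagnostic SNP key: %d sites separating %d species (%s)\n",
              nrow(x$sites), length(x$species),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Classify a sample against a diagnostic key
#'
#' Per key site with a non-missing call, every species whose private
#' (diagnostic) allele set contains the called allele receives one
#' vote; the verdict is the species with a plurality of votes, and a
#' tie or zero votes yields `"unclassified"`.
#'
#' @param key a `diagnostic_key` from [screen_diagnostic()].
#' @param calls named character vector site_id -> single-character call
#'   (IUPAC het letters allowed, `.` = missing). Calls at sites absent
#'   from the key are ignored with a warning.
#' @return list with `verdict` (species name or `"unclassified"`),
#'   `votes` (named integer vector per species) and `per_site`
#'   (data.frame: site_id, call, vote).
#' @export
classify_sample <- function(key, calls) {
  unknown <- setdiff(names(calls), key$sites$site_id)
  if (length(unknown) > 0L)
    warning("ignoring calls at sites not in the key: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  votes <- stats::setNames(integer(length(key$species)), key$species)
  rows <- list()
  for (sid in intersect(key$sites$site_id, names(calls))) {
    cc <- calls[[sid]]
    if (is.na(cc) || cc == ".") next
    obs <- expand_alleles(cc)
    diag_sp <- strsplit(key$sites$diagnoses[key$sites$site_id == sid], ",")[[1L]]
    vote <- NA_character_
    for (s in diag_sp) {
      if (any(obs %in% key$allele_sets[[sid]][[s]])) {
        votes[[s]] <- votes[[s]] + 1L
        vote <- s
      }
    }
    rows[[sid]] <- data.frame(site_id = sid, call = cc, vote = vote)
  }
  verdict <- "unclassified"
  if (any(votes > 0L)) {
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) verdict <- top
  }
  list(verdict = verdict, votes = votes,
       per_site = if (length(rows)) do.call(rbind, rows) else
         data.frame(site_id = character(0), call = character(0),
                    vote = character(0)))
}

#' Write a diagnostic key as TSV
#'
#' Serializes the key in the layout of a printed classification table:
#' site number, major allele frequency (5 decimals, ties rounded away
#' from zero), alleles, chromosome, position, then one column of calls
#' per accession.
#'
#' @param key a `diagnostic_key`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagnostic_key <- function(key, path) {
  gm <- key$genotype
  tab <- data.frame(
    no = seq_len(nrow(key$sites)),
    major_allele_freq = formatC(
      round_half_up(key$sites$major_allele_freq, 5), format = "f", digits = 5),
    alleles = key$sites$alleles,
    chromosome = key$sites$chromosome,
    position = key$sites$position,
    t(gm$calls), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
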