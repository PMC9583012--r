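#' Genotype matrix of accessions by SNP sites
#'
#' Container for genotyping-by-sequencing style SNP calls: one
#' single-character call per accession and site, over `A,C,G,T`, the
#' IUPAC ambiguity letters (heterozygous calls) and `.` (missing).
#'
#' @param calls character matrix (accessions x sites) of single-character
#'   calls, with accession rownames and site_id colnames.
#' @param sites data.frame with columns `chromosome`, `position`
#'   (1-based integer) and `site_id`, one row per column of `calls`.
#' @param species named character vector accession -> species.
#' @return an object of class `genotype_matrix`: list with `sites`,
#'   `accessions`, `species`, `calls`.
#' @export
genotype_matrix <- function(calls, sites, species) {
  if (!is.matrix(calls)) stopf("calls must be a matrix")
  acc <- rownames(calls)
  if (is.null(acc) || anyDuplicated(acc)) stopf("duplicate or missing accession identifiers")
  allowed <- c(BASES, names(IUPAC_HET), ".")
  bad <- setdiff(unique(as.vector(calls)), allowed)
  if (length(bad) > 0L)
    stopf("allele characters outside alphabet: %s", paste(bad, collapse = ", "))
  if (!all(c("chromosome", "position", "site_id") %in% names(sites)))
    stopf("sites needs chromosome, position, site_id columns")
  if (nrow(sites) != ncol(calls)) stopf("sites/calls dimension mismatch")
  if (any(sites$position < 0)) stopf("negative site positions")
  missing_sp <- setdiff(acc, names(species))
  if (length(missing_sp) > 0L)
    stopf("accessions without species label: %s",
          paste(missing_sp, collapse = ", "))
  colnames(calls) <- sites$site_id
  structure(
    list(sites = sites, accessions = acc, species = species[acc],
         calls = calls),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d accessions x %d sites, %d species\n",
              length(x$accessions), nrow(x$sites), length(unique(x$species))))
  invisible(x)
}

## Collapse one diploid VCF GT field to a single-character call.
collapse_gt <- function(gt, ref, alt_alleles) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(".")
  idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1L]]))
  if (any(is.na(idx))) return(".")
  alleles <- c(ref, alt_alleles)[idx + 1L]
  if (any(is.na(alleles)) || any(!alleles %in% BASES)) return(".")
  u <- unique(alleles)
  if (length(u) == 1L) u else iupac_from_pair(u[1L], u[2L])
}

#' Read a genotype table from TSV or VCF
#'
#' The TSV dialect has a header row `accession species <site_id...>` and
#' one row per accession; site identifiers are `chromosome:position`.
#' VCF input (read via vcfR) collapses diploid genotypes to one IUPAC
#' character: homozygous calls to the allele letter, heterozygous calls
#' to the ambiguity letter, missing to `.`.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param species_map for VCF input, a named character vector
#'   accession -> species (the TSV dialect carries its own species
#'   column).
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, format = c("tsv", "vcf"),
                                species_map = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE)
    if (!all(c("accession", "species") %in% names(tab)[1:2]))
      stopf("TSV genotype table must start with 'accession' and 'species' columns")
    if (anyDuplicated(tab$accession)) stopf("duplicate accession in genotype table")
    site_ids <- names(tab)[-(1:2)]
    calls <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(calls) <- tab$accession
    parts <- strsplit(site_ids, ":", fixed = TRUE)
    sites <- data.frame(
      chromosome = vapply(parts, `[`, "", 1L),
      position = as.integer(vapply(parts, function(p) p[2L], "")),
      site_id = site_ids)
    genotype_matrix(calls, sites, stats::setNames(tab$species, tab$accession))
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stopf("package 'vcfR' is required for VCF input")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",")
    calls <- matrix(".", nrow = ncol(gt), ncol = nrow(gt),
                    dimnames = list(colnames(gt), NULL))
    for (i in seq_len(nrow(gt)))
      for (j in seq_len(ncol(gt)))
        calls[j, i] <- collapse_gt(gt[i, j], fix[i, "REF"], alt_list[[i]])
    sites <- data.frame(
      chromosome = fix[, "CHROM"],
      position = as.integer(fix[, "POS"]),
      site_id = paste0(fix[, "CHROM"], ":", fix[, "POS"]))
    if (is.null(species_map)) stopf("species_map is required for VCF input")
    genotype_matrix(calls, sites, species_map)
  }
}

#' Write a genotype matrix in the TSV dialect
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  tab <- data.frame(accession = gm$accessions,
                    species = unname(gm$species),
                    gm$calls, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a genotype matrix by site
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over sites.
#' @return a [genotype_matrix()] with the retained sites.
#' @export
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$calls[, keep, drop = FALSE],
                  gm$sites[keep, , drop = FALSE], gm$species)
}

#' The published three-species Aegilops diagnostic SNP table
#'
#' Loads the 30-SNP x 14-accession genotype matrix published as the
#' molecular classification key for *Aegilops biuncialis* (5
#' accessions), *Ae. juvenalis* (3) and *Ae. columnaris* (6), together
#' with the printed major-allele frequencies and allele lists.
#'
#' @return a list with elements `genotype` (a [genotype_matrix()]),
#'   `printed` (data.frame of the printed `major_allele_freq` and
#'   `alleles` columns, one row per site).
#' @export
aegilops_snp_fixture <- function() {
  path <- system.file("extdata", "aegilops_snp_key_table.tsv",
                      package = "barcodekey", mustWork = TRUE)
  map_path <- system.file("extdata", "aegilops_gbs_species_map.tsv",
                          package = "barcodekey", mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  species <- read_species_map(map_path)
  acc <- setdiff(names(tab),
                 c("no", "major_allele_freq", "alleles", "chromosome", "position"))
  calls <- t(as.matrix(tab[, acc, drop = FALSE]))
  sites <- data.frame(chromosome = tab$chromosome,
                      position = as.integer(tab$position),
                      site_id = paste0(tab$chromosome, ":", tab$position))
  colnames(calls) <- sites$site_id
  list(genotype = genotype_matrix(calls, sites, species),
       printed = data.frame(site_id = sites$site_id,
                            major_allele_freq = as.numeric(tab$major_allele_freq),
                            alleles = tab$alleles))
}
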