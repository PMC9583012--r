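#' Aligned barcode locus with species labels
#'
#' Container for one aligned barcode region (e.g. ITS2, matK, rbcL,
#' psbM-petN). Sequences are stored as a character matrix of
#' single upper-case characters over `A,C,G,T,-,N` with one row per
#' accession; every accession carries a species label.
#'
#' @param seqs named character vector of aligned sequence strings, or a
#'   character matrix of single characters with accession rownames.
#' @param species named character vector mapping accession to species;
#'   must cover every accession in `seqs`.
#' @param locus_name name of the barcode region.
#' @return an object of class `locus_alignment`: a list with elements
#'   `locus_name`, `accessions`, `species` (named by accession) and
#'   `seqs` (accessions x sites character matrix).
#' @examples
#' aln <- locus_alignment(
#'   c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC", b1 = "ACGAACGTAC"),
#'   species = c(a1 = "sp_a", a2 = "sp_a", b1 = "sp_b"), "demo")
#' alignment_length(aln)
#' @export
locus_alignment <- function(seqs, species, locus_name = "locus") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stopf("sequences must be named by accession")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stopf("ragged alignment in locus '%s': lengths %s", locus_name,
            paste(unique(lens), collapse = ", "))
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (ncol(m) == 0L) stopf("alignment of length 0 in locus '%s'", locus_name)
  if (anyDuplicated(rownames(m)))
    stopf("duplicate accession identifiers in locus '%s'", locus_name)
  m[] <- toupper(m)
  m[!(m %in% c(BASES, "-", "N"))] <- "N"  # other ambiguity codes -> missing
  acc <- rownames(m)
  missing_sp <- setdiff(acc, names(species))
  if (length(missing_sp) > 0L)
    stopf("accessions without species label: %s",
          paste(missing_sp, collapse = ", "))
  sp <- species[acc]
  if (any(!nzchar(sp) | is.na(sp))) stopf("empty species labels")
  structure(
    list(locus_name = locus_name, accessions = acc, species = sp, seqs = m),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Aligned barcode locus '%s': %d accessions, %d sites, %d species\n",
              x$locus_name, length(x$accessions), ncol(x$seqs),
              length(unique(x$species))))
  invisible(x)
}

#' Number of aligned sites in a locus alignment
#' @param aln a [locus_alignment()].
#' @return integer alignment length.
#' @export
alignment_length <- function(aln) ncol(aln$seqs)

#' Read an aligned FASTA file with species labels
#'
#' Parses an aligned FASTA file (via ape) and attaches species labels.
#' Lower-case bases are canonicalized to upper case; gaps (`-`) and `N`
#' are preserved; any other ambiguity code becomes `N`.
#'
#' @param path path to an aligned FASTA file.
#' @param species_map named character vector accession -> species, e.g.
#'   from [read_species_map()].
#' @param locus_name locus label; defaults to the file name.
#' @return a [locus_alignment()].
#' @export
read_fasta_alignment <- function(path, species_map,
                                 locus_name = sub("\\.[^.]*$", "", basename(path))) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste0(s, collapse = ""), "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stopf("ragged alignment in '%s': record lengths %s", path,
          paste(unique(lens), collapse = ", "))
  locus_alignment(seqs, species_map, locus_name)
}

#' Write a locus alignment as aligned FASTA
#' @param aln a [locus_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1L, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (a in aln$accessions)
    writeLines(c(paste0(">", a), seqs[[a]]), con)
  invisible(path)
}

#' Read a species map
#'
#' Two- or three-column tab-separated table with header
#' `accession<TAB>species[<TAB>section]`.
#'
#' @param path path to the TSV file.
#' @return named character vector accession -> species; if a `section`
#'   column is present it is attached as the `"section"` attribute
#'   (named character vector accession -> section).
#' @export
read_species_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!all(c("accession", "species") %in% names(tab)))
    stopf("species map needs 'accession' and 'species' columns")
  if (anyDuplicated(tab$accession))
    stopf("duplicate accessions in species map")
  out <- stats::setNames(tab$species, tab$accession)
  if ("section" %in% names(tab))
    attr(out, "section") <- stats::setNames(tab$section, tab$accession)
  out
}

#' Concatenate barcode loci into a combined alignment
#'
#' Builds a multi-locus barcode (e.g. ITS2 + matK) over the union of
#' accessions. An accession absent from a locus is padded with `N` over
#' that locus's full length, so distance computations treat the locus as
#' missing data rather than indels. Locus boundaries are recorded in the
#' `"locus_boundaries"` attribute.
#'
#' @param alignments list of [locus_alignment()] objects (>= 1).
#' @param name name for the combined locus; defaults to the
#'   `+`-joined locus names.
#' @return a [locus_alignment()] whose length is the sum of the input
#'   lengths.
#' @export
concatenate_loci <- function(alignments, name = NULL) {
  if (length(alignments) == 0L) stopf("no alignments to concatenate")
  if (is.null(name))
    name <- paste(vapply(alignments, `[[`, "", "locus_name"), collapse = " + ")
  acc <- unique(unlist(lapply(alignments, `[[`, "accessions")))
  species <- stats::setNames(rep(NA_character_, length(acc)), acc)
  for (aln in alignments) species[aln$accessions] <- aln$species
  blocks <- lapply(alignments, function(aln) {
    L <- ncol(aln$seqs)
    m <- matrix("N", nrow = length(acc), ncol = L, dimnames = list(acc, NULL))
    m[aln$accessions, ] <- aln$seqs
    m
  })
  out <- locus_alignment(do.call(cbind, blocks), species, name)
  lens <- vapply(alignments, alignment_length, 0L)
  ends <- cumsum(lens)
  attr(out, "locus_boundaries") <- data.frame(
    locus = vapply(alignments, `[[`, "", "locus_name"),
    start = ends - lens + 1L, end = ends)
  out
}

#' Subset an alignment to chosen accessions
#' @param aln a [locus_alignment()].
#' @param accessions accession identifiers to keep, in the given order.
#' @return a [locus_alignment()].
#' @export
subset_alignment <- function(aln, accessions) {
  bad <- setdiff(accessions, aln$accessions)
  if (length(bad) > 0L)
    stopf("unknown accessions: %s", paste(bad, collapse = ", "))
  locus_alignment(aln$seqs[accessions, , drop = FALSE],
                  aln$species[accessions], aln$locus_name)
}
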