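## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value, the convention
#' used when formatting allele frequencies for the printed SNP key
#' (`round()` in R rounds ties to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Expand a vector of single-character calls into constituent alleles.
## Homozygous calls map to one allele, IUPAC ambiguity letters to two,
## missing (".") to none.
expand_alleles <- function(calls) {
  calls <- calls[!is.na(calls) & calls != "."]
  if (length(calls) == 0L) return(character(0))
  out <- character(0)
  for (cc in calls) {
    if (cc %in% BASES) {
      out <- c(out, cc)
    } else if (cc %in% names(IUPAC_HET)) {
      out <- c(out, strsplit(IUPAC_HET[[cc]], "")[[1L]])
    } else {
      stop("allele character outside alphabet: '", cc, "'", call. = FALSE)
    }
  }
  out
}

is_het_call <- function(calls) calls %in% names(IUPAC_HET)

## Map an unordered pair of distinct bases to its IUPAC ambiguity letter
## (IUPAC_HET values are stored with alleles in alphabetical order).
iupac_from_pair <- function(a, b) {
  key <- paste0(sort(c(a, b)), collapse = "")
  hit <- names(IUPAC_HET)[match(key, unlist(IUPAC_HET))]
  if (is.na(hit)) stop("not a base pair: ", a, "/", b, call. = FALSE)
  hit
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
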