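# Genetic-code utilities shared by the codon-usage and selection modules.
# Standard code (NCBI translation table 1) throughout; the 61 sense codons
# are indexed in fixed TCAG-major order so that state indices are stable
# across the likelihood, simulation and counting code.

CODON_BASES <- c("T", "C", "A", "G")

.all_codons <- function() {
  as.vector(outer(outer(CODON_BASES, CODON_BASES, paste0), CODON_BASES, paste0))
}

#' The standard genetic code and codon groupings
#'
#' `GENETIC_CODE_1` maps the 64 codons (T/C/A/G nested order) to one-letter
#' amino acids ("*" for stop); `SENSE_CODONS` and `STOP_CODONS` partition
#' them; `SYN_FAMILIES` lists the synonymous codon family of each amino
#' acid; `CODON_DEGENERACY` gives each codon's family size (NA for stops).
#'
#' @format named character vector of length 64
#' @export
GENETIC_CODE_1 <- local({
  b <- CODON_BASES
  codons <- character(64)
  k <- 0L
  for (i in b) for (j in b) for (l in b) {
    k <- k + 1L
    codons[k] <- paste0(i, j, l)
  }
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aa, codons)
})

#' @rdname GENETIC_CODE_1
#' @export
STOP_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 == "*"]

#' @rdname GENETIC_CODE_1
#' @export
SENSE_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]

#' Translate a codon to its one-letter amino acid ("*" for stop)
#' @param codon character vector of 3-letter codons (uppercase ACGT)
#' @return character vector of one-letter amino acids
#' @export
translate_codon <- function(codon) {
  unname(GENETIC_CODE_1[codon])
}

#' @rdname GENETIC_CODE_1
#' @export
SYN_FAMILIES <- local({
  aas <- setdiff(unique(GENETIC_CODE_1), "*")
  fams <- lapply(aas, function(a) names(GENETIC_CODE_1)[GENETIC_CODE_1 == a])
  stats::setNames(fams, aas)
})

#' @rdname GENETIC_CODE_1
#' @export
CODON_DEGENERACY <- local({
  deg <- integer(64)
  names(deg) <- names(GENETIC_CODE_1)
  for (fam in SYN_FAMILIES) deg[fam] <- length(fam)
  deg[STOP_CODONS] <- NA_integer_
  deg
})

#' Split a coding sequence into codons
#'
#' @param cds a single nucleotide string (A/C/G/T, uppercase or lowercase)
#' @param trim_stop drop a terminal stop codon if present
#' @return character vector of codons
#' @keywords internal
split_codons <- function(cds, trim_stop = TRUE) {
  cds <- toupper(as.character(cds))
  cds <- gsub("U", "T", cds, fixed = TRUE)
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  if (n %% 3L != 0L) {
    stop("coding sequence length (", n, ") is not a multiple of 3")
  }
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  if (trim_stop && length(codons) > 0L &&
      codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  codons
}

#' Validate a coding sequence
#'
#' Checks length divisibility by 3 and absence of internal stop codons under
#' the standard code. A terminal stop is allowed (and ignored).
#'
#' @param cds nucleotide string
#' @param id sequence identifier used in error messages
#' @return invisibly, the codon vector (terminal stop trimmed)
#' @export
validate_cds <- function(cds, id = "cds") {
  codons <- split_codons(cds, trim_stop = TRUE)
  bad <- !codons %in% names(GENETIC_CODE_1)
  if (any(bad)) {
    stop("sequence '", id, "' contains non-ACGT codons: ",
         paste(unique(codons[bad]), collapse = ", "))
  }
  if (any(codons %in% STOP_CODONS)) {
    stop("sequence '", id, "' contains an internal stop codon")
  }
  invisible(codons)
}
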