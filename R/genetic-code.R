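#' The standard nuclear genetic code
#'
#' Returns the standard codon table partitioned into 61 sense codons encoding
#' 20 amino acids and the 3 stop codons. All codons are upper-case DNA
#' triplets; amino acids are one-letter codes, stops are `"*"`. The table is
#' taken from [Biostrings::GENETIC_CODE] and is the single source of truth
#' for 64/61/20 bookkeeping throughout the package.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `table` (named character, codon -> amino acid or `"*"`), `codons`,
#'   `sense_codons`, `stop_codons` and `amino_acids`.
#' @examples
#' gc <- load_genetic_code()
#' gc$table[["ATG"]]       # "M"
#' length(gc$sense_codons) # 61
#' @export
load_genetic_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  stopifnot(length(tab) == 64L)
  stops <- sort(names(tab)[tab == "*"])
  sense <- sort(names(tab)[tab != "*"])
  out <- list(
    table        = tab,
    codons       = sort(names(tab)),
    sense_codons = sense,
    stop_codons  = stops,
    amino_acids  = sort(unique(unname(tab[sense])))
  )
  class(out) <- "genetic_code"
  out
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$codons), "codons,",
      length(x$sense_codons), "sense,",
      length(x$stop_codons), "stops,",
      length(x$amino_acids), "amino acids\n")
  invisible(x)
}

#' Watson-Crick anticodon of a codon (and vice versa)
#'
#' The anticodon, written 5'->3', is the reverse complement of its
#' Watson-Crick codon; the mapping is an involution, so the same function
#' converts in both directions.
#'
#' @param x character vector of DNA triplets.
#' @return Character vector of reverse-complement triplets.
#' @export
codon_to_anticodon <- function(x) {
  if (any(nchar(x) != 3L)) stopf("all inputs must be DNA triplets")
  revcomp(toupper(x))
}

#' Isoacceptor family id for a codon
#'
#' Maps each sense codon to the id of the isoacceptor family carrying its
#' Watson-Crick anticodon, in `Isotype-ANTICODON` notation (e.g. codon
#' `GGC` -> family `Gly-GCC`).
#'
#' @param code a [load_genetic_code()] object.
#' @param codons codons to map; defaults to all sense codons.
#' @return Named character vector, codon -> family id.
#' @export
codon_family_pairing <- function(code = load_genetic_code(),
                                 codons = code$sense_codons) {
  bad <- setdiff(codons, code$sense_codons)
  if (length(bad) > 0) stopf("not sense codons: %s", paste(bad, collapse = ", "))
  aa <- unname(code$table[codons])
  stats::setNames(paste0(AA_THREE[aa], "-", codon_to_anticodon(codons)), codons)
}
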