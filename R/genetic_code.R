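#' Genetic code tables for codon models
#'
#' Wraps an NCBI translation table as the set of sense codons used by the
#' codon substitution machinery.  The default is translation table 2
#' (vertebrate mitochondrial), under which TAA, TAG, AGA and AGG are stop
#' codons, leaving 60 sense codons; TGA codes for tryptophan and ATA for
#' methionine.
#'
#' @param code_id NCBI translation table identifier (integer or character),
#'   e.g. `2` for vertebrate mitochondrial, `1` for the standard code.
#' @return An object of class `"genetic_code"`: a list with elements
#'   `code_id`, `table` (named character vector over all 64 codons),
#'   `sense` (sense codon strings), `aa` (amino acid per sense codon) and
#'   `stops`.
#' @examples
#' gc2 <- genetic_code(2)
#' length(gc2$sense)  # 60
#' @export
genetic_code <- function(code_id = 2L) {
  tab <- Biostrings::getGeneticCode(as.character(code_id))
  sense <- names(tab)[tab != "*"]
  structure(
    list(code_id = as.character(code_id),
         table = tab,
         sense = sense,
         aa = unname(tab[sense]),
         stops = names(tab)[tab == "*"]),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$code_id, "): ",
      length(x$sense), " sense codons, stops: ",
      paste(x$stops, collapse = " "), "\n", sep = "")
  invisible(x)
}

# nucleotide at codon position p for each sense codon
codon_nuc <- function(code, pos) substr(code$sense, pos, pos)

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

.step_cache <- new.env(parent = emptyenv())

# Classify every ordered sense-codon pair:
#   0 = identical or differing at >1 position (rate zero),
#   1 = synonymous transversion, 2 = synonymous transition,
#   3 = nonsynonymous transversion, 4 = nonsynonymous transition.
single_step_types <- function(code) {
  key <- code$code_id
  if (!is.null(.step_cache[[key]])) return(.step_cache[[key]])
  n <- length(code$sense)
  m <- matrix(0L, n, n, dimnames = list(code$sense, code$sense))
  nucs <- lapply(1:3, function(p) codon_nuc(code, p))
  for (p in 1:3) {
    a <- nucs[[p]]
    same_other <- Reduce(`&`, lapply(setdiff(1:3, p), function(q) {
      outer(nucs[[q]], nucs[[q]], `==`)
    }))
    diff_here <- outer(a, a, `!=`)
    one_step <- same_other & diff_here
    ts <- outer(a, a, is_transition)
    syn <- outer(code$aa, code$aa, `==`)
    m[one_step] <- 1L + ts[one_step] + 2L * (!syn[one_step])
  }
  .step_cache[[key]] <- m
  m
}
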