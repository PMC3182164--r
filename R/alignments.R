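#' Codon alignments
#'
#' A codon alignment is stored as a taxa-by-sites character matrix of codon
#' triplets under a declared genetic code.  Codons containing any character
#' outside A/C/G/T (gaps, ambiguity codes) are treated as fully missing at
#' that site for that taxon and stored as `NA`.  Internal stop codons are
#' rejected at construction time.
#'
#' @param x character matrix of codon triplets (rows = taxa, columns = codon
#'   sites), or a taxa-by-nucleotides character matrix/named character vector
#'   of sequences whose lengths are multiples of three.
#' @param code a [genetic_code()] object; defaults to the vertebrate
#'   mitochondrial code (NCBI table 2).
#' @param gene_map optional `data.frame` with columns `gene`, `start`, `end`
#'   (1-based inclusive codon-site ranges tiling the alignment).
#' @return An object of class `"codon_alignment"`: the codon matrix with
#'   attributes `code` and `gene_map`.
#' @export
codon_alignment <- function(x, code = genetic_code(2), gene_map = NULL) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- do.call(rbind, lapply(x, function(s) strsplit(s, "")[[1]]))
  }
  x <- toupper(x)
  if (ncol(x) %% 3 == 0 && isTRUE(all(nchar(x[1, ]) == 1, na.rm = TRUE))) {
    # nucleotide matrix -> fold into triplets
    S <- ncol(x) / 3
    cod <- matrix(NA_character_, nrow(x), S, dimnames = list(rownames(x), NULL))
    for (j in seq_len(S)) {
      cod[, j] <- paste0(x[, 3 * j - 2], x[, 3 * j - 1], x[, 3 * j])
    }
    x <- cod
  }
  if (any(nchar(x[!is.na(x)]) != 3)) {
    stop("codon matrix entries must be nucleotide triplets")
  }
  bad <- !is.na(x) & !grepl("^[ACGT]{3}$", x)
  x[bad] <- NA_character_
  # internal stops are a reading-frame/data error
  stops <- which(matrix(x %in% code$stops, nrow(x)), arr.ind = TRUE)
  if (nrow(stops)) {
    stop(sprintf("internal stop codon '%s' in taxon '%s' at codon site %d",
                 x[stops[1, 1], stops[1, 2]],
                 rownames(x)[stops[1, 1]], stops[1, 2]))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  if (is.null(gene_map)) {
    gene_map <- data.frame(gene = "gene1", start = 1L, end = ncol(x),
                           stringsAsFactors = FALSE)
  }
  validate_gene_map(gene_map, ncol(x))
  structure(x, code = code, gene_map = gene_map, class = "codon_alignment")
}

validate_gene_map <- function(gm, S) {
  stopifnot(all(c("gene", "start", "end") %in% names(gm)))
  o <- order(gm$start)
  if (gm$start[o][1] != 1) stop("gene_map must start at codon site 1")
  ends <- gm$end[o]; starts <- gm$start[o]
  if (any(starts[-1] != ends[-length(ends)] + 1) || ends[length(ends)] != S) {
    stop("gene_map ranges must tile 1..S without gaps or overlap")
  }
  invisible(gm)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", nrow(x), " taxa x ", ncol(x),
      " codon sites (NCBI code ", attr(x, "code")$code_id, ", ",
      nrow(attr(x, "gene_map")), " gene(s))\n", sep = "")
  invisible(x)
}

#' Taxon labels of an alignment
#' @param aln a `codon_alignment` or `amino_msa`.
#' @return character vector of row labels.
#' @export
taxa_labels <- function(aln) rownames(aln)

#' Read an in-frame codon alignment
#'
#' Reads an aligned FASTA or sequential PHYLIP nucleotide file and folds it
#' into codons.  Sequence lengths must be equal and divisible by three, and
#' no sequence may contain an internal stop codon under the declared code.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @param code a [genetic_code()].
#' @return a [codon_alignment()]; taxon order is preserved from the file.
#' @export
read_codon_alignment <- function(path, format = c("fasta", "phylip"),
                                 code = genetic_code(2)) {
  format <- match.arg(format)
  m <- tryCatch(
    suppressWarnings(
      ape::read.dna(path,
                    format = if (format == "fasta") "fasta" else "sequential",
                    as.character = TRUE, as.matrix = TRUE)),
    error = function(e) stop("could not parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0) {
    stop("could not parse '", path, "': no aligned sequences found")
  }
  if (ncol(m) %% 3 != 0) {
    stop(sprintf("alignment length %d is not a multiple of 3 (taxon '%s')",
                 ncol(m), rownames(m)[1]))
  }
  codon_alignment(toupper(m), code = code)
}

#' Write a codon alignment
#'
#' @param aln a [codon_alignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"` (sequential).  Missing codons are
#'   written as `---`.
#' @export
write_codon_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  m <- unclass(aln)
  m[is.na(m)] <- "---"
  seqs <- apply(m, 1, paste0, collapse = "")
  nucs <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(nucs) <- rownames(m)
  ape::write.dna(nucs, path,
                 format = if (format == "fasta") "fasta" else "sequential",
                 colsep = "", nbcol = -1)
  invisible(path)
}

#' Concatenate per-gene codon alignments
#'
#' Joins alignments of the same taxon set into one alignment, recording each
#' gene's codon-site interval (1-based, inclusive) in `gene_map` in input
#' order.  Taxon order follows the first part; other parts are reordered to
#' match.
#'
#' @param parts named list of [codon_alignment()] objects (names are gene
#'   names).
#' @return a single [codon_alignment()].
#' @export
concatenate_genes <- function(parts) {
  stopifnot(length(parts) >= 1)
  if (is.null(names(parts)) || any(names(parts) == "")) {
    names(parts) <- paste0("gene", seq_along(parts))
  }
  ref <- rownames(parts[[1]])
  for (i in seq_along(parts)) {
    ti <- rownames(parts[[i]])
    if (!setequal(ti, ref)) {
      stop("taxon sets differ between genes: missing {",
           paste(setdiff(ref, ti), collapse = ", "), "}, extra {",
           paste(setdiff(ti, ref), collapse = ", "), "}")
    }
  }
  mats <- lapply(parts, function(p) unclass(p)[ref, , drop = FALSE])
  lens <- vapply(mats, ncol, 0L)
  ends <- cumsum(lens)
  gm <- data.frame(gene = names(parts),
                   start = as.integer(c(1L, utils::head(ends, -1) + 1L)),
                   end = as.integer(ends), stringsAsFactors = FALSE)
  codon_alignment(do.call(cbind, mats), code = attr(parts[[1]], "code"),
                  gene_map = gm)
}

#' Amino-acid alignments
#'
#' @param x character matrix (sequences x columns) of one-letter amino acid
#'   codes; anything outside the 20 standard residues is stored as the gap
#'   character `-`.
#' @return object of class `"amino_msa"`.
#' @export
amino_msa <- function(x) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- do.call(rbind, lapply(x, function(s) strsplit(s, "")[[1]]))
  }
  x <- toupper(x)
  x[!(x %in% AA20)] <- "-"
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  structure(x, class = "amino_msa")
}

#' The 20 standard amino acids (alphabetical one-letter codes)
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @export
print.amino_msa <- function(x, ...) {
  cat("Amino-acid MSA: ", nrow(x), " sequences x ", ncol(x), " columns\n",
      sep = "")
  invisible(x)
}

#' Read / write amino-acid FASTA alignments
#' @param path file path.
#' @return [amino_msa()] for the reader; `path` invisibly for the writer.
#' @export
read_amino_msa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop("no sequences in '", path, "'")
  m <- as.matrix(ss)
  amino_msa(m)
}

#' @rdname read_amino_msa
#' @param msa an [amino_msa()].
#' @export
write_amino_msa <- function(msa, path) {
  seqs <- apply(unclass(msa), 1, paste0, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- rownames(msa)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Translate a codon alignment
#'
#' One amino acid per codon site under the alignment's genetic code; missing
#' codons propagate as gaps.
#'
#' @param aln a [codon_alignment()].
#' @return an [amino_msa()] with the same row labels.
#' @export
translate_codons <- function(aln) {
  code <- attr(aln, "code")
  m <- unclass(aln)
  aa <- matrix(code$table[m], nrow(m), ncol(m), dimnames = dimnames(m))
  aa[is.na(aa)] <- "-"
  amino_msa(aa)
}

#' Serialize / read a gene map
#'
#' Tab-separated table with columns `gene`, `start`, `end` (1-based,
#' inclusive codon-site ranges).
#' @param aln a [codon_alignment()] (writer) .
#' @param path file path.
#' @export
write_gene_map <- function(aln, path) {
  utils::write.table(attr(aln, "gene_map"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_map
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  gm$start <- as.integer(gm$start); gm$end <- as.integer(gm$end)
  gm
}
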