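# Internal sequence utilities. All coordinates inside the package are
# 0-based half-open; every emitted table is 1-based inclusive (GFF style).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented where defined; `N` stays `N`.
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N and IUPAC codes)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNRYSWKMBDHV", "TGCAANYRSWMKVHDB", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# integer coding for the C++ window matcher: A,C,G,T -> 0..3, other -> 4
encode_dna <- function(x) {
  m <- match(seq_chars(x), DNA_BASES)
  m[is.na(m)] <- 5L
  m - 1L
}

gc_content <- function(x) {
  ch <- seq_chars(x)
  acgt <- ch %in% DNA_BASES
  if (!any(acgt)) return(NA_real_)
  sum(ch %in% c("G", "C")) / sum(acgt)
}

#' Translate an in-frame coding sequence
#'
#' Standard genetic code; a trailing stop codon is removed. Codons containing
#' N translate to `X`.
#'
#' @param cds nucleotide string whose length is a multiple of 3
#' @return amino-acid string, with `*` marking any internal stop
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# residue indices (0-based) into the protein scoring matrix
encode_protein <- function(x, alphabet) {
  m <- match(seq_chars(x), alphabet)
  m[is.na(m)] <- match("X", alphabet)
  m - 1L
}

#' BLOSUM62 scoring matrix with neutral ambiguity
#'
#' The Biostrings BLOSUM62 matrix with the `X` row/column set to zero, so an
#' ambiguous residue neither rewards nor penalizes any pairing.
#'
#' @return 25 x 25 numeric matrix
#' @keywords internal
blosum62_neutral_x <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  S["X", ] <- 0
  S[, "X"] <- 0
  S
}

# IUPAC motif match for short PAM-style motifs
iupac_match <- function(observed, motif) {
  if (nchar(observed) != nchar(motif)) return(FALSE)
  tab <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  obs <- seq_chars(toupper(observed))
  mot <- seq_chars(toupper(motif))
  all(mapply(function(o, m) {
    allowed <- tab[[m]]
    !is.null(allowed) && grepl(o, allowed, fixed = TRUE)
  }, obs, mot))
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  sum(seq_chars(a) != seq_chars(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
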