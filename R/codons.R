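# Codon-level utilities shared across the diversity, divergence and
# simulation code. All sequences are plain upper-case character scalars in
# transcript orientation unless stated otherwise; the standard nuclear
# genetic code (Biostrings::GENETIC_CODE) is used throughout.

.pollensel_cache <- new.env(parent = emptyenv())

#' The standard genetic code as a named vector
#'
#' @return Named character vector mapping codon (e.g. "ATG") to one-letter
#'   amino acid, with "*" for stop codons.
#' @keywords internal
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc == "*"]
}

#' Split a CDS string into codons
#' @param seq character scalar, length divisible by 3
#' @return character vector of codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS to amino acids (one letter per codon, "*" = stop)
#' @keywords internal
translate_codons <- function(codons) {
  aa <- genetic_code()[codons]
  aa[is.na(aa)] <- "X"  # ambiguity or non-ACGT
  unname(aa)
}

translate_cds <- function(seq) paste(translate_codons(split_codons(seq)), collapse = "")

#' Per-position degeneracy of every codon
#'
#' For each sense codon and each of its three positions, the number of the
#' three alternative bases that preserve the amino acid (0 = zero-fold,
#' 3 = four-fold degenerate).
#'
#' @return 64 x 3 integer matrix, rownames = codons.
#' @keywords internal
codon_degeneracy <- function() {
  if (!is.null(.pollensel_cache$degeneracy)) return(.pollensel_cache$degeneracy)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  m <- matrix(NA_integer_, nrow = length(gc), ncol = 3,
              dimnames = list(names(gc), NULL))
  for (cd in names(gc)) {
    aa <- gc[[cd]]
    for (p in 1:3) {
      alt <- setdiff(bases, substr(cd, p, p))
      muts <- vapply(alt, function(b) {
        x <- cd
        substr(x, p, p) <- b
        gc[[x]]
      }, character(1))
      m[cd, p] <- sum(muts == aa)
    }
  }
  .pollensel_cache$degeneracy <- m
  m
}

#' Reverse complement of nucleotide strings
#' @param x character vector of DNA sequences
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement single bases (vectorised)
#' @keywords internal
comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

#' Harmonic number a_k = sum_{i=1}^{k} 1/i
#'
#' The Watterson correction factor for a sample of k + 1 sequences.
#' @param k positive integer
#' @export
harmonic_number <- function(k) {
  stopifnot(k >= 1)
  sum(1 / seq_len(k))
}

#' Random sense-codon CDS (start codon, no internal stop, terminal stop)
#' @param n_codons number of internal codons, excluding start and stop
#' @keywords internal
random_cds <- function(n_codons) {
  body <- sample(sense_codons(), n_codons, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(stop_codons(), 1))
}
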