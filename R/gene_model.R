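# GeneModel: a gene's chromosome, strand and the CDS intervals of its
# representative splice model, in 1-based inclusive genomic coordinates.
# Intervals are stored in transcript (5'->3') order: ascending genomic start
# on the + strand, descending on the - strand.

#' Construct a gene model
#'
#' @param gene_id character scalar
#' @param chromosome character scalar
#' @param strand "+" or "-"
#' @param cds matrix or data.frame with columns start, end (1-based
#'   inclusive genomic coordinates); will be put into transcript order
#' @param gene_start,gene_end genomic span of the gene feature; default
#'   to the CDS span
#' @param is_representative flag
#' @return object of class "gene_model"
#' @export
gene_model <- function(gene_id, chromosome, strand, cds,
                       gene_start = NULL, gene_end = NULL,
                       is_representative = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  cds <- as.matrix(cds[, c("start", "end"), drop = FALSE])
  storage.mode(cds) <- "integer"
  if (any(cds[, "end"] < cds[, "start"])) stop("CDS interval with end < start in ", gene_id)
  o <- order(cds[, "start"])
  cds <- cds[o, , drop = FALSE]
  if (nrow(cds) > 1 && any(cds[-1, "start"] <= cds[-nrow(cds), "end"]))
    stop("overlapping CDS intervals in ", gene_id)
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  gm <- list(
    gene_id = gene_id,
    chromosome = chromosome,
    strand = strand,
    cds = cds,
    gene_start = if (is.null(gene_start)) min(cds[, "start"]) else as.integer(gene_start),
    gene_end = if (is.null(gene_end)) max(cds[, "end"]) else as.integer(gene_end),
    is_representative = isTRUE(is_representative)
  )
  class(gm) <- "gene_model"
  gm
}

#' Total CDS length of a gene model
#' @param gm gene_model
#' @export
cds_length <- function(gm) sum(gm$cds[, "end"] - gm$cds[, "start"] + 1L)

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%d-%d (%s), %d CDS interval(s), CDS %d nt>\n",
              x$gene_id, x$chromosome, x$gene_start, x$gene_end, x$strand,
              nrow(x$cds), cds_length(x)))
  invisible(x)
}

#' Genomic CDS positions in transcript order
#'
#' @param gm gene_model
#' @return integer vector of genomic positions; element i is the genomic
#'   coordinate of CDS (transcript) position i.
#' @export
cds_genomic_positions <- function(gm) {
  pos <- lapply(seq_len(nrow(gm$cds)), function(i) {
    s <- gm$cds[i, "start"]; e <- gm$cds[i, "end"]
    if (gm$strand == "+") seq.int(s, e) else seq.int(e, s)
  })
  as.integer(unlist(pos))
}

#' Map genomic positions to CDS (transcript) coordinates
#'
#' @param gm gene_model
#' @param positions integer vector of genomic positions
#' @return integer vector of 1-based CDS positions; NA for positions
#'   outside the CDS.
#' @export
map_to_cds <- function(gm, positions) {
  match(as.integer(positions), cds_genomic_positions(gm))
}

#' Extract the reference CDS of a gene model from a genome
#'
#' @param gm gene_model
#' @param genome DNAStringSet (names = chromosomes) or named character vector
#' @return character scalar: spliced CDS in transcript orientation
#' @export
extract_cds <- function(gm, genome) {
  chrom <- as.character(genome[[gm$chromosome]])
  pieces <- vapply(seq_len(nrow(gm$cds)), function(i) {
    substr(chrom, gm$cds[i, "start"], gm$cds[i, "end"])
  }, character(1))
  # pieces are in transcript order of intervals but each piece is read on
  # the + strand; for - strand genes reverse-complement each piece
  if (gm$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Summarise a list of gene models as a data frame
#' @param models list of gene_model objects
#' @export
gene_model_table <- function(models) {
  data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chromosome = vapply(models, `[[`, character(1), "chromosome"),
    strand = vapply(models, `[[`, character(1), "strand"),
    gene_start = vapply(models, `[[`, integer(1), "gene_start"),
    gene_end = vapply(models, `[[`, integer(1), "gene_end"),
    n_cds = vapply(models, function(m) nrow(m$cds), integer(1)),
    cds_length = vapply(models, cds_length, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Validate a gene model against a reference genome
#'
#' Checks CDS length divisibility by 3, a start codon, a terminal stop and
#' the absence of internal stop codons in the reference frame.
#' @param gm gene_model
#' @param genome reference sequences
#' @return TRUE invisibly, or an error
#' @export
validate_gene_model <- function(gm, genome) {
  cds <- extract_cds(gm, genome)
  if (nchar(cds) %% 3 != 0) stop(gm$gene_id, ": CDS length not divisible by 3")
  aa <- translate_codons(split_codons(cds))
  if (aa[1] != "M") stop(gm$gene_id, ": no start codon")
  if (aa[length(aa)] != "*") stop(gm$gene_id, ": no terminal stop codon")
  if (any(aa[-length(aa)] == "*")) stop(gm$gene_id, ": internal stop codon")
  invisible(TRUE)
}
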