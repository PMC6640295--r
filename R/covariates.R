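# The six genomic covariates used to control all group comparisons:
# expression level, GC content, within-gene RSCU variance (codon bias),
# gene density in fixed 100-kb windows, gene length and average intron
# length.

#' GC content of a nucleotide sequence, in percent
#'
#' Ambiguity codes are excluded from both numerator and denominator.
#' @param sequence character vector of nucleotide sequences
#' @return numeric vector, 100 * (G + C) / (A + C + G + T)
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(toupper(sequence)),
                                   letters = c("A", "C", "G", "T"))
  tot <- rowSums(f)
  if (any(tot == 0)) stop("sequence with no unambiguous bases")
  unname(100 * (f[, "C"] + f[, "G"]) / tot)
}

#' Within-gene variance of relative synonymous codon usage
#'
#' RSCU of codon c for amino acid a is count(c) * k_a / sum of counts over
#' a's codons, with k_a the synonymous family size. Codons of amino acids
#' unused in the gene are excluded; stop codons are excluded; single-codon
#' amino acids (Met, Trp) enter with RSCU 1 when present. Returns the
#' population variance of the included codons' RSCU values.
#'
#' @param cds coding sequence (length divisible by 3)
#' @return non-negative scalar
#' @export
rscu_variance <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) == 0) stop("CDS shorter than one codon")
  vals <- rscu_values(cds)
  v <- vals$rscu
  mean((v - mean(v))^2)
}

#' Per-codon RSCU values of the amino acids used in a gene
#' @param cds coding sequence
#' @return data.frame with codon, amino acid and RSCU of every sense codon
#'   belonging to an amino acid used in the gene
#' @export
rscu_values <- function(cds) {
  codons <- split_codons(toupper(cds))
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  counts <- table(factor(codons[codons %in% sense], levels = sense))
  fam <- split(sense, gc[sense])
  out <- lapply(names(fam), function(aa) {
    cs <- fam[[aa]]
    tot <- sum(counts[cs])
    if (tot == 0) return(NULL)  # amino acid not used in this gene
    data.frame(codon = cs, aa = aa,
               rscu = as.numeric(counts[cs]) * length(cs) / tot,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Gene density in fixed windows along each chromosome
#'
#' Chromosomes are partitioned into half-open windows [0, w), [w, 2w), ...;
#' each gene is assigned to the window containing its start coordinate and
#' its density is that window's gene count (so a gene's own window always
#' contains it: density >= 1).
#'
#' @param models list of gene_model objects
#' @param window window width in nt (default 100 kb)
#' @return named numeric vector of densities, one per gene
#' @export
gene_density <- function(models, window = 100000) {
  tab <- gene_model_table(models)
  win <- floor(tab$gene_start / window)
  key <- paste(tab$chromosome, win)
  counts <- table(key)
  dens <- as.numeric(counts[key])
  names(dens) <- tab$gene_id
  dens
}

#' Gene length and average intron length of a gene model
#'
#' Gene length is the genomic span of the gene feature; average intron
#' length is the mean gap between consecutive CDS intervals (0 for
#' single-interval genes).
#'
#' @param gm gene_model
#' @return list with gene_length and avg_intron_length
#' @export
intron_stats <- function(gm) {
  cds <- gm$cds[order(gm$cds[, "start"]), , drop = FALSE]
  introns <- if (nrow(cds) > 1)
    cds[-1, "start"] - cds[-nrow(cds), "end"] - 1L else integer(0)
  list(gene_length = gm$gene_end - gm$gene_start + 1L,
       avg_intron_length = if (length(introns)) mean(introns) else 0)
}

#' Compute the six genomic covariates for every gene
#'
#' @param models list of gene_model objects
#' @param genome reference sequences (DNAStringSet)
#' @param classes output of \code{\link{classify_life_stage}} supplying
#'   expression_level (genes absent from it get NA)
#' @param gc_on compute GC content on the genomic gene span ("locus",
#'   default) or on the spliced CDS ("cds")
#' @param window gene-density window width
#' @return data.frame: gene_id, expression_level, gc_percent,
#'   rscu_variance, gene_length, avg_intron_length, gene_density
#' @export
compute_covariates <- function(models, genome, classes = NULL,
                               gc_on = c("locus", "cds"), window = 100000) {
  gc_on <- match.arg(gc_on)
  dens <- gene_density(models, window)
  rows <- lapply(models, function(gm) {
    cds <- extract_cds(gm, genome)
    seq_gc <- if (gc_on == "cds") cds else {
      chrom <- as.character(genome[[gm$chromosome]])
      substr(chrom, gm$gene_start, gm$gene_end)
    }
    is <- intron_stats(gm)
    data.frame(gene_id = gm$gene_id,
               gc_percent = gc_content(seq_gc),
               rscu_variance = rscu_variance(cds),
               gene_length = is$gene_length,
               avg_intron_length = is$avg_intron_length,
               gene_density = unname(dens[gm$gene_id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$expression_level <- if (is.null(classes)) NA_real_ else
    classes$expression_level[match(out$gene_id, classes$gene_id)]
  out[, c("gene_id", "expression_level", "gc_percent", "rscu_variance",
          "gene_length", "avg_intron_length", "gene_density")]
}
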