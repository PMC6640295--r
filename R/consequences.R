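# Reconstruction of per-strain coding sequences from filtered variant
# calls, and scoring of putatively deleterious alleles: premature stop
# codons (SNP-only, positional) and frameshift indels. Strains are fully
# homozygous inbred lines; every call is applied as such.

# Concatenated CDS in genomic (+) orientation with its genomic positions.
.cds_plus <- function(gm, genome) {
  chrom <- as.character(genome[[gm$chromosome]])
  cds <- gm$cds[order(gm$cds[, "start"]), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(cds)), function(i)
    substr(chrom, cds[i, "start"], cds[i, "end"]), character(1))
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq.int(cds[i, "start"], cds[i, "end"])))
  list(seq = paste(seqs, collapse = ""), pos = as.integer(pos))
}

#' Variants of one gene, restricted to its CDS
#'
#' SNPs are returned with transcript-oriented CDS coordinates and alleles
#' (complemented for minus-strand genes); indels are returned if their
#' anchor base lies within the CDS.
#'
#' @param gm gene_model
#' @param variants variant_table (already quality filtered)
#' @return list with data.frames \code{snps} (strain_id, cds_pos, ref_t,
#'   alt_t, position, quality) and \code{indels} (strain_id, position,
#'   ref_allele, alt_allele, length_change)
#' @export
gene_variants <- function(gm, variants) {
  v <- variants[variants$chromosome == gm$chromosome, , drop = FALSE]
  tpos <- cds_genomic_positions(gm)
  snp <- v[v$kind == "SNP", , drop = FALSE]
  cp <- match(snp$position, tpos)
  keep <- !is.na(cp)
  snp <- snp[keep, , drop = FALSE]
  cp <- cp[keep]
  flip <- gm$strand == "-"
  snps <- data.frame(
    strain_id = snp$strain_id,
    cds_pos = cp,
    ref_t = if (flip) comp_base(snp$ref_allele) else snp$ref_allele,
    alt_t = if (flip) comp_base(snp$alt_allele) else snp$alt_allele,
    position = snp$position,
    quality = snp$quality,
    stringsAsFactors = FALSE
  )
  ind <- v[v$kind == "indel" & v$position %in% tpos, , drop = FALSE]
  indels <- data.frame(
    strain_id = ind$strain_id,
    position = ind$position,
    ref_allele = ind$ref_allele,
    alt_allele = ind$alt_allele,
    length_change = nchar(ind$alt_allele) - nchar(ind$ref_allele),
    stringsAsFactors = FALSE
  )
  list(snps = snps, indels = indels)
}

#' Build one strain's coding sequence
#'
#' Applies the strain's filtered SNPs and left-anchored indels to the
#' reference CDS; minus-strand genes are reverse-complemented into
#' transcript orientation after application. Variants whose reference
#' allele disagrees with the reference sequence, or whose span is not
#' fully contained in a single CDS interval, are rejected and counted
#' without aborting the gene.
#'
#' @param gm gene_model
#' @param genome reference sequences
#' @param strain_variants variant_table rows of a single strain
#' @return list with gene_id, strain_id, sequence (transcript
#'   orientation) and n_rejected
#' @export
build_strain_cds <- function(gm, genome, strain_variants) {
  cp <- .cds_plus(gm, genome)
  seq <- cp$seq
  v <- strain_variants[strain_variants$chromosome == gm$chromosome, , drop = FALSE]
  rejected <- 0L
  snp <- v[v$kind == "SNP", , drop = FALSE]
  idx <- match(snp$position, cp$pos)
  for (i in seq_len(nrow(snp))) {
    j <- idx[i]
    if (is.na(j)) next
    if (substr(seq, j, j) != snp$ref_allele[i]) { rejected <- rejected + 1L; next }
    substr(seq, j, j) <- snp$alt_allele[i]
  }
  ind <- v[v$kind == "indel", , drop = FALSE]
  j <- match(ind$position, cp$pos)
  inside <- !is.na(j)  # indels anchored outside the CDS are simply ignored
  ind <- ind[inside, , drop = FALSE]; j <- j[inside]
  if (nrow(ind)) {
    o <- order(j, decreasing = TRUE)
    ind <- ind[o, , drop = FALSE]; j <- j[o]
    for (i in seq_len(nrow(ind))) {
      nr <- nchar(ind$ref_allele[i])
      end <- j[i] + nr - 1L
      contiguous <- end <= length(cp$pos) &&
        cp$pos[end] == ind$position[i] + nr - 1L
      if (!contiguous || substr(seq, j[i], end) != ind$ref_allele[i]) {
        rejected <- rejected + 1L
        next
      }
      seq <- paste0(substr(seq, 1, j[i] - 1L), ind$alt_allele[i],
                    substr(seq, end + 1L, nchar(seq)))
      # positions after the edit are only used for matching later indels,
      # which were sorted to strictly smaller anchors; no shift needed
    }
  }
  if (gm$strand == "-") seq <- revcomp(seq)
  list(gene_id = gm$gene_id, strain_id = unique(v$strain_id)[1],
       sequence = seq, n_rejected = rejected)
}

#' Score unique premature-stop alleles of a gene
#'
#' A premature stop is a SNP that, applied alone to the reference CDS,
#' creates a stop codon at any codon before the reference terminal stop.
#' Uniqueness is keyed on the (CDS position, alternative base) pair; the
#' reported frequency is the unique count divided by the panel size, and
#' the raw count is returned alongside.
#'
#' @param gm gene_model
#' @param ref_cds reference CDS (transcript orientation)
#' @param variants variant_table (quality filtered, whole panel)
#' @param n_strains panel size
#' @return list with unique_stop_alleles, stop_allele_frequency, n_rejected
#' @export
score_premature_stops <- function(gm, ref_cds, variants, n_strains) {
  gv <- gene_variants(gm, variants)
  snps <- gv$snps
  n_codons <- nchar(ref_cds) %/% 3L
  rejected <- 0L
  if (nrow(snps)) {
    ok <- substring(ref_cds, snps$cds_pos, snps$cds_pos) == snps$ref_t
    rejected <- sum(!ok)
    snps <- snps[ok, , drop = FALSE]
  }
  uniq <- unique(snps[, c("cds_pos", "alt_t")])
  n_stop <- 0L
  gc <- genetic_code()
  for (i in seq_len(nrow(uniq))) {
    pos <- uniq$cds_pos[i]
    codon_i <- (pos - 1L) %/% 3L + 1L
    if (codon_i >= n_codons) next  # terminal stop codon: stop-loss, not premature
    codon <- substring(ref_cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    substr(codon, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- uniq$alt_t[i]
    aa <- gc[codon]
    if (!is.na(aa) && aa == "*") n_stop <- n_stop + 1L
  }
  list(unique_stop_alleles = n_stop,
       stop_allele_frequency = n_stop / n_strains,
       n_rejected = rejected)
}

#' Proportion of strains carrying a frameshift in a gene's CDS
#'
#' A strain counts once if it carries at least one CDS indel whose length
#' change is not a multiple of 3.
#'
#' @param gm gene_model
#' @param variants variant_table (quality filtered, whole panel)
#' @param n_strains panel size
#' @return frameshift frequency in [0, 1]
#' @export
score_frameshifts <- function(gm, variants, n_strains) {
  ind <- gene_variants(gm, variants)$indels
  fs <- ind[abs(ind$length_change) %% 3L != 0L, , drop = FALSE]
  length(unique(fs$strain_id)) / n_strains
}

#' Deleterious-allele statistics for every gene
#'
#' @param models list of gene_model objects
#' @param genome reference sequences
#' @param variants variant_table (quality filtered)
#' @param n_strains panel size
#' @return data.frame: gene_id, unique_stop_alleles, stop_allele_frequency,
#'   frameshift_frequency, n_strains
#' @export
score_deleterious <- function(models, genome, variants, n_strains) {
  rows <- lapply(models, function(gm) {
    ref <- extract_cds(gm, genome)
    st <- score_premature_stops(gm, ref, variants, n_strains)
    data.frame(gene_id = gm$gene_id,
               unique_stop_alleles = st$unique_stop_alleles,
               stop_allele_frequency = st$stop_allele_frequency,
               frameshift_frequency = score_frameshifts(gm, variants, n_strains),
               n_strains = n_strains,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
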