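# Readers and writers for the standard formats the pipeline touches: GFF3
# gene models, FASTA genomes, variant calls (VCF or a simple per-strain
# TSV dialect), expression tables and BLAST outfmt-6-like hit tables.
# Coordinates are 1-based inclusive everywhere (GFF3/VCF convention).

#' Read gene models from a GFF3 file
#'
#' One gene model per representative mRNA is returned. When a gene has
#' several mRNAs the one with the longest total CDS is taken as
#' representative (ties broken by lexicographic mRNA ID). Genes whose CDS
#' length is not divisible by 3 are excluded with a warning.
#'
#' @param path GFF3 file
#' @return named list of \code{\link{gene_model}} objects, ordered by
#'   (chromosome, gene start). Attribute \code{excluded} lists gene IDs
#'   dropped by the divisibility rule.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf != 9L]
    if (length(bad))
      stop("unparseable GFF3 line ", bad[1], " in ", path, ": ", lines[bad[1]])
  }
  g <- as.data.frame(rtracklayer::readGFF(path,
    columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type == "mRNA", , drop = FALSE]
  cdss <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(mrnas) == 0 || nrow(cdss) == 0) stop("no mRNA/CDS features in ", path)

  cds_by_mrna <- split(cdss, cdss$Parent)
  mrna_cds_len <- vapply(cds_by_mrna, function(d) sum(d$end - d$start + 1L), numeric(1))

  excluded <- character(0)
  models <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    gm_mrnas <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, , drop = FALSE]
    if (nrow(gm_mrnas) == 0) next
    cand <- gm_mrnas$ID
    len <- mrna_cds_len[cand]
    len[is.na(len)] <- 0
    rep_id <- cand[order(-len, cand)][1]
    d <- cds_by_mrna[[rep_id]]
    if (is.null(d) || nrow(d) == 0) next
    total <- sum(d$end - d$start + 1L)
    if (total %% 3L != 0L) {
      excluded <- c(excluded, gid)
      next
    }
    models[[gid]] <- gene_model(
      gene_id = gid,
      chromosome = as.character(genes$seqid[i]),
      strand = as.character(genes$strand[i]),
      cds = data.frame(start = d$start, end = d$end),
      gene_start = genes$start[i],
      gene_end = genes$end[i],
      is_representative = TRUE
    )
  }
  if (length(excluded))
    warning("excluded ", length(excluded),
            " gene(s) with CDS length not divisible by 3: ",
            paste(excluded, collapse = ", "))
  tab <- gene_model_table(models)
  models <- models[order(tab$chromosome, tab$gene_start)]
  attr(models, "excluded") <- excluded
  models
}

#' Read a genome FASTA
#' @param path FASTA file
#' @return DNAStringSet; names truncated to the first whitespace token
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#' @param seqs named character vector or DNAStringSet
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.variant_columns <- c("strain_id", "chromosome", "position",
                      "ref_allele", "alt_allele", "kind", "quality")

.finish_variants <- function(v, min_quality, n_missing) {
  v$kind <- ifelse(nchar(v$ref_allele) == 1L & nchar(v$alt_allele) == 1L,
                   "SNP", "indel")
  if (any(!is.na(v$quality) & v$quality < 0)) stop("negative phred quality")
  keep <- !is.na(v$quality) & v$quality >= min_quality
  n_missing <- n_missing + sum(is.na(v$quality))
  v <- v[keep, .variant_columns, drop = FALSE]
  v <- v[order(v$strain_id, v$chromosome, v$position), , drop = FALSE]
  rownames(v) <- NULL
  attr(v, "n_missing_quality") <- n_missing
  class(v) <- c("variant_table", "data.frame")
  v
}

#' Read per-strain variant calls
#'
#' Accepts either a VCF (extension \code{.vcf}) or the simple TSV dialect
#' with columns \code{strain, chrom, pos, ref, alt, qual}. Records below
#' \code{min_quality} or with a missing quality are dropped (the number of
#' missing-quality records is reported in attribute
#' \code{n_missing_quality}); multi-allelic records are split into one row
#' per alternative allele. All calls are treated as homozygous (inbred
#' strain panel).
#'
#' @param path input file
#' @param min_quality minimum phred-scaled quality to retain (default 25)
#' @return data.frame of class \code{variant_table} with columns
#'   strain_id, chromosome, position, ref_allele, alt_allele, kind, quality
#' @export
read_variants <- function(path, min_quality = 25) {
  stopifnot(min_quality >= 0)
  if (grepl("\\.vcf(\\.gz)?$", path)) read_variants_vcf(path, min_quality)
  else read_variants_tsv(path, min_quality)
}

#' @rdname read_variants
#' @export
read_variants_tsv <- function(path, min_quality = 25) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(qual = "character"))
  need <- c("strain", "chrom", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(v)))
    stop("variant TSV must have columns ", paste(need, collapse = ", "))
  if (nrow(v) == 0) {
    out <- data.frame(strain_id = character(0), chromosome = character(0),
                      position = integer(0), ref_allele = character(0),
                      alt_allele = character(0), kind = character(0),
                      quality = numeric(0), stringsAsFactors = FALSE)
    return(.finish_variants(out, min_quality, 0L))
  }
  # split multi-allelic rows (comma-separated alt)
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(v)), lengths(alts))
  qual <- suppressWarnings(as.numeric(ifelse(v$qual %in% c(".", ""), NA, v$qual)))
  if (any(is.na(suppressWarnings(as.integer(v$pos)))))
    stop("malformed variant record: non-integer position")
  out <- data.frame(
    strain_id = v$strain[idx],
    chromosome = as.character(v$chrom[idx]),
    position = as.integer(v$pos)[idx],
    ref_allele = toupper(v$ref[idx]),
    alt_allele = toupper(unlist(alts)),
    quality = qual[idx],
    stringsAsFactors = FALSE
  )
  .finish_variants(out, min_quality, 0L)
}

#' @rdname read_variants
#' @export
read_variants_vcf <- function(path, min_quality = 25) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  strains <- colnames(gt)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rows <- vector("list", length(strains))
  for (s in seq_along(strains)) {
    # first allele index of the (homozygous) genotype call
    a <- sub("^([0-9.]+)[/|].*$", "\\1", gt[, s])
    a <- suppressWarnings(as.integer(ifelse(a %in% c(".", NA), NA, a)))
    carried <- which(!is.na(a) & a > 0L)
    if (!length(carried)) next
    rows[[s]] <- data.frame(
      strain_id = strains[s],
      chromosome = fix[carried, "CHROM"],
      position = as.integer(fix[carried, "POS"]),
      ref_allele = toupper(fix[carried, "REF"]),
      alt_allele = toupper(vapply(carried, function(i) alts[[i]][a[i]], character(1))),
      quality = qual[carried],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(strain_id = character(0), chromosome = character(0),
                      position = integer(0), ref_allele = character(0),
                      alt_allele = character(0), quality = numeric(0),
                      stringsAsFactors = FALSE)
  .finish_variants(out, min_quality, 0L)
}

#' Write a variant table in the TSV dialect
#' @param variants variant_table (or compatible data.frame)
#' @param path output file
#' @export
write_variants_tsv <- function(variants, path) {
  out <- data.frame(strain = variants$strain_id, chrom = variants$chromosome,
                    pos = variants$position, ref = variants$ref_allele,
                    alt = variants$alt_allele, qual = variants$quality)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as a multi-sample VCF
#'
#' Minimal VCFv4.2 with homozygous GT fields; one ALT per record (records
#' are not merged across strains sharing a site unless alleles coincide).
#' @param variants variant_table
#' @param strains full strain panel (column order in the VCF)
#' @param path output file
#' @export
write_variants_vcf <- function(variants, strains, path) {
  key <- paste(variants$chromosome, variants$position,
               variants$ref_allele, variants$alt_allele, sep = "\r")
  sites <- !duplicated(key)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", strains), collapse = "\t")), con)
  carriers <- split(variants$strain_id, key)
  quals <- tapply(variants$quality, key, min)
  v <- variants[sites, , drop = FALSE]
  v <- v[order(v$chromosome, v$position), , drop = FALSE]
  k <- paste(v$chromosome, v$position, v$ref_allele, v$alt_allele, sep = "\r")
  for (i in seq_len(nrow(v))) {
    gts <- ifelse(strains %in% carriers[[k[i]]], "1/1", "0/0")
    writeLines(paste(c(v$chromosome[i], v$position[i], ".", v$ref_allele[i],
                       v$alt_allele[i], format(quals[[k[i]]]), "PASS", ".",
                       "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a per-gene, per-tissue expression table
#'
#' TSV with columns \code{gene_id, tissue, level, presence}. Gene x tissue
#' pairs absent from the table are treated as (level 0, presence 0) by the
#' classification functions.
#'
#' @param path TSV file
#' @return data.frame with the four columns
#' @export
read_expression_table <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "level", "presence")
  if (!all(need %in% names(e)))
    stop("expression table must have columns ", paste(need, collapse = ", "))
  if (any(is.na(e$presence)) || any(e$presence < 0 | e$presence > 1))
    stop("presence score outside [0, 1]")
  if (any(is.na(e$level)) || any(e$level < 0))
    stop("negative or missing expression level")
  e[, need]
}

#' Write an expression table
#' @param expr data.frame with gene_id, tissue, level, presence
#' @param path output file
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST outfmt-6-like hit table
#'
#' Tab-separated with at least \code{qseqid sseqid pident length} and a
#' final \code{bitscore} column (the standard 12-column layout, or any
#' headered TSV containing those four names).
#'
#' @param path hit table file
#' @return data.frame with qseqid, sseqid, pident, length, bitscore
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1)
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (grepl("qseqid", first)) {
    h <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    h <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(h) != length(std)) stop("expected ", length(std), " columns, got ", ncol(h))
    names(h) <- std
  }
  need <- c("qseqid", "sseqid", "pident", "length", "bitscore")
  if (!all(need %in% names(h))) stop("hit table lacks required columns")
  if (any(h$pident < 0 | h$pident > 100)) stop("percent identity outside [0, 100]")
  if (any(h$length < 1)) stop("aligned length < 1")
  h[, need]
}

#' Write a hit table (headered outfmt-6-like TSV)
#' @param hits data.frame with qseqid, sseqid, pident, length, bitscore
#' @param path output file
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models to GFF3
#' @param models list of gene_model objects
#' @param path output file
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  tab <- gene_model_table(models)
  o <- order(tab$chromosome, tab$gene_start)
  for (gm in models[o]) {
    gid <- gm$gene_id
    mid <- paste0(gid, ".1")
    line <- function(type, s, e, attrs, phase = ".")
      paste(gm$chromosome, "pollensel", type, s, e, ".", gm$strand, phase,
            attrs, sep = "\t")
    writeLines(line("gene", gm$gene_start, gm$gene_end, paste0("ID=", gid)), con)
    writeLines(line("mRNA", gm$gene_start, gm$gene_end,
                    paste0("ID=", mid, ";Parent=", gid)), con)
    cds <- gm$cds[order(gm$cds[, "start"]), , drop = FALSE]
    # phase of each CDS piece in transcript order
    tr <- if (gm$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    lens <- cds[tr, "end"] - cds[tr, "start"] + 1L
    phase_tr <- c(0L, cumsum(lens)[-length(lens)]) %% 3L
    phase <- integer(nrow(cds)); phase[tr] <- (3L - phase_tr) %% 3L
    for (i in seq_len(nrow(cds)))
      writeLines(line("CDS", cds[i, "start"], cds[i, "end"],
                      paste0("ID=", mid, ".cds;Parent=", mid), phase[i]), con)
  }
  invisible(path)
}
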