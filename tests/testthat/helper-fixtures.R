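# Fixtures built in code and independent oracles used across test files.
# The oracles are deliberately naive (brute force, enumeration) and share
# no code with the implementation paths they check.

# --- tiny GFF3 / FASTA fixtures -----------------------------------------

write_toy_gff3 <- function(path, strand = "+", cds = list(c(1, 9), c(20, 25)),
                           gene_id = "gA", chrom = "chr1", extra_lines = NULL) {
  span <- range(unlist(cds))
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, span[1], span[2],
            strand, gene_id),
    sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s", chrom,
            span[1], span[2], strand, gene_id, gene_id),
    vapply(cds, function(iv)
      sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              chrom, iv[1], iv[2], strand, gene_id, gene_id), character(1)),
    extra_lines)
  writeLines(lines, path)
  path
}

# a single-interval plus-strand gene over an explicit CDS, with its genome
make_gene_fixture <- function(cds, chrom = "chr1", gene_id = "gX",
                              strand = "+", pad = 10) {
  set.seed(nchar(cds))
  flank <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
  locus <- if (strand == "+") cds else revcomp(cds)
  genome <- Biostrings::DNAStringSet(
    setNames(paste0(flank(pad), locus, flank(pad)), chrom))
  gm <- gene_model(gene_id, chrom, strand,
                   data.frame(start = pad + 1, end = pad + nchar(cds)))
  list(gm = gm, genome = genome)
}

variant_row <- function(strain, chrom, pos, ref, alt, qual = 40) {
  v <- data.frame(strain_id = strain, chromosome = chrom, position = as.integer(pos),
                  ref_allele = ref, alt_allele = alt,
                  kind = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "indel"),
                  quality = qual, stringsAsFactors = FALSE)
  class(v) <- c("variant_table", "data.frame")
  v
}

bind_variants <- function(...) {
  v <- do.call(rbind, lapply(list(...), as.data.frame))
  class(v) <- c("variant_table", "data.frame")
  v
}

# --- diversity oracles ---------------------------------------------------

# pi by direct averaging of pairwise per-site Hamming distances over a
# strain x site allele matrix (characters)
oracle_pi <- function(allele_matrix, L) {
  n <- nrow(allele_matrix)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(allele_matrix[i, ] != allele_matrix[j, ])
  tot / choose(n, 2) / L
}

oracle_theta <- function(S, n, L) {
  a <- 0
  for (i in 1:(n - 1)) a <- a + 1 / i
  S / a / L
}

# --- dN/dS oracle: recursive path enumeration ----------------------------

# average syn/nonsyn step counts over all minimal substitution paths
# between two codons, discarding paths through stop codons (all kept if
# every path is discarded) -- written independently of codon_differences
oracle_codon_diff <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("U", "T", names(code))
  walk <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(syn = 0, nonsyn = 0, stopped = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      step_syn <- as.numeric(code[[nxt]] != "*" && code[[nxt]] == code[[cur]])
      step_stop <- as.numeric(code[[nxt]] == "*")
      for (tail in walk(nxt, target)) {
        out[[length(out) + 1]] <- c(syn = step_syn + tail[["syn"]],
                                    nonsyn = (1 - step_syn) + tail[["nonsyn"]],
                                    stopped = max(step_stop, tail[["stopped"]]))
      }
    }
    out
  }
  m <- do.call(rbind, walk(c1, c2))
  keep <- m[, "stopped"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(syn = mean(m[keep, "syn"]), nonsyn = mean(m[keep, "nonsyn"]))
}

# --- RSCU oracle: direct tally ------------------------------------------

oracle_rscu_variance <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("U", "T", names(code))
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  cods <- cods[code[cods] != "*"]
  vals <- c()
  for (aa in unique(code[cods])) {
    fam <- names(code)[code == aa & code != "*"]
    cnt <- sapply(fam, function(cc) sum(cods == cc))
    vals <- c(vals, cnt * length(fam) / sum(cnt))
  }
  mean((vals - mean(vals))^2)
}

# --- misc ----------------------------------------------------------------

toy_expression <- function(rows) {
  # rows: list of c(gene, tissue, level, presence)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], tissue = r[[2]], level = as.numeric(r[[3]]),
               presence = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

toy_tissue_side <- c(pollen_mature = "pollen", pollen = "pollen",
                     pollen_tube = "pollen",
                     pollen_tube_a = "pollen", pollen_tube_b = "pollen",
                     leaf = "sporophyte", root = "sporophyte",
                     xylem = "sporophyte", guard_cell = "sporophyte",
                     root_hair = "sporophyte", stem = "sporophyte",
                     seed = "sporophyte")
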