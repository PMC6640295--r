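# Site-class partitioning of coding sequences (0-fold / 4-fold degenerate
# positions as proxies for nonsynonymous / synonymous sites) and per-gene
# diversity statistics: Watterson's theta, nucleotide diversity pi, and
# site-frequency spectra for the gamma-DFE fit. Codons carrying more than
# one SNP across the panel, or any ambiguity, are masked.

#' Classify every CDS position by codon degeneracy
#'
#' A position is four_fold if all three alternative bases preserve the
#' amino acid, zero_fold if none does, other in between. All three
#' positions of a codon are masked when the codon contains an ambiguity
#' code or when more than one of its positions is polymorphic in the
#' panel.
#'
#' @param ref_cds reference CDS (transcript orientation)
#' @param snp_positions CDS positions polymorphic in the panel (any
#'   strain); used for the >1-SNP-per-codon masking rule
#' @return character vector (length = CDS length) with values zero_fold,
#'   four_fold, other, masked; attribute \code{n_masked_codons}
#' @export
classify_sites <- function(ref_cds, snp_positions = integer(0)) {
  codons <- split_codons(toupper(ref_cds))
  deg <- codon_degeneracy()
  cls <- character(3L * length(codons))
  known <- codons %in% rownames(deg)
  for (i in seq_along(codons)) {
    j <- (i - 1L) * 3L
    if (!known[i]) { cls[j + 1:3] <- "masked"; next }
    d <- deg[codons[i], ]
    cls[j + 1:3] <- ifelse(d == 3L, "four_fold", ifelse(d == 0L, "zero_fold", "other"))
  }
  masked_amb <- sum(!known)
  # mask codons with >1 polymorphic position
  snp_codon <- (unique(snp_positions) - 1L) %/% 3L + 1L
  multi <- as.integer(names(which(table(snp_codon) > 1L)))
  for (i in multi) cls[(i - 1L) * 3L + 1:3] <- "masked"
  attr(cls, "n_masked_codons") <- masked_amb + length(multi)
  cls
}

#' Watterson's theta per site
#'
#' theta = S / (a_{n-1} * L) with a_{n-1} the harmonic number.
#'
#' @param S number of segregating sites
#' @param n sample size (number of strains)
#' @param L number of sites surveyed
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(n >= 2, L >= 1, S >= 0)
  S / (harmonic_number(n - 1L) * L)
}

#' Nucleotide diversity per site from allele counts
#'
#' pi = sum over polymorphic sites of the expected pairwise difference
#' 2 c (n - c) / (n (n - 1)), divided by L, with c the alternative-allele
#' count at the site.
#'
#' @param alt_counts alternative-allele counts of the polymorphic sites
#' @param n sample size
#' @param L number of sites surveyed
#' @export
nucleotide_diversity <- function(alt_counts, n, L) {
  stopifnot(n >= 2, L >= 1, all(alt_counts >= 0), all(alt_counts <= n))
  sum(2 * alt_counts * (n - alt_counts) / (n * (n - 1))) / L
}

#' Site-frequency spectra of a gene (or pooled set of sites)
#'
#' Counts polymorphic unmasked sites by alternative-allele count
#' (unfolded) or minor-allele count (folded). Sites listed in
#' \code{missing_positions} (a base not reliably called in every strain)
#' are dropped and L adjusted; triallelic sites (same position, more than
#' one alternative allele) are excluded and counted.
#'
#' @param snps data.frame with cds_pos and strain_id (one row per carrier
#'   call), e.g. \code{gene_variants()$snps}
#' @param site_classes output of \code{\link{classify_sites}}
#' @param n haploid sample size (number of strains)
#' @param fold fold the spectrum to minor-allele counts (default TRUE)
#' @param missing_positions CDS positions lacking a reliable call in some
#'   strain
#' @return object of class \code{sfs_pair}: list with n, fold, sfs_n,
#'   sfs_s (length n-1 unfolded or floor(n/2) folded), L_n, L_s, S_n,
#'   S_s, D_n = D_s = 0, n_triallelic
#' @export
build_sfs <- function(snps, site_classes, n, fold = TRUE,
                      missing_positions = integer(0)) {
  stopifnot(n >= 2)
  usable <- site_classes %in% c("zero_fold", "four_fold")
  if (length(missing_positions)) usable[missing_positions] <- FALSE
  L_n <- sum(site_classes == "zero_fold" & usable)
  L_s <- sum(site_classes == "four_fold" & usable)
  K <- if (fold) n %/% 2L else n - 1L
  sfs_n <- numeric(K); sfs_s <- numeric(K)
  n_tri <- 0L
  if (nrow(snps)) {
    snps <- snps[usable[snps$cds_pos], , drop = FALSE]
  }
  if (nrow(snps)) {
    # triallelic: more than one distinct alt allele at a position
    if (!is.null(snps$alt_t)) {
      n_alleles <- tapply(snps$alt_t, snps$cds_pos, function(a) length(unique(a)))
      tri <- as.integer(names(n_alleles)[n_alleles > 1L])
      n_tri <- length(tri)
      if (n_tri) snps <- snps[!snps$cds_pos %in% tri, , drop = FALSE]
    }
  }
  if (nrow(snps)) {
    counts <- tapply(snps$strain_id, snps$cds_pos, function(s) length(unique(s)))
    pos <- as.integer(names(counts))
    cnt <- as.integer(counts)
    seg <- cnt >= 1L & cnt <= n - 1L  # fixed differences are not polymorphisms
    pos <- pos[seg]; cnt <- cnt[seg]
    if (fold) cnt <- pmin(cnt, n - cnt)
    for (k in seq_along(pos)) {
      cls <- site_classes[pos[k]]
      if (cls == "zero_fold") sfs_n[cnt[k]] <- sfs_n[cnt[k]] + 1
      else sfs_s[cnt[k]] <- sfs_s[cnt[k]] + 1
    }
  }
  structure(list(n = n, fold = fold, sfs_n = sfs_n, sfs_s = sfs_s,
                 L_n = L_n, L_s = L_s, S_n = sum(sfs_n), S_s = sum(sfs_s),
                 D_n = 0, D_s = 0, n_triallelic = n_tri),
            class = "sfs_pair")
}

#' @export
print.sfs_pair <- function(x, ...) {
  cat(sprintf("<sfs_pair n=%d %s | S_n=%g over L_n=%g, S_s=%g over L_s=%g>\n",
              x$n, if (x$fold) "folded" else "unfolded",
              x$S_n, x$L_n, x$S_s, x$L_s))
  invisible(x)
}

#' Sum per-gene SFS pairs into one pooled pair
#' @param pairs list of sfs_pair objects with identical n and fold
#' @export
sum_sfs_pairs <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  n <- pairs[[1]]$n; fold <- pairs[[1]]$fold
  stopifnot(all(vapply(pairs, function(p) p$n == n && p$fold == fold, logical(1))))
  add <- function(f) Reduce(`+`, lapply(pairs, `[[`, f))
  structure(list(n = n, fold = fold,
                 sfs_n = add("sfs_n"), sfs_s = add("sfs_s"),
                 L_n = add("L_n"), L_s = add("L_s"),
                 S_n = add("S_n"), S_s = add("S_s"),
                 D_n = add("D_n"), D_s = add("D_s"),
                 n_triallelic = add("n_triallelic")),
            class = "sfs_pair")
}

#' Per-gene diversity statistics at 0-fold and 4-fold sites
#'
#' @param models list of gene_model objects
#' @param genome reference sequences
#' @param variants variant_table (quality filtered)
#' @param n_strains panel size
#' @param fold fold the spectra (default TRUE)
#' @return list with \code{stats} (data.frame: gene_id, n, L_n, L_s, S_n,
#'   S_s, theta_n, theta_s, pi_n, pi_s) and \code{sfs} (named list of
#'   per-gene sfs_pair objects)
#' @export
gene_diversity <- function(models, genome, variants, n_strains, fold = TRUE) {
  sfs_list <- list()
  rows <- lapply(models, function(gm) {
    ref <- extract_cds(gm, genome)
    snps <- gene_variants(gm, variants)$snps
    cls <- classify_sites(ref, snps$cds_pos)
    sp <- build_sfs(snps, cls, n_strains, fold = fold)
    sfs_list[[gm$gene_id]] <<- sp
    # allele counts of retained polymorphic sites, for pi
    stat_for <- function(sfs, L) {
      if (L == 0) return(c(NA_real_, NA_real_))
      S <- sum(sfs)
      counts <- rep(seq_along(sfs), times = sfs)
      if (fold) {
        # folded bin i holds minor-allele count i; pairwise term is
        # symmetric in c vs n-c so the minor count is sufficient
      }
      c(watterson_theta(S, n_strains, L),
        nucleotide_diversity(counts, n_strains, L))
    }
    tn <- stat_for(sp$sfs_n, sp$L_n)
    ts <- stat_for(sp$sfs_s, sp$L_s)
    if (sp$L_n == 0 || sp$L_s == 0)
      warning(gm$gene_id, ": no usable sites in one class, statistics NA")
    data.frame(gene_id = gm$gene_id, n = n_strains,
               L_n = sp$L_n, L_s = sp$L_s, S_n = sp$S_n, S_s = sp$S_s,
               theta_n = tn[1], theta_s = ts[1], pi_n = tn[2], pi_s = ts[2],
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  list(stats = stats, sfs = sfs_list)
}

#' Write a set of per-gene spectra as JSON
#' @param sfs named list of sfs_pair objects
#' @param path output file
#' @export
write_sfs_json <- function(sfs, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write SFS JSON")
  x <- lapply(sfs, function(p) p[c("n", "fold", "sfs_n", "sfs_s",
                                   "L_n", "L_s", "D_n", "D_s")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-gene spectra from JSON
#' @param path JSON file written by \code{\link{write_sfs_json}}
#' @export
read_sfs_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read SFS JSON")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(p) {
    structure(list(n = p$n, fold = p$fold,
                   sfs_n = as.numeric(p$sfs_n), sfs_s = as.numeric(p$sfs_s),
                   L_n = p$L_n, L_s = p$L_s,
                   S_n = sum(p$sfs_n), S_s = sum(p$sfs_s),
                   D_n = p$D_n, D_s = p$D_s, n_triallelic = 0L),
              class = "sfs_pair")
  })
}
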