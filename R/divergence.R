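# Pairwise divergence: reciprocal-best-hit orthology from BLAST-like hit
# tables, protein-guided back-translation to codon alignments, and
# counting-method dN/dS (Nei-Gojobori site counting with equal-weight
# averaging over minimal substitution paths and Jukes-Cantor correction).

#' Best hit per query of a hit table
#'
#' Ties on bit score are broken by higher identity, then lexicographic
#' subject ID, so the result is deterministic.
#' @param hits data.frame qseqid, sseqid, pident, length, bitscore
#' @return data.frame with one row per query
#' @keywords internal
best_hits <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is retained iff b is a's top hit, a is b's top hit, and
#' both retained hit rows satisfy the identity and aligned-length
#' thresholds.
#'
#' @param hits_ab,hits_ba hit tables in the two directions
#' @param min_identity minimum percent identity (default 30)
#' @param min_length minimum aligned length in amino acids (default 150)
#' @return data.frame: gene_id_a, gene_id_b, percent_identity,
#'   aligned_length
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 min_identity = 30, min_length = 150) {
  ab <- best_hits(hits_ab)
  ba <- best_hits(hits_ba)
  back <- ba$sseqid[match(ab$sseqid, ba$qseqid)]
  mutual <- !is.na(back) & back == ab$qseqid
  ab <- ab[mutual, , drop = FALSE]
  ba_row <- ba[match(ab$sseqid, ba$qseqid), , drop = FALSE]
  ok <- ab$pident >= min_identity & ab$length >= min_length &
    ba_row$pident >= min_identity & ba_row$length >= min_length
  out <- data.frame(gene_id_a = ab$qseqid[ok], gene_id_b = ab$sseqid[ok],
                    percent_identity = ab$pident[ok],
                    aligned_length = ab$length[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned amino acid is replaced by its source codon and each gap by
#' "---" (pal2nal-style). The ungapped proteins must translate exactly
#' from their CDS (terminal stop trimmed); a mismatch is a hard error
#' naming the position.
#'
#' @param protein_a,protein_b aligned protein sequences (equal length,
#'   "-" for gaps)
#' @param cds_a,cds_b source coding sequences
#' @return list with codon_a, codon_b (strings of length 3 x alignment
#'   length)
#' @export
backtranslate_alignment <- function(protein_a, protein_b, cds_a, cds_b) {
  if (nchar(protein_a) != nchar(protein_b))
    stop("aligned proteins differ in length")
  bt_one <- function(prot, cds, label) {
    codons <- split_codons(toupper(cds))
    if (length(codons) && translate_codons(codons[length(codons)]) == "*")
      codons <- codons[-length(codons)]
    aa_cds <- translate_codons(codons)
    chars <- strsplit(prot, "")[[1]]
    res <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") { res[i] <- "---"; next }
      k <- k + 1L
      if (k > length(codons))
        stop(label, ": protein longer than CDS translation")
      if (aa_cds[k] != chars[i])
        stop(label, ": translation mismatch at protein position ", i,
             " (CDS codon ", k, " gives ", aa_cds[k], ", alignment has ",
             chars[i], ")")
      res[i] <- codons[k]
    }
    if (k != length(codons))
      stop(label, ": CDS has ", length(codons) - k, " unaligned trailing codon(s)")
    paste(res, collapse = "")
  }
  list(codon_a = bt_one(protein_a, cds_a, "sequence a"),
       codon_b = bt_one(protein_b, cds_b, "sequence b"))
}

# Synonymous-site count of a codon: sum over positions of the fraction of
# the three one-step changes that are synonymous (changes to stop codons
# count as nonsynonymous).
.syn_sites_per_codon <- function() {
  if (!is.null(.pollensel_cache$syn_sites)) return(.pollensel_cache$syn_sites)
  deg <- codon_degeneracy()
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  s <- numeric(nrow(deg)); names(s) <- rownames(deg)
  for (cd in rownames(deg)) {
    tot <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        x <- cd; substr(x, p, p) <- b
        if (gc[[x]] != "*" && gc[[x]] == gc[[cd]]) tot <- tot + 1
      }
    }
    s[cd] <- tot / 3
  }
  .pollensel_cache$syn_sites <- s
  s
}

.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Synonymous/nonsynonymous differences between two codons
#'
#' Averages with equal weight over all minimal substitution paths;
#' paths passing through a stop codon are discarded (all paths are kept
#' if every path would be discarded).
#'
#' @param c1,c2 codons (sense codons, no ambiguity)
#' @return c(syn, nonsyn) average difference counts
#' @export
codon_differences <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .pollensel_cache$codon_diff[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  paths <- list()
  for (ord in .perms[[as.character(k)]]) {
    cur <- c1
    syn <- 0; nonsyn <- 0; through_stop <- FALSE
    for (p in pos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") through_stop <- TRUE
      if (gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*") syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(syn, nonsyn, through_stop)
  }
  m <- do.call(rbind, paths)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  res <- c(syn = mean(m[keep, 1]), nonsyn = mean(m[keep, 2]))
  if (is.null(.pollensel_cache$codon_diff))
    .pollensel_cache$codon_diff <- new.env(parent = emptyenv())
  assign(key, res, envir = .pollensel_cache$codon_diff)
  res
}

#' Jukes-Cantor multiple-hit correction
#' @param p proportion of observed differences, in [0, 3/4)
#' @return corrected distance d = -(3/4) log(1 - 4p/3)
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN/dS by the Nei-Gojobori counting method
#'
#' Codon columns containing a gap, an ambiguity code or a stop codon in
#' either sequence are excluded. Site counts are averaged between the two
#' sequences; observed differences are resolved by equal-weight averaging
#' over minimal substitution paths; the proportions are corrected with
#' Jukes-Cantor. Pairs with dS above \code{ds_max} (default 2) or an
#' undefined correction are flagged excluded; omega is +Inf when dS = 0
#' with dN > 0 and NA when both are 0.
#'
#' @param codon_a,codon_b aligned codon sequences (equal length, multiple
#'   of 3; "---" gaps allowed)
#' @param ds_max dS ceiling above which the pair is excluded
#' @return list of class \code{dnds_estimate}: dN, dS, omega, pN, pS,
#'   N_sites, S_sites, N_diffs, S_diffs, n_codons (comparable codons),
#'   excluded, reason
#' @export
pairwise_dnds <- function(codon_a, codon_b, ds_max = 2) {
  ca <- split_codons(toupper(codon_a))
  cb <- split_codons(toupper(codon_b))
  if (length(ca) != length(cb)) stop("codon alignments differ in length")
  gc <- genetic_code()
  ok <- ca %in% names(gc) & cb %in% names(gc) &
    gc[ca] != "*" & gc[cb] != "*"
  ok[is.na(ok)] <- FALSE
  ca <- ca[ok]; cb <- cb[ok]
  mk <- function(dN, dS, omega, pN = NA, pS = NA, Ns = NA, Ss = NA,
                 Nd = NA, Sd = NA, nc = length(ca),
                 excluded = FALSE, reason = NA_character_)
    structure(list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
                   N_sites = Ns, S_sites = Ss, N_diffs = Nd, S_diffs = Sd,
                   n_codons = nc, excluded = excluded, reason = reason),
              class = "dnds_estimate")
  if (!length(ca))
    return(mk(NA, NA, NA, excluded = TRUE, reason = "no comparable codons"))
  ssc <- .syn_sites_per_codon()
  S_sites <- (sum(ssc[ca]) + sum(ssc[cb])) / 2
  N_sites <- 3 * length(ca) - S_sites
  diff <- which(ca != cb)
  S_d <- 0; N_d <- 0
  for (i in diff) {
    d <- codon_differences(ca[i], cb[i])
    S_d <- S_d + d[["syn"]]
    N_d <- N_d + d[["nonsyn"]]
  }
  pS <- if (S_sites > 0) S_d / S_sites else 0
  pN <- if (N_sites > 0) N_d / N_sites else 0
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  if (is.na(dS) || is.na(dN))
    return(mk(dN, dS, NA, pN, pS, N_sites, S_sites, N_d, S_d,
              excluded = TRUE, reason = "saturated (p >= 3/4)"))
  omega <- if (dS > 0) dN / dS else if (dN > 0) Inf else NA_real_
  excluded <- dS > ds_max
  mk(dN, dS, omega, pN, pS, N_sites, S_sites, N_d, S_d,
     excluded = excluded,
     reason = if (excluded) paste0("dS > ", ds_max) else NA_character_)
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("<dnds dN=%.4g dS=%.4g omega=%.4g over %d codons%s>\n",
              x$dN, x$dS, x$omega, x$n_codons,
              if (x$excluded) paste0(" EXCLUDED: ", x$reason) else ""))
  invisible(x)
}

#' dN/dS for a table of ortholog pairs
#'
#' Aligns nothing: the pairs are assumed gap-free or pre-aligned at the
#' protein level (pass alignments via \code{alignments}, a named list of
#' \code{list(protein_a, protein_b)} keyed by gene_id_a; identical-length
#' pairs default to the trivial alignment).
#'
#' @param pairs output of \code{\link{reciprocal_best_hits}}
#' @param cds_a,cds_b named character vectors of coding sequences
#' @param alignments optional named list of protein alignments
#' @param ds_max dS ceiling
#' @return data.frame: gene_id_a, gene_id_b, dN, dS, omega, n_codons,
#'   excluded, reason
#' @export
divergence_table <- function(pairs, cds_a, cds_b, alignments = NULL, ds_max = 2) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_id_a[i]; gb <- pairs$gene_id_b[i]
    a <- cds_a[[ga]]; b <- cds_b[[gb]]
    if (!is.null(alignments) && ga %in% names(alignments)) {
      al <- alignments[[ga]]
      cod <- backtranslate_alignment(al$protein_a, al$protein_b, a, b)
    } else {
      trim <- function(x) {
        cs <- split_codons(toupper(x))
        if (translate_codons(cs[length(cs)]) == "*") cs <- cs[-length(cs)]
        paste(cs, collapse = "")
      }
      ta <- trim(a); tb <- trim(b)
      if (nchar(ta) != nchar(tb))
        stop("pair ", ga, "/", gb, " needs a protein alignment (unequal CDS)")
      cod <- list(codon_a = ta, codon_b = tb)
    }
    est <- pairwise_dnds(cod$codon_a, cod$codon_b, ds_max = ds_max)
    data.frame(gene_id_a = ga, gene_id_b = gb, dN = est$dN, dS = est$dS,
               omega = est$omega, n_codons = est$n_codons,
               excluded = est$excluded, reason = est$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
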