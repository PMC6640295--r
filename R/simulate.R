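# Seeded synthetic data with the statistical structure the analysis
# assumes: a multi-chromosome gene complement with introns, presence-
# scored expression across pollen and sporophytic tissues, a panel of
# fully homozygous strains whose 0-fold variants are drawn from class-
# specific gamma DFEs (4-fold variants neutral), and diverged ortholog
# pairs evolved at class-specific dN/dS. Every stage is deterministic
# under the configured seed; allele frequencies are drawn independently
# per site from the expected sample-frequency distribution (no linkage),
# using the same weights as the DFE estimator (sfs_weights).

.default_tissues <- function() {
  list(
    pollen = c("uninucleate", "bicellular", "tricellular", "mature_pollen",
               "sperm_cell", "pollen_tube"),
    sporophyte = c("leaf", "root", "stem", "seedling", "flower", "silique",
                   "seed", "guard_cell", "xylem", "root_hair")
  )
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: an
#' 80-strain homozygous panel, 7 pollen-side expression sets (the two
#' pollen-tube sets are emitted separately and merged by the classifier)
#' and 10 sporophytic tissues, class fractions matching the observed gene
#' complement (9.4% pollen-specific and 33.2% sporophyte-specific of
#' expressed genes, 20.7% unexpressed overall), a per-site scaled
#' mutation rate of 0.005, a gamma DFE with shape 0.3 and mean 4Nes 2000
#' for sporophyte-specific genes relaxed fivefold (400) in pollen-
#' specific genes, stop-gain and frameshift injection rates twice as high
#' in the pollen class, and divergence at the observed median rates
#' (dS 0.15; dN/dS 0.208 pollen vs 0.164 sporophyte).
#'
#' @param seed integer seed; all four generators derive their streams
#'   from it
#' @param n_chromosomes,genes_per_chromosome genome layout
#' @param n_strains homozygous strain panel size
#' @param class_fractions named fractions (pollen_specific,
#'   sporophyte_specific, shared, not_expressed) summing to 1
#' @param dfe named list per class: c(shape, mean_S) of the deleterious
#'   gamma (mean on the 4Nes scale; mean_S = 0 switches selection off)
#' @param theta_site per-site scaled mutation rate at synonymous sites
#' @param stop_gain_rate,indel_rate per-gene injection probabilities per
#'   class (named vectors)
#' @param omega,ds per-class dN/dS and branch dS for the diverged
#'   orthologs
#' @param gene_codons range of internal codon counts per gene
#' @param introns_range range of intron counts per gene
#' @param intron_length range of intron lengths
#' @param intergenic range of intergenic gap lengths
#' @param single_tissue_fraction,broad_fraction fractions of sporophyte-
#'   specific genes limited to one cell type (guard cell, xylem or root
#'   hair) or expressed in at least five tissues
#' @param decoy_rate expected number of sub-threshold-quality decoy
#'   records per gene (exercises the phred filter)
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 5,
                       genes_per_chromosome = 20,
                       n_strains = 80,
                       class_fractions = c(pollen_specific = 0.094,
                                           sporophyte_specific = 0.332,
                                           shared = 0.367,
                                           not_expressed = 0.207),
                       dfe = list(pollen_specific = c(shape = 0.3, mean_S = 400),
                                  sporophyte_specific = c(shape = 0.3, mean_S = 2000),
                                  shared = c(shape = 0.3, mean_S = 2000),
                                  not_expressed = c(shape = 0.3, mean_S = 2000)),
                       theta_site = 0.005,
                       stop_gain_rate = c(pollen_specific = 0.30,
                                          sporophyte_specific = 0.15,
                                          shared = 0.15,
                                          not_expressed = 0.15),
                       indel_rate = c(pollen_specific = 0.30,
                                      sporophyte_specific = 0.15,
                                      shared = 0.15,
                                      not_expressed = 0.15),
                       omega = c(pollen_specific = 0.208,
                                 sporophyte_specific = 0.164,
                                 shared = 0.164,
                                 not_expressed = 0.164),
                       ds = 0.15,
                       gene_codons = c(80, 250),
                       introns_range = c(0, 4),
                       intron_length = c(60, 200),
                       intergenic = c(300, 800),
                       single_tissue_fraction = 0.15,
                       broad_fraction = 0.45,
                       decoy_rate = 0.5) {
  classes <- c("pollen_specific", "sporophyte_specific", "shared", "not_expressed")
  stopifnot(all(classes %in% names(class_fractions)),
            abs(sum(class_fractions) - 1) < 1e-6,
            theta_site > 0, n_strains >= 4,
            all(vapply(dfe, function(p) p[["shape"]] > 0 && p[["mean_S"]] >= 0,
                       logical(1))))
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              n_strains = n_strains, class_fractions = class_fractions[classes],
              dfe = dfe, theta_site = theta_site,
              stop_gain_rate = stop_gain_rate, indel_rate = indel_rate,
              omega = omega, ds = ds,
              gene_codons = gene_codons, introns_range = introns_range,
              intron_length = intron_length, intergenic = intergenic,
              tissues = .default_tissues(),
              single_tissue_fraction = single_tissue_fraction,
              broad_fraction = broad_fraction,
              decoy_rate = decoy_rate)
  class(cfg) <- "sim_config"
  cfg
}

.seed_for <- function(config, stage) {
  off <- c(genome = 0L, expression = 1L, variants = 2L, divergence = 3L)
  (config$seed + off[[stage]]) %% .Machine$integer.max
}

#' Simulate the reference genome, gene models and truth table
#'
#' Genes are laid out with random strand and 0-4 introns; every CDS has a
#' start codon, no internal stop and a terminal stop. The truth table
#' records each gene's life-stage class and the class parameters used by
#' the later stages.
#'
#' @param config sim_config
#' @param dir optional directory; when given, genome.fasta, genes.gff3
#'   and truth.tsv are written there
#' @return list with genome (DNAStringSet), models (list of gene_model),
#'   truth (data.frame) and, when written, the file paths
#' @export
simulate_genome <- function(config, dir = NULL) {
  set.seed(.seed_for(config, "genome"))
  bases <- c("A", "C", "G", "T")
  n_genes <- config$n_chromosomes * config$genes_per_chromosome
  classes <- if (n_genes)
    sample(names(config$class_fractions), n_genes, replace = TRUE,
           prob = config$class_fractions) else character(0)
  models <- list()
  chroms <- character(config$n_chromosomes)
  names(chroms) <- paste0("chr", seq_len(config$n_chromosomes))
  truth <- list()
  g <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    seqs <- character(0)
    at <- 0L  # current chromosome length
    for (k in seq_len(config$genes_per_chromosome)) {
      g <- g + 1L
      gid <- sprintf("g%04d", g)
      gap <- sample(config$intergenic[1]:config$intergenic[2], 1)
      n_cod <- sample(config$gene_codons[1]:config$gene_codons[2], 1)
      cds <- random_cds(n_cod)
      n_int <- sample(config$introns_range[1]:config$introns_range[2], 1)
      # intron insertion points: distinct codon boundaries inside the CDS
      cuts <- if (n_int > 0)
        sort(sample(seq_len(nchar(cds) %/% 3L - 1L), n_int) * 3L) else integer(0)
      ilens <- if (n_int > 0)
        sample(config$intron_length[1]:config$intron_length[2], n_int,
               replace = TRUE) else integer(0)
      pieces <- substring(cds, c(1L, cuts + 1L), c(cuts, nchar(cds)))
      introns <- vapply(ilens, function(l) paste0(
        "GT", paste(sample(bases, l - 4L, replace = TRUE), collapse = ""), "AG"),
        character(1))
      locus_t <- paste0(pieces[1],
                        paste0(vapply(seq_len(n_int), function(i)
                          paste0(introns[i], pieces[i + 1L]), character(1)),
                          collapse = ""))
      strand <- sample(c("+", "-"), 1)
      locus_g <- if (strand == "-") revcomp(locus_t) else locus_t
      gene_start <- at + gap + 1L
      gene_end <- gene_start + nchar(locus_g) - 1L
      # CDS intervals in transcript coordinates, then mapped to genomic
      t_starts <- c(1L, cuts + 1L) + c(0L, cumsum(ilens))
      t_ends <- t_starts + (c(cuts, nchar(cds)) - c(0L, cuts)) - 1L
      if (strand == "+") {
        iv <- data.frame(start = gene_start + t_starts - 1L,
                         end = gene_start + t_ends - 1L)
      } else {
        iv <- data.frame(start = gene_end - t_ends + 1L,
                         end = gene_end - t_starts + 1L)
      }
      models[[gid]] <- gene_model(gid, names(chroms)[ch], strand, iv,
                                  gene_start, gene_end)
      seqs <- c(seqs, paste(sample(bases, gap, replace = TRUE), collapse = ""),
                locus_g)
      at <- gene_end
      cls <- classes[g]
      breadth <- if (cls == "sporophyte_specific") {
        u <- stats::runif(1)
        if (u < config$single_tissue_fraction) 1L
        else if (u < config$single_tissue_fraction + config$broad_fraction)
          sample(5:length(config$tissues$sporophyte), 1)
        else sample(2:4, 1)
      } else NA_integer_
      single_type <- if (!is.na(breadth) && breadth == 1L)
        sample(c("guard_cell", "xylem", "root_hair"), 1) else NA_character_
      truth[[g]] <- data.frame(
        gene_id = gid, class = cls, chromosome = names(chroms)[ch],
        strand = strand, cds_length = nchar(cds), n_introns = n_int,
        shape = config$dfe[[cls]][["shape"]],
        mean_S = config$dfe[[cls]][["mean_S"]],
        theta_site = config$theta_site,
        stop_gain_rate = config$stop_gain_rate[[cls]],
        indel_rate = config$indel_rate[[cls]],
        omega = config$omega[[cls]], ds = config$ds,
        sp_breadth = breadth, sp_single_type = single_type,
        stringsAsFactors = FALSE)
    }
    tail_gap <- sample(config$intergenic[1]:config$intergenic[2], 1)
    seqs <- c(seqs, paste(sample(bases, tail_gap, replace = TRUE), collapse = ""))
    chroms[ch] <- paste(seqs, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(chroms)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0))
  out <- list(genome = genome, models = models, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(fasta = write_fasta(genome, file.path(dir, "genome.fasta")),
                   gff3 = write_gff3(models, file.path(dir, "genes.gff3")),
                   truth = {
                     p <- file.path(dir, "truth.tsv")
                     utils::write.table(truth, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
                     p
                   })
  }
  out
}

#' Simulate the presence-scored expression table
#'
#' Pollen-specific genes are present (score >= 0.9) only in pollen
#' tissues, sporophyte-specific genes only in the number of sporophytic
#' tissues recorded in the truth table, shared genes in both, silent
#' genes nowhere. The two pollen-tube sets are emitted as separate
#' tissues so the classifier's merging step is exercised.
#'
#' @param config sim_config
#' @param truth truth table from \code{\link{simulate_genome}}
#' @param dir optional output directory (expression.tsv)
#' @return list with expr (long data.frame), tissue_side (named vector)
#'   and optionally the path
#' @export
simulate_expression <- function(config, truth, dir = NULL) {
  set.seed(.seed_for(config, "expression"))
  pol <- config$tissues$pollen
  spo <- config$tissues$sporophyte
  emit_pol <- c(setdiff(pol, "pollen_tube"), "pollen_tube_a", "pollen_tube_b")
  rows <- list()
  level_present <- function(k) pmin(stats::rlnorm(k, log(800), 1) + 1, 20000)
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    present_pol <- character(0); present_spo <- character(0)
    if (cls %in% c("pollen_specific", "shared"))
      present_pol <- sample(pol, sample(seq_along(pol), 1))
    if (cls %in% c("sporophyte_specific", "shared")) {
      b <- truth$sp_breadth[i]
      if (is.na(b)) b <- sample(seq_along(spo), 1)  # shared genes: any breadth
      present_spo <- if (!is.na(truth$sp_single_type[i]))
        truth$sp_single_type[i] else sample(spo, b)
    }
    tissues <- c(emit_pol, spo)
    present <- tissues %in% c(present_spo,
                              if ("pollen_tube" %in% present_pol)
                                c(setdiff(present_pol, "pollen_tube"),
                                  sample(c("pollen_tube_a", "pollen_tube_b"),
                                         sample(1:2, 1)))
                              else present_pol)
    lev <- ifelse(present, level_present(length(tissues)),
                  stats::runif(length(tissues), 0, 50))
    prs <- ifelse(present, stats::runif(length(tissues), 0.9, 1),
                  stats::runif(length(tissues), 0, 0.85))
    rows[[i]] <- data.frame(gene_id = truth$gene_id[i], tissue = tissues,
                            level = lev, presence = prs,
                            stringsAsFactors = FALSE)
  }
  expr <- do.call(rbind, rows)
  tissue_side <- c(stats::setNames(rep("pollen", length(pol)), pol),
                   stats::setNames(rep("sporophyte", length(spo)), spo))
  out <- list(expr = expr, tissue_side = tissue_side)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$path <- write_expression_table(expr, file.path(dir, "expression.tsv"))
  }
  out
}

# carrier count of an injected deleterious allele: low-frequency but not
# strictly singleton, P(k) proportional to 1/k up to n/4
.injected_carriers <- function(n) {
  K <- max(1L, n %/% 4L)
  sample.int(K, 1, prob = 1 / seq_len(K))
}

# sample segregating sites for a set of CDS positions: returns data.frame
# (cds_pos, count) of sites drawn polymorphic, with sample counts from the
# normalised weight vector w (length n-1)
.draw_sites <- function(positions, theta, w) {
  if (!length(positions)) return(data.frame(cds_pos = integer(0), count = integer(0)))
  p_seg <- min(theta * sum(w), 1)
  seg <- positions[stats::runif(length(positions)) < p_seg]
  if (!length(seg)) return(data.frame(cds_pos = integer(0), count = integer(0)))
  data.frame(cds_pos = seg,
             count = sample.int(length(w), length(seg), replace = TRUE,
                                prob = w / sum(w)))
}

#' Simulate the homozygous strain variant panel
#'
#' Synonymous SNPs are placed at 4-fold sites with frequencies from the
#' neutral sample-frequency distribution (weight 1/i); nonsynonymous SNPs
#' at 0-fold sites with frequencies from the gamma-DFE sampling
#' distribution of the gene's class (same weights as the estimator).
#' Premature-stop SNPs and frameshift indels are injected as separate
#' per-gene Bernoulli processes (one singleton carrier each). A small
#' number of sub-threshold-quality decoy records exercises the phred
#' filter.
#'
#' @param config sim_config
#' @param truth,models,genome outputs of \code{\link{simulate_genome}}
#' @param dir optional output directory (variants.tsv)
#' @return list with variants (variant_table, already above-threshold
#'   except decoys), strains (character vector) and optionally the path
#' @export
simulate_strain_variants <- function(config, truth, models, genome, dir = NULL) {
  set.seed(.seed_for(config, "variants"))
  n <- config$n_strains
  strains <- sprintf("strain%03d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  deg <- codon_degeneracy()
  w_neutral <- 1 / seq_len(n - 1L)
  w_class <- lapply(config$dfe, function(p)
    sfs_weights(n, p[["shape"]], p[["mean_S"]]))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    gm <- models[[truth$gene_id[i]]]
    cls <- truth$class[i]
    ref <- extract_cds(gm, genome)
    codons <- split_codons(ref)
    d <- matrix(deg[codons, ], ncol = 3)
    deg_pos <- as.integer(t(d))           # per CDS position degeneracy
    four <- which(deg_pos == 3L)
    zero <- which(deg_pos == 0L)
    tpos <- cds_genomic_positions(gm)
    flip <- gm$strand == "-"
    snps <- rbind(.draw_sites(four, config$theta_site, w_neutral),
                  .draw_sites(zero, config$theta_site, w_class[[cls]]))
    # stop-gain injection: one singleton SNP creating a premature stop
    if (stats::runif(1) < truth$stop_gain_rate[i]) {
      cand <- list()
      for (ci in seq_len(length(codons) - 1L)) {
        cd <- codons[ci]
        for (p in 1:3) for (b in setdiff(bases, substr(cd, p, p))) {
          x <- cd; substr(x, p, p) <- b
          if (genetic_code()[[x]] == "*")
            cand[[length(cand) + 1L]] <- c((ci - 1L) * 3L + p, b)
        }
      }
      if (length(cand)) {
        pick <- cand[[sample.int(length(cand), 1)]]
        pos <- as.integer(pick[1])
        if (!pos %in% snps$cds_pos) {
          snps <- rbind(snps, data.frame(cds_pos = pos,
                                         count = .injected_carriers(n)))
          attr(snps, "stop_alt") <- stats::setNames(pick[2], pos)
        }
      }
    }
    stop_alt <- attr(snps, "stop_alt")
    gcode <- genetic_code()
    if (nrow(snps)) {
      for (k in seq_len(nrow(snps))) {
        cp <- snps$cds_pos[k]
        ref_t <- substring(ref, cp, cp)
        alt_t <- if (!is.null(stop_alt) && as.character(cp) %in% names(stop_alt)) {
          stop_alt[[as.character(cp)]]
        } else {
          # background DFE draws never create a stop codon; premature
          # stops are governed solely by the stop_gain_rate process
          ci <- (cp - 1L) %/% 3L
          codon <- substring(ref, ci * 3L + 1L, ci * 3L + 3L)
          within <- (cp - 1L) %% 3L + 1L
          cand <- setdiff(bases, ref_t)
          ok <- vapply(cand, function(b) {
            x <- codon; substr(x, within, within) <- b
            gcode[[x]] != "*"
          }, logical(1))
          sample(cand[ok], 1)
        }
        carriers <- sample(strains, snps$count[k])
        gpos <- tpos[cp]
        rows[[length(rows) + 1L]] <- data.frame(
          strain = carriers, chrom = gm$chromosome, pos = gpos,
          ref = if (flip) comp_base(ref_t) else ref_t,
          alt = if (flip) comp_base(alt_t) else alt_t,
          qual = round(stats::runif(length(carriers), 30, 60), 1),
          stringsAsFactors = FALSE)
      }
    }
    # frameshift indel injection: one singleton 1- or 2-nt deletion
    if (stats::runif(1) < truth$indel_rate[i]) {
      len <- sample(1:2, 1)
      iv <- gm$cds[order(gm$cds[, "start"]), , drop = FALSE]
      widths <- iv[, "end"] - iv[, "start"] + 1L
      ok_iv <- which(widths >= len + 2L)
      j <- ok_iv[sample.int(length(ok_iv), 1)]
      anchor <- unname(iv[j, "start"] +
        sample.int(widths[j] - len - 1L, 1) + 1L)  # keep first/last base of piece
      chrom_seq <- as.character(genome[[gm$chromosome]])
      refstr <- substr(chrom_seq, anchor - 1L, anchor + len - 1L)
      carriers <- sample(strains, .injected_carriers(n))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = carriers, chrom = gm$chromosome, pos = anchor - 1L,
        ref = refstr, alt = substr(refstr, 1, 1),
        qual = round(stats::runif(length(carriers), 30, 60), 1),
        stringsAsFactors = FALSE)
    }
    # low-quality decoys (must be removed by the phred >= 25 filter)
    n_decoy <- stats::rpois(1, config$decoy_rate)
    if (n_decoy > 0) {
      cp <- sample.int(nchar(ref), n_decoy, replace = TRUE)
      ref_t <- substring(ref, cp, cp)
      alt_t <- vapply(ref_t, function(r) sample(setdiff(bases, r), 1), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = sample(strains, n_decoy, replace = TRUE),
        chrom = gm$chromosome, pos = tpos[cp],
        ref = if (flip) comp_base(ref_t) else ref_t,
        alt = if (flip) comp_base(alt_t) else alt_t,
        qual = round(stats::runif(n_decoy, 5, 24.9), 1),
        stringsAsFactors = FALSE)
    }
  }
  v <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strain = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), qual = numeric(0))
  out <- list(variants_raw = v, strains = strains)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(dir, "variants.tsv")
    utils::write.table(v, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out$path <- p
  }
  out
}

#' Evolve a diverged copy of a CDS at target dS and dN = omega * dS
#'
#' Per-codon Gillespie process over unit branch length: each one-step
#' change occurs at rate dS/3 if synonymous, omega*dS/3 if nonsynonymous;
#' changes to stop codons are forbidden. The start and terminal stop
#' codons are held fixed.
#'
#' @param cds reference CDS (with terminal stop)
#' @param omega target dN/dS
#' @param ds target synonymous substitutions per synonymous site
#' @return diverged CDS of equal length
#' @export
simulate_diverged_cds <- function(cds, omega, ds) {
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- split_codons(toupper(cds))
  ncod <- length(codons)
  evolve <- seq_len(ncod)
  evolve <- evolve[codons != "ATG" | seq_len(ncod) != 1L]
  evolve <- setdiff(evolve, ncod)  # terminal stop fixed
  for (ci in evolve) {
    cur <- codons[ci]
    t <- 0
    repeat {
      # enumerate one-step changes and their rates
      tgt <- character(0); rate <- numeric(0)
      for (p in 1:3) for (b in setdiff(bases, substr(cur, p, p))) {
        x <- cur; substr(x, p, p) <- b
        if (gc[[x]] == "*") next
        tgt <- c(tgt, x)
        rate <- c(rate, if (gc[[x]] == gc[[cur]]) ds / 3 else omega * ds / 3)
      }
      tot <- sum(rate)
      if (tot == 0) break
      t <- t + stats::rexp(1, tot)
      if (t > 1) break
      cur <- tgt[sample.int(length(tgt), 1, prob = rate / tot)]
    }
    codons[ci] <- cur
  }
  paste(codons, collapse = "")
}

#' Simulate diverged ortholog pairs and the reciprocal hit tables
#'
#' @param config sim_config
#' @param truth,models,genome outputs of \code{\link{simulate_genome}}
#' @param dir optional output directory (cds_a.fasta, cds_b.fasta,
#'   hits_ab.tsv, hits_ba.tsv)
#' @return list with cds_a, cds_b (named character vectors; names of b
#'   carry suffix "_b"), hits_ab, hits_ba and optionally paths
#' @export
simulate_divergence <- function(config, truth, models, genome, dir = NULL) {
  set.seed(.seed_for(config, "divergence"))
  cds_a <- vapply(truth$gene_id, function(g)
    extract_cds(models[[g]], genome), character(1))
  cds_b <- vapply(seq_len(nrow(truth)), function(i)
    simulate_diverged_cds(cds_a[[i]], truth$omega[i], truth$ds[i]), character(1))
  names(cds_b) <- paste0(truth$gene_id, "_b")
  prot <- function(x) {
    aa <- translate_codons(split_codons(x))
    paste(aa[-length(aa)], collapse = "")
  }
  pa <- vapply(cds_a, prot, character(1))
  pb <- vapply(cds_b, prot, character(1))
  pid <- vapply(seq_along(pa), function(i) {
    a <- strsplit(pa[i], "")[[1]]; b <- strsplit(pb[i], "")[[1]]
    100 * mean(a == b)
  }, numeric(1))
  len <- nchar(pa)
  hits_ab <- data.frame(qseqid = names(cds_a), sseqid = names(cds_b),
                        pident = round(pid, 2), length = len,
                        bitscore = round(2 * len * pid / 100, 1),
                        stringsAsFactors = FALSE)
  hits_ba <- data.frame(qseqid = names(cds_b), sseqid = names(cds_a),
                        pident = round(pid, 2), length = len,
                        bitscore = round(2 * len * pid / 100, 1),
                        stringsAsFactors = FALSE)
  # spurious low-scoring cross hits so reciprocal-best filtering has work
  if (nrow(truth) >= 2) {
    k <- max(1L, nrow(truth) %/% 5L)
    qi <- sample.int(nrow(truth), k)
    si <- vapply(qi, function(q) sample(setdiff(seq_len(nrow(truth)), q), 1),
                 integer(1))
    noise <- data.frame(qseqid = names(cds_a)[qi], sseqid = names(cds_b)[si],
                        pident = round(stats::runif(k, 15, 28), 2),
                        length = pmin(len[qi], len[si]),
                        bitscore = round(stats::runif(k, 30, 60), 1),
                        stringsAsFactors = FALSE)
    hits_ab <- rbind(hits_ab, noise)
  }
  out <- list(cds_a = cds_a, cds_b = cds_b, hits_ab = hits_ab, hits_ba = hits_ba)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(
      cds_a = write_fasta(cds_a, file.path(dir, "cds_a.fasta")),
      cds_b = write_fasta(cds_b, file.path(dir, "cds_b.fasta")),
      hits_ab = write_hit_table(hits_ab, file.path(dir, "hits_ab.tsv")),
      hits_ba = write_hit_table(hits_ba, file.path(dir, "hits_ba.tsv")))
  }
  out
}

#' Run the generators
#'
#' @param config sim_config
#' @param dir optional output directory for all files
#' @param stages which generators to run after the genome stage
#' @return list combining the outputs of \code{\link{simulate_genome}},
#'   \code{\link{simulate_expression}},
#'   \code{\link{simulate_strain_variants}} and
#'   \code{\link{simulate_divergence}}, plus \code{variants}: the
#'   quality-filtered variant table (phred >= 25)
#' @export
simulate_dataset <- function(config, dir = NULL,
                             stages = c("expression", "variants", "divergence")) {
  out <- simulate_genome(config, dir)
  if ("expression" %in% stages)
    out <- c(out, simulate_expression(config, out$truth, dir))
  if ("variants" %in% stages) {
    va <- simulate_strain_variants(config, out$truth, out$models, out$genome, dir)
    # filter exactly as the reader would
    tmp <- tempfile(fileext = ".tsv")
    utils::write.table(va$variants_raw, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    va$variants <- read_variants_tsv(tmp, min_quality = 25)
    unlink(tmp)
    out <- c(out, va)
  }
  if ("divergence" %in% stages)
    out <- c(out, simulate_divergence(config, out$truth, out$models,
                                      out$genome, dir))
  c(out, list(config = config))
}
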