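# Per-strain CDS reconstruction and deleterious-allele scoring.
# Fixture gene: ATG TGG CAA TGT TAA (Met-Trp-Gln-Cys-stop), one interval.

fix_cds <- "ATGTGGCAATGTTAA"

test_that("strain CDS reconstruction applies SNPs and indels", {
  f <- make_gene_fixture(fix_cds)
  g0 <- build_strain_cds(f$gm, f$genome, variant_row("s1", "chr2", 1, "A", "C"))
  expect_equal(g0$sequence, fix_cds)  # no variants on this chromosome

  # SNP at CDS position 5 (genomic 15): G -> A
  g1 <- build_strain_cds(f$gm, f$genome, variant_row("s1", "chr1", 15, "G", "A"))
  expect_equal(g1$sequence, "ATGTAGCAATGTTAA")
  expect_equal(g1$n_rejected, 0L)

  # 2-nt deletion anchored at genomic 16 (CDS pos 6): removes positions 7-8
  del <- variant_row("s1", "chr1", 16, "GCA", "G")
  g2 <- build_strain_cds(f$gm, f$genome, del)
  expect_equal(nchar(g2$sequence), nchar(fix_cds) - 2)
  expect_equal(g2$sequence, "ATGTGGATGTTAA")

  # disagreeing reference allele: rejected, gene not aborted
  g3 <- build_strain_cds(f$gm, f$genome, variant_row("s1", "chr1", 15, "T", "A"))
  expect_equal(g3$sequence, fix_cds)
  expect_equal(g3$n_rejected, 1L)
})

test_that("premature stops are unique (position, alt) pairs over the panel", {
  f <- make_gene_fixture(fix_cds)
  n_strains <- 10
  # TGG codon, SNP G->A at its 2nd position (CDS 5) -> TAG in 5 strains
  snps <- do.call(bind_variants, lapply(sprintf("s%d", 1:5), function(s)
    variant_row(s, "chr1", 15, "G", "A")))
  res <- score_premature_stops(f$gm, fix_cds, snps, n_strains)
  expect_equal(res$unique_stop_alleles, 1L)
  expect_equal(res$stop_allele_frequency, 0.1)

  # a second, different stop-creating SNP: CAA -> TAA at CDS 7 (genomic 17)
  snps2 <- bind_variants(snps, variant_row("s9", "chr1", 17, "C", "T"))
  expect_equal(score_premature_stops(f$gm, fix_cds, snps2, n_strains)$unique_stop_alleles, 2L)

  # a SNP in the terminal stop codon is stop-loss, not premature
  snps3 <- variant_row("s1", "chr1", 23, "T", "C")  # CDS 13, TAA -> CAA
  expect_equal(score_premature_stops(f$gm, fix_cds, snps3, n_strains)$unique_stop_alleles, 0L)

  # a non-stop SNP counts nothing
  snps4 <- variant_row("s1", "chr1", 12, "T", "C")  # CDS 2: ATG -> ACG
  r4 <- score_premature_stops(f$gm, fix_cds, snps4, n_strains)
  expect_equal(r4$unique_stop_alleles, 0L)
})

test_that("frameshift frequency counts strains once, in-frame indels never", {
  f <- make_gene_fixture(fix_cds)
  del2 <- variant_row("s1", "chr1", 16, "GCA", "G")          # 2-nt: frameshift
  expect_equal(score_frameshifts(f$gm, del2, 10), 0.1)
  del3 <- do.call(bind_variants, lapply(sprintf("s%d", 1:10), function(s)
    variant_row(s, "chr1", 14, "TGGC", "T")))                # 3-nt: in frame
  expect_equal(score_frameshifts(f$gm, del3, 10), 0)
  two_in_one <- bind_variants(variant_row("s1", "chr1", 13, "GT", "G"),
                              variant_row("s1", "chr1", 17, "CA", "C"))
  expect_equal(score_frameshifts(f$gm, two_in_one, 10), 0.1)
})

test_that("a minus-strand mirror gene yields identical scores", {
  plus <- make_gene_fixture(fix_cds, strand = "+")
  minus <- make_gene_fixture(fix_cds, strand = "-")
  # CDS position p: genomic 10 + p on +, 26 - p with complemented alleles on -
  mk <- function(strand, strain, p, ref, alt) {
    if (strand == "+") variant_row(strain, "chr1", 10 + p, ref, alt)
    else variant_row(strain, "chr1", 26 - p, comp_base(ref), comp_base(alt))
  }
  for (fx in list(list(f = plus, s = "+"), list(f = minus, s = "-"))) {
    snps <- bind_variants(mk(fx$s, "s1", 5, "G", "A"), mk(fx$s, "s2", 7, "C", "T"))
    res <- score_premature_stops(fx$f$gm, fix_cds, snps, 10)
    expect_equal(res$unique_stop_alleles, 2L)
    expect_equal(res$stop_allele_frequency, 0.2)
    g <- build_strain_cds(fx$f$gm, fx$f$genome,
                          snps[snps$strain_id == "s1", , drop = FALSE])
    expect_equal(g$sequence, "ATGTAGCAATGTTAA")
  }
})

test_that("synthetic genomes without injected events score zero everywhere", {
  cfg <- sim_config(seed = 21, n_chromosomes = 1, genes_per_chromosome = 10,
                    n_strains = 12,
                    stop_gain_rate = c(pollen_specific = 0, sporophyte_specific = 0,
                                       shared = 0, not_expressed = 0),
                    indel_rate = c(pollen_specific = 0, sporophyte_specific = 0,
                                   shared = 0, not_expressed = 0),
                    dfe = list(pollen_specific = c(shape = 0.3, mean_S = 0),
                               sporophyte_specific = c(shape = 0.3, mean_S = 0),
                               shared = c(shape = 0.3, mean_S = 0),
                               not_expressed = c(shape = 0.3, mean_S = 0)))
  d <- simulate_dataset(cfg, stages = "variants")
  del <- score_deleterious(d$models, d$genome, d$variants, cfg$n_strains)
  expect_true(all(del$unique_stop_alleles == 0))
  expect_true(all(del$frameshift_frequency == 0))
})

test_that("injected stop-gain alleles are recovered at the configured rate", {
  rate <- 0.5
  cfg <- sim_config(seed = 22, n_chromosomes = 2, genes_per_chromosome = 50,
                    n_strains = 12, gene_codons = c(60, 100),
                    stop_gain_rate = c(pollen_specific = rate, sporophyte_specific = rate,
                                       shared = rate, not_expressed = rate),
                    decoy_rate = 0)
  d <- simulate_dataset(cfg, stages = "variants")
  del <- score_deleterious(d$models, d$genome, d$variants, cfg$n_strains)
  G <- nrow(del)
  se <- sqrt(rate * (1 - rate) / G)
  # injected singleton stop alleles: expected >= rate per gene (background
  # 0-fold SNPs occasionally add further stop alleles)
  expect_gt(mean(del$unique_stop_alleles >= 1), rate - 3 * se)
})
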