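# Site classes, Watterson's theta, pi and site-frequency spectra.

test_that("site degeneracy follows the standard code", {
  cls <- classify_sites("GGGTGGATG")
  # GGG (Gly): positions 1,2 zero-fold, position 3 four-fold
  expect_equal(cls[1:3], c("zero_fold", "zero_fold", "four_fold"))
  # TGG (Trp): all three positions zero-fold
  expect_equal(cls[4:6], rep("zero_fold", 3))
  # ATG (Met): positions 1,2 zero-fold; position 3 zero-fold (all change Met)
  expect_equal(cls[7:9], rep("zero_fold", 3))
  # CTA (Leu): position 1 is 'other' (TTA is Leu, ATA/GTA are not)
  expect_equal(classify_sites("CTA")[1], "other")
})

test_that("codons with more than one SNP are fully masked", {
  cls <- classify_sites("GGGAAA", snp_positions = c(1, 3))
  expect_equal(cls[1:3], rep("masked", 3))
  expect_equal(cls[4:6], classify_sites("GGGAAA")[4:6])
  expect_equal(attr(cls, "n_masked_codons"), 1L)
  # a single SNP masks nothing
  expect_false(any(classify_sites("GGGAAA", snp_positions = 2) == "masked"))
  # ambiguity masks its codon
  expect_equal(classify_sites("GGNAAA")[1:3], rep("masked", 3))
})

test_that("masking monotonicity: a second SNP never increases L or S", {
  set.seed(8)
  cds <- random_cds(40)
  snps1 <- data.frame(strain_id = "s1", cds_pos = 10L, alt_t = "A")
  snps2 <- rbind(snps1, data.frame(strain_id = "s2", cds_pos = 12L, alt_t = "C"))
  c1 <- classify_sites(cds, snps1$cds_pos)
  c2 <- classify_sites(cds, snps2$cds_pos)
  s1 <- build_sfs(snps1, c1, n = 10)
  s2 <- build_sfs(snps2, c2, n = 10)
  expect_lte(s2$L_n, s1$L_n)
  expect_lte(s2$L_s, s1$L_s)
  expect_lte(s2$S_n + s2$S_s, s1$S_n + s1$S_s)
})

test_that("Watterson's theta matches its closed form and a harmonic oracle", {
  expect_equal(watterson_theta(3, 5, 200), 3 / ((1 + 1/2 + 1/3 + 1/4) * 200))
  expect_equal(watterson_theta(3, 5, 200), 0.0072)
  expect_equal(watterson_theta(0, 5, 200), 0)
  for (n in c(2, 17, 80, 300))
    expect_equal(watterson_theta(7, n, 1000), oracle_theta(7, n, 1000))
})

test_that("pi matches the pairwise-difference definition", {
  # one site A/A/T among 3 strains, L = 100
  expect_equal(nucleotide_diversity(1, 3, 100), (2/3) / 100)
  expect_equal(nucleotide_diversity(integer(0), 3, 100), 0)  # monomorphic
  # brute-force pairwise oracle on random allele matrices
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:12, 1); L <- 50
    mat <- matrix("A", n, L)
    n_poly <- sample(3:8, 1)
    sites <- sample(L, n_poly)
    counts <- integer(0)
    for (s in sites) {
      k <- sample(n - 1, 1)
      mat[sample(n, k), s] <- "T"
      counts <- c(counts, k)
    }
    expect_equal(nucleotide_diversity(counts, n, L), oracle_pi(mat, L))
  }
})

test_that("spectra bin sites by allele count, with folding", {
  cds <- strrep("GGG", 40)                 # position 3 of each codon four-fold
  cls <- classify_sites(cds)
  mk_snps <- function(pos, k) data.frame(
    strain_id = sprintf("s%d", seq_len(k)), cds_pos = pos, alt_t = "A",
    stringsAsFactors = FALSE)
  n <- 80
  snps <- rbind(mk_snps(3, 3), mk_snps(6, 78), mk_snps(4, 5))
  unf <- build_sfs(snps, cls, n, fold = FALSE)
  expect_equal(unf$sfs_s[3], 1)            # alt in 3 of 80 at a 4-fold site
  expect_equal(unf$sfs_s[78], 1)
  expect_equal(unf$sfs_n[5], 1)            # zero-fold site
  fol <- build_sfs(snps, cls, n, fold = TRUE)
  expect_equal(fol$sfs_s[2], 1)            # 78/80 folds to minor count 2
  expect_equal(fol$sfs_s[3], 1)
  expect_equal(sum(fol$sfs_n), fol$S_n)    # sums equal segregating counts
  expect_equal(sum(fol$sfs_s), fol$S_s)
})

test_that("triallelic sites are excluded and counted", {
  cds <- strrep("GGG", 10)
  cls <- classify_sites(cds)
  snps <- data.frame(strain_id = c("s1", "s2"), cds_pos = c(3L, 3L),
                     alt_t = c("A", "T"), stringsAsFactors = FALSE)
  sp <- build_sfs(snps, cls, n = 10)
  expect_equal(sp$n_triallelic, 1L)
  expect_equal(sp$S_s, 0)
})

test_that("missing-data positions reduce L", {
  cds <- strrep("GGG", 10)
  cls <- classify_sites(cds)
  no_miss <- build_sfs(data.frame(strain_id = character(0), cds_pos = integer(0),
                                  alt_t = character(0)), cls, n = 10)
  miss <- build_sfs(data.frame(strain_id = character(0), cds_pos = integer(0),
                               alt_t = character(0)), cls, n = 10,
                    missing_positions = c(3L, 6L))
  expect_equal(no_miss$L_s - miss$L_s, 2)
})

test_that("pi and theta from the spectrum match their closed forms per gene", {
  # unfolded identity: pi = sum i (n - i) sfs[i] / C(n,2) / L
  cfg <- sim_config(seed = 31, n_chromosomes = 1, genes_per_chromosome = 8,
                    n_strains = 16)
  d <- simulate_dataset(cfg, stages = "variants")
  div <- gene_diversity(d$models, d$genome, d$variants, cfg$n_strains,
                        fold = FALSE)
  n <- cfg$n_strains
  for (g in names(d$models)) {
    sp <- div$sfs[[g]]
    row <- div$stats[div$stats$gene_id == g, ]
    i <- seq_len(n - 1)
    if (sp$L_s > 0)
      expect_equal(row$pi_s, sum(i * (n - i) * sp$sfs_s) / choose(n, 2) / sp$L_s)
    if (sp$L_n > 0)
      expect_equal(row$theta_n, sp$S_n / (harmonic_number(n - 1) * sp$L_n))
  }
})
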