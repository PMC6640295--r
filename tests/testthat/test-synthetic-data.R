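# The synthetic-data generator: determinism, construction invariants,
# class recovery, and the neutral/selected limits of the variant panel.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 17, n_chromosomes = 2, genes_per_chromosome = 4,
                    n_strains = 10)
  d1 <- simulate_dataset(cfg, dir = file.path(tempdir(), "simA"))
  d2 <- simulate_dataset(cfg, dir = file.path(tempdir(), "simB"))
  for (f in c("genome.fasta", "genes.gff3", "truth.tsv", "expression.tsv",
              "variants.tsv", "cds_a.fasta", "cds_b.fasta", "hits_ab.tsv")) {
    expect_identical(readLines(file.path(tempdir(), "simA", f)),
                     readLines(file.path(tempdir(), "simB", f)),
                     label = f)
  }
})

test_that("simulated gene models satisfy every CDS invariant", {
  cfg <- sim_config(seed = 18, n_chromosomes = 5, genes_per_chromosome = 20,
                    n_strains = 8)
  d <- simulate_genome(cfg)
  expect_length(d$models, 100)
  for (gm in d$models) expect_true(validate_gene_model(gm, d$genome))
  # round trip through the written files reproduces the models
  dir <- file.path(tempdir(), "simRT")
  simulate_genome(cfg, dir = dir)
  models2 <- read_gff3(file.path(dir, "genes.gff3"))
  genome2 <- read_genome_fasta(file.path(dir, "genome.fasta"))
  expect_setequal(names(models2), names(d$models))
  for (g in names(d$models))
    expect_identical(extract_cds(models2[[g]], genome2),
                     extract_cds(d$models[[g]], d$genome))
})

test_that("an empty gene complement still yields valid files", {
  cfg <- sim_config(seed = 19, n_chromosomes = 2, genes_per_chromosome = 0,
                    n_strains = 8)
  dir <- file.path(tempdir(), "simEmpty")
  d <- simulate_genome(cfg, dir = dir)
  expect_length(d$models, 0)
  expect_length(read_genome_fasta(file.path(dir, "genome.fasta")), 2)
})

test_that("the classifier recovers the truth table exactly", {
  cfg <- sim_config(seed = 20, n_chromosomes = 5, genes_per_chromosome = 20,
                    n_strains = 8)
  d <- simulate_dataset(cfg, stages = "expression")
  cl <- classify_life_stage(merge_pollen_tube(d$expr), d$tissue_side)
  got <- cl$life_stage_class[match(d$truth$gene_id, cl$gene_id)]
  expect_equal(mean(got == d$truth$class), 1)
  # sporophyte breadth is reproduced too
  sp <- d$truth$class == "sporophyte_specific"
  expect_equal(cl$sporophyte_tissue_count[match(d$truth$gene_id, cl$gene_id)][sp],
               d$truth$sp_breadth[sp])
})

test_that("with selection off, nonsynonymous diversity matches synonymous", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2, genes_per_chromosome = 100,
                    n_strains = 20, gene_codons = c(60, 120),
                    dfe = list(pollen_specific = c(shape = 0.3, mean_S = 0),
                               sporophyte_specific = c(shape = 0.3, mean_S = 0),
                               shared = c(shape = 0.3, mean_S = 0),
                               not_expressed = c(shape = 0.3, mean_S = 0)),
                    stop_gain_rate = c(pollen_specific = 0, sporophyte_specific = 0,
                                       shared = 0, not_expressed = 0),
                    indel_rate = c(pollen_specific = 0, sporophyte_specific = 0,
                                   shared = 0, not_expressed = 0))
  d <- simulate_dataset(cfg, stages = "variants")
  div <- gene_diversity(d$models, d$genome, d$variants, cfg$n_strains)
  s <- div$stats
  # mean theta_s within 3 SE of the configured theta_site
  se_s <- sd(s$theta_s) / sqrt(nrow(s))
  expect_lt(abs(mean(s$theta_s) - cfg$theta_site), 3 * se_s)
  # neutral limit: per-site theta_n close to theta_s
  dd <- s$theta_n - s$theta_s
  expect_lt(abs(mean(dd)), 3 * sd(dd) / sqrt(nrow(s)))
})

test_that("strong selection suppresses nonsynonymous diversity", {
  cfg <- sim_config(seed = 24, n_chromosomes = 2, genes_per_chromosome = 100,
                    n_strains = 20, gene_codons = c(60, 120),
                    dfe = list(pollen_specific = c(shape = 0.3, mean_S = 2000),
                               sporophyte_specific = c(shape = 0.3, mean_S = 2000),
                               shared = c(shape = 0.3, mean_S = 2000),
                               not_expressed = c(shape = 0.3, mean_S = 2000)))
  d <- simulate_dataset(cfg, stages = "variants")
  div <- gene_diversity(d$models, d$genome, d$variants, cfg$n_strains)
  expect_lt(mean(div$stats$theta_n) / mean(div$stats$theta_s), 0.5)
})

test_that("divergence simulation honours omega = 0 and the dS target", {
  set.seed(25)
  cds <- random_cds(2000)
  same <- simulate_diverged_cds(cds, omega = 0, ds = 0.2)
  prot <- function(x) paste(translate_codons(split_codons(x)), collapse = "")
  expect_identical(prot(same), prot(cds))   # no nonsynonymous change at all
  expect_false(identical(same, cds))        # but synonymous changes occurred
  est <- pairwise_dnds(substr(cds, 1, nchar(cds) - 3),
                       substr(same, 1, nchar(same) - 3))
  # path averaging between synonymous codons of split families (e.g. the
  # two serine boxes) can assign tiny fractional nonsynonymous counts
  # even though the proteins are identical
  expect_lt(est$dN, 0.002)
  expect_gt(est$dS, 0.1)
})

test_that("injected frameshifts appear iff the indel rate is positive", {
  base <- list(seed = 26, n_chromosomes = 1, genes_per_chromosome = 30,
               n_strains = 10, gene_codons = c(60, 100))
  z <- c(pollen_specific = 0, sporophyte_specific = 0, shared = 0,
         not_expressed = 0)
  cfg0 <- do.call(sim_config, c(base, list(indel_rate = z)))
  d0 <- simulate_dataset(cfg0, stages = "variants")
  expect_equal(sum(d0$variants$kind == "indel"), 0)
  cfg1 <- do.call(sim_config, c(base, list(indel_rate = z + 1)))
  d1 <- simulate_dataset(cfg1, stages = "variants")
  del <- score_deleterious(d1$models, d1$genome, d1$variants, cfg1$n_strains)
  expect_true(all(del$frameshift_frequency > 0))
})
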