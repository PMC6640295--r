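# Life-stage classification, pollen-tube merging, comparison groups and
# the chromosome-distribution chi-square test.

test_that("pollen-tube merging takes the element-wise maximum", {
  expr <- toy_expression(list(
    list("g1", "pollen_tube_a", 1200, 0.95),
    list("g1", "pollen_tube_b", 800, 0.99),
    list("g2", "pollen_tube_a", 0, 0.1),
    list("g2", "pollen_tube_b", 0, 0.2),
    list("g3", "leaf", 50, 0.95)))
  m <- merge_pollen_tube(expr)
  tube <- m[m$tissue == "pollen_tube", ]
  expect_equal(tube$level[tube$gene_id == "g1"], 1200)
  expect_equal(tube$presence[tube$gene_id == "g1"], 0.99)
  # g3 had neither tube column: absent pair counts as (0, 0)
  expect_false("g3" %in% tube$gene_id)
  expect_error(merge_pollen_tube(expr[expr$tissue == "leaf", ]), "not in")
})

test_that("merging then classifying equals classifying a pre-merged table", {
  expr <- toy_expression(list(
    list("g1", "pollen_tube_a", 1200, 0.95),
    list("g1", "pollen_tube_b", 800, 0.99),
    list("g1", "leaf", 10, 0.3),
    list("g2", "pollen_tube_a", 30, 0.5),
    list("g2", "pollen_tube_b", 20, 0.4),
    list("g2", "leaf", 900, 0.97)))
  pre <- toy_expression(list(
    list("g1", "pollen_tube", 1200, 0.99),
    list("g1", "leaf", 10, 0.3),
    list("g2", "pollen_tube", 30, 0.5),
    list("g2", "leaf", 900, 0.97)))
  a <- classify_life_stage(merge_pollen_tube(expr), toy_tissue_side)
  b <- classify_life_stage(pre, toy_tissue_side)
  expect_equal(a, b)
})

test_that("life-stage classes follow the presence threshold", {
  expr <- toy_expression(list(
    list("g1", "pollen_mature", 500, 0.95), list("g1", "leaf", 40, 0.2),
    list("g2", "pollen", 300, 0.95), list("g2", "leaf", 200, 0.95),
    list("g3", "pollen", 10, 0.89), list("g3", "leaf", 10, 0.89),
    list("g4", "leaf", 100, 0.92), list("g4", "root", 150, 0.91)))
  cl <- classify_life_stage(expr, toy_tissue_side)
  got <- setNames(cl$life_stage_class, cl$gene_id)
  expect_equal(unname(got[c("g1", "g2", "g3", "g4")]),
               c("pollen_specific", "shared", "not_expressed",
                 "sporophyte_specific"))
  expect_equal(cl$expression_level[cl$gene_id == "g3"], 0)
  expect_equal(cl$expression_level[cl$gene_id == "g4"], 150)
  expect_equal(cl$sporophyte_tissue_count[cl$gene_id == "g4"], 2L)
  expect_error(classify_life_stage(
    toy_expression(list(list("g", "mystery", 1, 0.5))), toy_tissue_side),
    "unknown tissue")
})

test_that("classification partitions genes and is monotone in the threshold", {
  set.seed(11)
  tissues <- names(toy_tissue_side)
  expr <- expand.grid(gene_id = sprintf("g%02d", 1:40), tissue = tissues,
                      stringsAsFactors = FALSE)
  expr$presence <- runif(nrow(expr))
  expr$level <- ifelse(expr$presence > 0, runif(nrow(expr), 1, 1000), 0)
  for (th in c(0.5, 0.9)) {
    cl <- classify_life_stage(expr, toy_tissue_side, threshold = th)
    expect_equal(nrow(cl), 40)            # every gene exactly one class
    expect_setequal(cl$gene_id, unique(expr$gene_id))
  }
  lo <- classify_life_stage(expr, toy_tissue_side, threshold = 0.5)
  hi <- classify_life_stage(expr, toy_tissue_side, threshold = 0.95)
  m <- merge(lo, hi, by = "gene_id", suffixes = c("_lo", "_hi"))
  # raising the threshold can only remove present tissues: a gene can move
  # toward not_expressed (or from shared to one-sided) but never flip side
  expect_false(any(m$life_stage_class_lo == "pollen_specific" &
                     m$life_stage_class_hi %in% c("sporophyte_specific", "shared")))
  expect_false(any(m$life_stage_class_lo == "sporophyte_specific" &
                     m$life_stage_class_hi %in% c("pollen_specific", "shared")))
  expect_false(any(m$life_stage_class_lo == "not_expressed" &
                     m$life_stage_class_hi != "not_expressed"))
})

test_that("comparison groups respect tissue-specificity definitions", {
  cl <- data.frame(
    gene_id = c("p1", "s_xy", "s_leaf", "s_broad", "sh"),
    life_stage_class = c("pollen_specific", "sporophyte_specific",
                         "sporophyte_specific", "sporophyte_specific", "shared"),
    sporophyte_tissue_count = c(0L, 1L, 1L, 5L, 3L),
    expression_level = c(100, 50, 60, 70, 80),
    sporophyte_tissues = c("", "xylem", "leaf", "leaf,root,stem,seed,xylem",
                           "leaf,root,stem"),
    stringsAsFactors = FALSE)
  g1 <- select_comparison_groups(cl, "pollen_vs_single_tissue")
  expect_equal(g1$a, "p1")
  expect_equal(g1$b, "s_xy")    # leaf is not one of the configured cell types
  g2 <- select_comparison_groups(cl, "pollen_vs_broad")
  expect_equal(g2$b, "s_broad")
  # a pollen gene is never in a sporophyte set, a shared gene in neither
  expect_false(any(c("p1", "sh") %in% c(g1$b, g2$b)))
  expect_warning(select_comparison_groups(cl[cl$gene_id == "p1", ],
                                          "pollen_vs_broad"), "empty")
})

test_that("chromosome distribution test matches the closed form", {
  # exactly proportional counts give chi-square 0
  all_c <- c(100, 200, 300)
  res <- chromosome_distribution_test(all_c / 10, all_c)
  expect_equal(res$chi_square, 0)
  expect_equal(res$df, 2L)
  # a hand-computable case
  res2 <- chromosome_distribution_test(c(10, 20), c(100, 100))
  expect_equal(res2$chi_square, (10 - 15)^2 / 15 + (20 - 15)^2 / 15)
  expect_error(chromosome_distribution_test(c(1, 1), c(0, 10)), "chromosome 1")
  expect_error(chromosome_distribution_test(c(0, 0), c(5, 5)), "empty")
})
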