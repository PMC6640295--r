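# Life-stage classification of genes from presence-scored expression.
# A tissue counts as expressing a gene only when its presence score reaches
# the threshold (default 0.9); genes reliably detected only on the pollen
# (gametophyte) side are pollen-specific, only on the sporophyte side
# sporophyte-specific, on both shared, on neither not expressed.

#' Merge the two pollen-tube expression sets into one tissue
#'
#' The merged tissue takes the element-wise maximum of level and presence
#' of the two source tissues; genes present in neither keep (0, 0).
#'
#' @param expr long expression table (gene_id, tissue, level, presence)
#' @param tube_a,tube_b names of the two source tissues
#' @param merged name of the merged tissue column
#' @return expression table with the two source tissues replaced
#' @export
merge_pollen_tube <- function(expr, tube_a = "pollen_tube_a",
                              tube_b = "pollen_tube_b",
                              merged = "pollen_tube") {
  for (t in c(tube_a, tube_b))
    if (!t %in% expr$tissue) stop("tissue not in expression table: ", t)
  a <- expr[expr$tissue == tube_a, , drop = FALSE]
  b <- expr[expr$tissue == tube_b, , drop = FALSE]
  genes <- union(a$gene_id, b$gene_id)
  ia <- match(genes, a$gene_id); ib <- match(genes, b$gene_id)
  val <- function(x, i, col) ifelse(is.na(i), 0, x[[col]][i])
  m <- data.frame(
    gene_id = genes,
    tissue = merged,
    level = pmax(val(a, ia, "level"), val(b, ib, "level")),
    presence = pmax(val(a, ia, "presence"), val(b, ib, "presence")),
    stringsAsFactors = FALSE
  )
  rbind(expr[!expr$tissue %in% c(tube_a, tube_b), , drop = FALSE], m)
}

#' Classify genes by life stage of expression
#'
#' @param expr long expression table (gene_id, tissue, level, presence);
#'   absent gene x tissue pairs count as (0, 0)
#' @param tissue_side named character vector mapping every tissue name to
#'   "pollen" or "sporophyte"
#' @param threshold presence score at or above which a gene counts as
#'   present in a tissue (default 0.9)
#' @return data.frame with gene_id, life_stage_class (pollen_specific,
#'   sporophyte_specific, shared, not_expressed), sporophyte_tissue_count,
#'   expression_level (maximum level over present tissues, 0 when not
#'   expressed) and sporophyte_tissues (comma-joined names of present
#'   sporophytic tissues)
#' @export
classify_life_stage <- function(expr, tissue_side, threshold = 0.9) {
  unknown <- setdiff(unique(expr$tissue), names(tissue_side))
  if (length(unknown)) stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  if (!all(tissue_side %in% c("pollen", "sporophyte")))
    stop("tissue_side values must be 'pollen' or 'sporophyte'")
  pres <- expr$presence >= threshold
  if (any(pres & expr$level <= 0))
    stop("present call (presence >= ", threshold, ") with zero expression level")
  side <- tissue_side[expr$tissue]
  by_gene <- split(seq_len(nrow(expr)), expr$gene_id)
  out <- lapply(names(by_gene), function(g) {
    i <- by_gene[[g]]
    p <- pres[i]
    pol <- any(p & side[i] == "pollen")
    spo_t <- sort(expr$tissue[i][p & side[i] == "sporophyte"])
    cls <- if (pol && length(spo_t)) "shared"
      else if (pol) "pollen_specific"
      else if (length(spo_t)) "sporophyte_specific"
      else "not_expressed"
    data.frame(gene_id = g, life_stage_class = cls,
               sporophyte_tissue_count = length(spo_t),
               expression_level = if (any(p)) max(expr$level[i][p]) else 0,
               sporophyte_tissues = paste(spo_t, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select two disjoint gene groups for comparison
#'
#' Groupings: \code{pollen_vs_sporophyte} (all pollen-specific vs all
#' sporophyte-specific genes), \code{pollen_vs_single_tissue} (vs genes
#' present in exactly one sporophytic tissue from \code{single_tissue_types}),
#' \code{pollen_vs_broad} (vs genes present in at least \code{min_broad}
#' sporophytic tissues), and \code{single_tissue_vs_broad}. Shared and
#' unexpressed genes never enter a group.
#'
#' @param classes output of \code{\link{classify_life_stage}}
#' @param grouping one of the groupings above
#' @param single_tissue_types sporophytic cell types defining the
#'   single-tissue set (default guard cell, xylem, root hair)
#' @param min_broad minimum sporophytic tissue count of the broad set
#' @return list with character vectors \code{a} and \code{b} of gene IDs
#'   and the grouping name
#' @export
select_comparison_groups <- function(classes,
                                     grouping = c("pollen_vs_sporophyte",
                                                  "pollen_vs_single_tissue",
                                                  "pollen_vs_broad",
                                                  "single_tissue_vs_broad"),
                                     single_tissue_types = c("guard_cell", "xylem", "root_hair"),
                                     min_broad = 5) {
  grouping <- match.arg(grouping)
  pollen <- classes$gene_id[classes$life_stage_class == "pollen_specific"]
  spo <- classes[classes$life_stage_class == "sporophyte_specific", , drop = FALSE]
  single <- spo$gene_id[spo$sporophyte_tissue_count == 1 &
                          spo$sporophyte_tissues %in% single_tissue_types]
  broad <- spo$gene_id[spo$sporophyte_tissue_count >= min_broad]
  sets <- switch(grouping,
    pollen_vs_sporophyte = list(a = pollen, b = spo$gene_id),
    pollen_vs_single_tissue = list(a = pollen, b = single),
    pollen_vs_broad = list(a = pollen, b = broad),
    single_tissue_vs_broad = list(a = single, b = broad))
  if (!length(sets$a) || !length(sets$b))
    warning("empty comparison group in grouping ", grouping)
  c(sets, list(grouping = grouping))
}

#' Chi-square test of a gene group's distribution over chromosomes
#'
#' Goodness-of-fit of the group's per-chromosome counts against the
#' proportions of all genes: expected_c = group_total * all_c / all_total,
#' chi-square = sum (obs - exp)^2 / exp with df = #chromosomes - 1.
#'
#' @param group_counts per-chromosome counts of the gene group
#' @param all_counts per-chromosome counts of all genes (same order)
#' @return list with chi_square, df, p_value and the expected counts
#' @export
chromosome_distribution_test <- function(group_counts, all_counts) {
  if (length(group_counts) != length(all_counts))
    stop("count vectors differ in length")
  if (length(all_counts) < 2) stop("need at least 2 chromosomes")
  if (any(group_counts < 0) || any(all_counts < 0)) stop("negative count")
  if (sum(group_counts) == 0) stop("empty gene group")
  expected <- sum(group_counts) * all_counts / sum(all_counts)
  if (any(expected == 0)) {
    chrom <- if (!is.null(names(all_counts))) names(all_counts) else as.character(seq_along(all_counts))
    stop("expected count 0 for chromosome ", chrom[which(expected == 0)[1]])
  }
  chi <- sum((group_counts - expected)^2 / expected)
  df <- length(all_counts) - 1L
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE),
       expected = expected)
}
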