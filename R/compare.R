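# Covariate-controlled group comparison machinery: Mann-Whitney U tests
# with Bonferroni correction, partial Spearman correlations, principal-
# component regression with jackknife predictor pruning, and ANCOVA with
# the life-stage group as binary covariate plus equal-count quantile
# binning along the selected component.

#' Mann-Whitney U test with Bonferroni adjustment
#'
#' Two-sided; exact when sample sizes permit (stats::wilcox.test
#' default), normal approximation otherwise. The adjusted p is
#' min(1, raw * family_size).
#'
#' @param values_a,values_b the two groups (non-empty numeric)
#' @param family_size number of tests in the declared family (default 1)
#' @return list with U, raw_p, adj_p, n_a, n_b
#' @export
mann_whitney_bonferroni <- function(values_a, values_b, family_size = 1) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (!length(values_a) || !length(values_b)) stop("empty group")
  if (all(values_a == values_a[1]) && all(values_b == values_b[1]) &&
      values_a[1] == values_b[1]) {
    # identical constant groups: no evidence either way
    return(list(U = length(values_a) * length(values_b) / 2, raw_p = 1,
                adj_p = 1, n_a = length(values_a), n_b = length(values_b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), raw_p = wt$p.value,
       adj_p = min(1, wt$p.value * family_size),
       n_a = length(values_a), n_b = length(values_b))
}

#' Spearman rank partial correlation
#'
#' Correlation of the residuals of rank(x) and rank(y) after linear
#' regression on the ranks of the controls; p from the t distribution
#' with n - 2 - k degrees of freedom (k = number of controls).
#'
#' @param x,y numeric vectors
#' @param controls data.frame or matrix of control variables
#' @return list with rho, p, n, df
#' @export
partial_spearman <- function(x, y, controls) {
  controls <- as.data.frame(controls)
  cc <- stats::complete.cases(x, y, controls)
  x <- x[cc]; y <- y[cc]; controls <- controls[cc, , drop = FALSE]
  k <- ncol(controls)
  n <- length(x)
  if (n < k + 3) stop("need at least controls + 3 complete observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = n, df = n - 2 - k,
                flagged = "constant variable"))
  rx <- rank(x); ry <- rank(y)
  rc <- as.data.frame(lapply(controls, rank))
  res_x <- stats::resid(stats::lm(rx ~ ., data = rc))
  res_y <- stats::resid(stats::lm(ry ~ ., data = rc))
  rho <- stats::cor(res_x, res_y)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df,
       flagged = NA_character_)
}

# log transform with declared offsets; variables with zeros but no
# configured offset get half the smallest positive observed value
.log_transform <- function(df, offsets) {
  applied <- list()
  for (v in names(df)) {
    x <- df[[v]]
    off <- 0
    if (v %in% names(offsets)) off <- offsets[[v]]
    else if (any(x == 0, na.rm = TRUE)) {
      pos <- x[x > 0 & is.finite(x)]
      if (!length(pos)) stop("variable ", v, " has no positive values")
      off <- min(pos) / 2
    }
    if (any(x + off <= 0, na.rm = TRUE))
      stop("variable ", v, " not positive after offset")
    df[[v]] <- log(x + off)
    applied[[v]] <- off
  }
  list(data = df, offsets = unlist(applied))
}

#' Principal-component regression with jackknife predictor pruning
#'
#' All variables (dependent included) are log transformed (configured
#' additive offsets for the length variables; a variable with zeros and
#' no configured offset gets half its smallest positive value).
#' Predictors are centred and scaled, the dependent is regressed on all
#' principal components, and each component's explained percentage of
#' dependent variance is its squared correlation with the dependent.
#' Each predictor's coefficient on the predictor scale (loading-weighted
#' sum of the component slopes) is tested by leave-one-out jackknife with
#' a normal approximation; nonsignificant predictors are removed and the
#' analysis repeated until all remaining predictors are significant.
#'
#' @param data data.frame holding the dependent and predictor columns
#' @param dependent name of the dependent variable
#' @param predictors names of the predictor variables
#' @param alpha pruning significance level (default 0.05)
#' @param log_offsets named additive offsets applied before the log
#' @return object of class \code{pcr_model}: loadings, explained (% of
#'   dependent variance per component), selected (index of the best
#'   component), scores of the final model, jackknife (data.frame with
#'   estimate, se, p per predictor), pruning history, transformed data,
#'   offsets
#' @export
pc_regression <- function(data, dependent, predictors, alpha = 0.05,
                          log_offsets = c(gene_length = 1e-4,
                                          avg_intron_length = 1e-4)) {
  vars <- c(dependent, predictors)
  df <- data[, vars, drop = FALSE]
  df <- df[stats::complete.cases(df) &
             rowSums(!is.finite(as.matrix(df))) == 0, , drop = FALSE]
  if (nrow(df) < 10) stop("need at least 10 complete cases")
  tr <- .log_transform(df, log_offsets)
  df <- tr$data
  history <- list()
  preds <- predictors
  repeat {
    fit <- .pcr_fit(df[[dependent]], as.matrix(df[, preds, drop = FALSE]))
    jk <- .pcr_jackknife(df[[dependent]], as.matrix(df[, preds, drop = FALSE]))
    history[[length(history) + 1L]] <- list(predictors = preds,
                                            explained = fit$explained,
                                            selected = fit$selected,
                                            jackknife = jk)
    drop <- jk$predictor[jk$p >= alpha]
    if (!length(drop) || length(preds) - length(drop) < 1) break
    preds <- setdiff(preds, drop)
  }
  structure(list(dependent = dependent, predictors = preds,
                 all_predictors = predictors,
                 loadings = fit$loadings, explained = fit$explained,
                 selected = fit$selected, scores = fit$scores,
                 slope = fit$slopes[fit$selected],
                 jackknife = jk, history = history,
                 data = df, offsets = tr$offsets,
                 pruned_all = length(jk$predictor[jk$p >= alpha]) == length(preds)),
            class = "pcr_model")
}

.pcr_fit <- function(y, X) {
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  Z <- pc$x
  slopes <- vapply(seq_len(ncol(Z)), function(j)
    stats::cov(y, Z[, j]) / stats::var(Z[, j]), numeric(1))
  explained <- vapply(seq_len(ncol(Z)), function(j)
    100 * stats::cor(y, Z[, j])^2, numeric(1))
  explained[!is.finite(explained)] <- 0
  list(loadings = pc$rotation, scores = Z, slopes = slopes,
       explained = explained, selected = which.max(explained))
}

.pcr_jackknife <- function(y, X) {
  # per-predictor coefficient of the principal-component regression,
  # mapped back to the predictor scale through the loadings (summed over
  # all components; invariant to component sign)
  coefs <- function(yy, XX) {
    f <- .pcr_fit(yy, XX)
    as.numeric(f$loadings %*% f$slopes)
  }
  beta_full <- coefs(y, X)
  n <- length(y)
  betas <- matrix(NA_real_, n, ncol(X))
  for (i in seq_len(n))
    betas[i, ] <- coefs(y[-i], X[-i, , drop = FALSE])
  m <- colMeans(betas)
  se <- sqrt((n - 1) / n * colSums(sweep(betas, 2, m)^2))
  z <- beta_full / se
  data.frame(predictor = colnames(X), estimate = beta_full, se = se,
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model %s ~ %s | PC%d explains %.2f%% (total %.2f%%)>\n",
              x$dependent, paste(x$predictors, collapse = "+"),
              x$selected, x$explained[x$selected], sum(x$explained)))
  invisible(x)
}

#' ANCOVA with life-stage covariate and equal-count quantile bins
#'
#' Fits dependent ~ pc * group on the (already log-transformed) dependent
#' and reports the group and interaction (slope-difference) p-values.
#' When the slopes differ significantly, the pooled component axis is
#' split into n_bins equal-count bins and a Mann-Whitney test with
#' Bonferroni family n_bins is run within each bin.
#'
#' @param dependent numeric vector (log scale)
#' @param pc_scores component scores on the pooled data
#' @param group factor or character with exactly two levels
#' @param n_bins number of quantile bins (default 5)
#' @param alpha significance level for the interaction gate
#' @param force_bins run the binned tests regardless of the interaction
#' @return list of class \code{group_comparison}: model (lm), group_p,
#'   interaction_p, slopes (per group), bins (data.frame with per-bin
#'   medians, means, raw and adjusted p; NULL if not run)
#' @export
ancova_with_bins <- function(dependent, pc_scores, group, n_bins = 5,
                             alpha = 0.05, force_bins = FALSE) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2, length(dependent) == length(pc_scores),
            length(group) == length(dependent))
  dat <- data.frame(y = dependent, pc = pc_scores, g = group)
  dat <- dat[stats::complete.cases(dat) & is.finite(dat$y) & is.finite(dat$pc), ]
  fit <- stats::lm(y ~ pc * g, data = dat)
  sm <- summary(fit)$coefficients
  group_p <- sm[3, 4]
  interaction_p <- sm[4, 4]
  slopes <- c(sm[2, 1], sm[2, 1] + sm[4, 1])
  names(slopes) <- levels(group)
  bins <- NULL
  if (force_bins || interaction_p < alpha) {
    # equal-count bins along the pooled component axis
    idx <- ceiling(rank(dat$pc, ties.method = "first") * n_bins / nrow(dat))
    rows <- lapply(seq_len(n_bins), function(b) {
      sel <- idx == b
      ya <- dat$y[sel & dat$g == levels(group)[1]]
      yb <- dat$y[sel & dat$g == levels(group)[2]]
      if (!length(ya) || !length(yb))
        return(data.frame(bin = b, n_a = length(ya), n_b = length(yb),
                          median_a = NA, median_b = NA, mean_a = NA,
                          mean_b = NA, raw_p = NA, adj_p = NA, tested = FALSE))
      mw <- mann_whitney_bonferroni(ya, yb, family_size = n_bins)
      data.frame(bin = b, n_a = length(ya), n_b = length(yb),
                 median_a = stats::median(ya), median_b = stats::median(yb),
                 mean_a = mean(ya), mean_b = mean(yb),
                 raw_p = mw$raw_p, adj_p = mw$adj_p, tested = TRUE)
    })
    bins <- do.call(rbind, rows)
  }
  structure(list(model = fit, group_p = group_p,
                 interaction_p = interaction_p, slopes = slopes,
                 levels = levels(group), bins = bins, n = nrow(dat)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison %s vs %s | group p=%.3g, interaction p=%.3g%s>\n",
              x$levels[1], x$levels[2], x$group_p, x$interaction_p,
              if (!is.null(x$bins)) paste0(", ", nrow(x$bins), " bins") else ""))
  invisible(x)
}

#' Covariate-controlled comparison of a statistic between two gene groups
#'
#' The full machinery in one call: a plain Mann-Whitney test on the raw
#' statistic, a principal-component regression of the statistic on the
#' genomic covariates over the pooled groups (with jackknife pruning),
#' and an ANCOVA of the log statistic on the best component with the
#' group as binary covariate (binned tests when slopes differ).
#'
#' @param stats_table data.frame with gene_id and the dependent column
#' @param covariates output of \code{\link{compute_covariates}}
#' @param groups list with gene-id vectors \code{a} and \code{b} (see
#'   \code{\link{select_comparison_groups}})
#' @param dependent name of the statistic column in stats_table
#' @param predictors covariate columns (default the six genomic
#'   covariates)
#' @param family_size Bonferroni family of the raw test
#' @param alpha pruning / interaction significance level
#' @return list: mw (raw-group test), pcr (pcr_model), ancova
#'   (group_comparison), data (merged analysis frame)
#' @export
compare_groups <- function(stats_table, covariates, groups, dependent,
                           predictors = c("expression_level", "gc_percent",
                                          "rscu_variance", "gene_length",
                                          "avg_intron_length", "gene_density"),
                           family_size = 1, alpha = 0.05) {
  d <- merge(stats_table, covariates, by = "gene_id")
  d$group <- ifelse(d$gene_id %in% groups$a, "a",
                    ifelse(d$gene_id %in% groups$b, "b", NA))
  d <- d[!is.na(d$group), , drop = FALSE]
  mw <- mann_whitney_bonferroni(d[[dependent]][d$group == "a"],
                                d[[dependent]][d$group == "b"],
                                family_size = family_size)
  pcr <- pc_regression(d, dependent, predictors, alpha = alpha)
  # rows surviving the PCR's complete-case filtering, in order
  used <- match(rownames(pcr$data), rownames(d))
  anc <- ancova_with_bins(pcr$data[[dependent]],
                          pcr$scores[, pcr$selected],
                          d$group[used], alpha = alpha)
  list(mw = mw, pcr = pcr, ancova = anc, data = d)
}
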