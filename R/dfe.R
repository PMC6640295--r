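# Gamma distribution-of-fitness-effects estimation from paired synonymous
# / nonsynonymous site-frequency spectra (the GammaZero family: all-
# deleterious gamma DFE, no beneficial mass), with per-frequency-class
# nuisance multipliers r_i shared by both site categories, Poisson
# likelihood, discretisation into Nes bins, the adaptive proportion alpha,
# and a gene bootstrap.
#
# Scaled selection is parameterised internally as S = 4 Ne s (magnitude of
# the deleterious effect); reported bins follow the Nes convention, i.e.
# bin edges are multiplied by 4 before evaluating the gamma CDF.
#
# Numerics: the population frequency density of a deleterious mutation
# with scaled effect S is H(x; -S) = (1 - e^{-S(1-x)}) / (x(1-x)(1-e^{-S}))
# (limit 1/x as S -> 0). Sample-frequency weights are Gauss-Legendre
# integrals of binomial sampling against H; the gamma expectation over S
# uses Gauss-Legendre on the probability scale (nodes at gamma quantiles),
# which is deterministic and singularity-free.

.gl_nodes <- function(m, a = 0, b = 1) {
  key <- paste0("gl", m, "_", a, "_", b)
  hit <- .pollensel_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- pracma::gaussLegendre(m, a, b)
  .pollensel_cache[[key]] <- g
  g
}

# binomial sampling kernel C(n,i) x^i (1-x)^(n-i) evaluated at the x nodes,
# cached per (n, nx): matrix (n-1) x nx
.binom_kernel <- function(n, nx) {
  key <- paste0("bk", n, "_", nx)
  hit <- .pollensel_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- .gl_nodes(nx)
  i <- seq_len(n - 1L)
  lx <- log(g$x); l1x <- log1p(-g$x)
  B <- exp(outer(i, lx) + outer(n - i, l1x) + lchoose(n, i))
  .pollensel_cache[[key]] <- list(B = B, x = g$x, w = g$w)
  .pollensel_cache[[key]]
}

# H(x; -S) for S >= 0 (deleterious magnitude), stable for large S:
# e^{-Sx} (1 - e^{-S(1-x)}) / (x (1-x) (1 - e^{-S}))
.h_sel <- function(x, S) {
  if (S < 1e-8) return(1 / x)
  exp(-S * x) * (-expm1(-S * (1 - x))) / (x * (1 - x) * (-expm1(-S)))
}

#' Expected sample-frequency weights under a gamma DFE
#'
#' Weight of frequency class i (i = 1..n-1) is the gamma expectation over
#' the scaled effect S of the integral of binomial sampling against the
#' deleterious frequency density H(x; -S). With mean_S = 0 the exact
#' neutral weights 1/i are returned.
#'
#' @param n haploid sample size
#' @param shape gamma shape (b > 0)
#' @param mean_S mean scaled effect E[4 Ne s] >= 0
#' @param nx Gauss-Legendre order on the frequency axis
#' @param ns Gauss-Legendre order on the gamma probability axis
#' @return numeric vector of length n - 1
#' @export
sfs_weights <- function(n, shape, mean_S, nx = 160, ns = 64) {
  stopifnot(n >= 4, shape > 0, mean_S >= 0)
  i <- seq_len(n - 1L)
  if (mean_S == 0) return(1 / i)
  bk <- .binom_kernel(n, nx)
  gs <- .gl_nodes(ns)
  Sj <- stats::qgamma(gs$x, shape = shape, scale = mean_S / shape)
  H <- vapply(Sj, function(S) .h_sel(bk$x, S), numeric(nx))  # nx x ns
  if (!all(is.finite(H))) stop("quadrature failure at shape=", shape,
                               " mean_S=", mean_S)
  inner <- H %*% gs$w            # E_gamma[H(x; -S)] at each x node
  as.numeric(bk$B %*% (bk$w * inner))
}

#' Fold an unfolded spectrum (or weight vector) to minor-allele classes
#' @param v numeric vector of length n - 1
#' @param n haploid sample size
#' @return vector of length floor(n / 2)
#' @export
fold_sfs <- function(v, n) {
  stopifnot(length(v) == n - 1L)
  K <- n %/% 2L
  out <- numeric(K)
  for (i in seq_len(K)) out[i] <- if (i == n - i) v[i] else v[i] + v[n - i]
  out
}

#' Expected SFS counts for one site category
#'
#' Expected count in class i is theta * L * r_i * weight_i, with the
#' weights from \code{\link{sfs_weights}} (synonymous sites use
#' mean_S = 0). Folding sums classes i and n - i; the nuisance
#' multipliers r index the (possibly folded) observed classes, r[1] = 1.
#'
#' @inheritParams sfs_weights
#' @param theta per-site mutation parameter
#' @param r nuisance multipliers (length n - 1 unfolded, floor(n/2)
#'   folded), or NULL for all 1
#' @param L number of sites
#' @param fold fold the spectrum
#' @export
expected_sfs <- function(shape, mean_S, theta, r = NULL, n, L, fold = TRUE) {
  w <- sfs_weights(n, shape, mean_S)
  if (fold) w <- fold_sfs(w, n)
  if (is.null(r)) r <- rep(1, length(w))
  stopifnot(length(r) == length(w), abs(r[1] - 1) < 1e-12)
  theta * L * r * w
}

# Profile log-likelihood machinery: given (shape, mean_S) the Poisson MLEs
# of theta and of each r_i (i >= 2) are closed-form, because each r_i
# scales its class in both categories and theta scales class 1 (r_1 = 1).
.dfe_profile <- function(pars, obs_n, obs_s, n, L_n, L_s, fold, r_free) {
  shape <- exp(pars[1]); mean_S <- exp(pars[2])
  wn <- sfs_weights(n, shape, mean_S)
  ws <- 1 / seq_len(n - 1L)
  if (fold) { wn <- fold_sfs(wn, n); ws <- fold_sfs(ws, n) }
  En0 <- L_n * wn; Es0 <- L_s * ws
  if (r_free) {
    theta <- (obs_n[1] + obs_s[1]) / (En0[1] + Es0[1])
    r <- (obs_n + obs_s) / (theta * (En0 + Es0))
    r[1] <- 1
    r[!is.finite(r)] <- 1
  } else {
    theta <- sum(obs_n + obs_s) / sum(En0 + Es0)
    r <- rep(1, length(wn))
  }
  lam_n <- pmax(theta * r * En0, 1e-300)
  lam_s <- pmax(theta * r * Es0, 1e-300)
  ll <- sum(stats::dpois(obs_n, lam_n, log = TRUE)) +
    sum(stats::dpois(obs_s, lam_s, log = TRUE))
  list(ll = ll, theta = theta, r = r)
}

#' Fit a gamma DFE to a pair of spectra
#'
#' Maximises the Poisson likelihood of the synonymous and nonsynonymous
#' spectra jointly over (shape, mean scaled effect), profiling out theta
#' and the per-class nuisance multipliers r (closed-form Poisson MLEs);
#' optimisation is multi-start L-BFGS-B on the log scale.
#'
#' @param sfs sfs_pair object (see \code{\link{build_sfs}})
#' @param r_free estimate per-class nuisance multipliers (default TRUE);
#'   with FALSE all r_i are fixed to 1
#' @param starts matrix of starting values, columns (shape, mean_S)
#' @param bin_edges Nes bin edges for the reported discretisation
#' @return object of class \code{dfe_fit}: shape, mean_S (4Nes scale),
#'   mean_Nes, theta_hat, r, log_likelihood, bin_proportions, convergence,
#'   boundary flag, plus the data dimensions
#' @export
fit_gamma_dfe <- function(sfs, r_free = TRUE,
                          starts = NULL,
                          bin_edges = c(0, 2, 10, 100, Inf)) {
  stopifnot(inherits(sfs, "sfs_pair"), sfs$L_n > 0, sfs$L_s > 0)
  if (is.null(starts))
    starts <- cbind(shape = c(0.1, 0.3, 0.5, 1, 2),
                    mean_S = c(10, 100, 1000, 50, 5000))
  lb <- log(c(0.01, 1e-3)); ub <- log(c(20, 1e7))
  obs_n <- sfs$sfs_n; obs_s <- sfs$sfs_s
  nll <- function(p) -.dfe_profile(p, obs_n, obs_s, sfs$n, sfs$L_n, sfs$L_s,
                                   sfs$fold, r_free)$ll
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- log(as.numeric(starts[k, ]))
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  prof <- .dfe_profile(best$par, obs_n, obs_s, sfs$n, sfs$L_n, sfs$L_s,
                       sfs$fold, r_free)
  shape <- exp(best$par[1]); mean_S <- exp(best$par[2])
  boundary <- any(abs(best$par - lb) < 1e-6) || any(abs(best$par - ub) < 1e-6)
  structure(list(
    shape = shape, mean_S = mean_S, mean_Nes = mean_S / 4,
    theta_hat = prof$theta, r = prof$r,
    log_likelihood = -best$value,
    bin_proportions = dfe_discretize(shape, mean_S, bin_edges),
    bin_edges = bin_edges,
    convergence = best$convergence, boundary = boundary,
    n = sfs$n, fold = sfs$fold, L_n = sfs$L_n, L_s = sfs$L_s,
    r_free = r_free
  ), class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("<dfe_fit shape=%.3f mean 4Nes=%.1f theta=%.3g logL=%.2f%s>\n",
              x$shape, x$mean_S, x$theta_hat, x$log_likelihood,
              if (x$boundary) " [boundary]" else ""))
  cat("  Nes bins:", paste(sprintf("%.3f", x$bin_proportions), collapse = " "), "\n")
  invisible(x)
}

#' Discretise a gamma DFE into Nes bins
#'
#' Proportions are gamma CDF differences at the bin edges. Edges are on
#' the Nes scale by default; the internal parameterisation is S = 4 Ne s,
#' so the gamma with mean mean_S is evaluated at 4 x the edges.
#'
#' @param shape gamma shape, or a dfe_fit object (then the second
#'   positional argument is taken as the bin edges)
#' @param mean_S mean scaled effect on the 4Nes scale
#' @param bin_edges increasing edges, first typically 0, last Inf
#' @param scale "Nes" (default) or "S" (edges already on the 4Nes scale)
#' @return named vector of proportions summing to 1
#' @export
dfe_discretize <- function(shape, mean_S = NULL,
                           bin_edges = c(0, 2, 10, 100, Inf),
                           scale = c("Nes", "S")) {
  scale <- match.arg(scale)
  if (inherits(shape, "dfe_fit")) {
    if (!is.null(mean_S)) bin_edges <- mean_S
    mean_S <- shape$mean_S
    shape <- shape$shape
  }
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  edges <- if (scale == "Nes") 4 * bin_edges else bin_edges
  cdf <- stats::pgamma(edges, shape = shape, scale = mean_S / shape)
  p <- diff(cdf)
  names(p) <- paste0("[", bin_edges[-length(bin_edges)], ",",
                     bin_edges[-1], ")")
  p / sum(p)
}

#' Expectation of a function of the scaled effect under the fitted gamma
#' @param f vectorised function of S
#' @param shape,mean_S gamma parameters (S scale)
#' @param ns quadrature order
#' @keywords internal
gamma_expect <- function(f, shape, mean_S, ns = 128) {
  if (mean_S == 0) return(f(0))
  g <- .gl_nodes(ns)
  S <- stats::qgamma(g$x, shape = shape, scale = mean_S / shape)
  sum(g$w * f(S))
}

#' Adaptive proportion alpha from a DFE fit and divergence counts
#'
#' The expected non-adaptive dN/dS is the gamma expectation of the
#' relative fixation probability of a deleterious mutation,
#' S / (e^S - 1) (1 at S = 0, 0 as S grows); alpha subtracts the
#' corresponding expected non-adaptive divergence from the observed:
#' alpha = 1 - (D_s L_n / (D_n L_s)) * E[S / (e^S - 1)].
#'
#' @param fit dfe_fit object
#' @param sfs sfs_pair with divergence counts D_n, D_s > 0
#' @return list with alpha, expected_omega_na
#' @export
estimate_alpha <- function(fit, sfs) {
  if (is.null(sfs$D_n) || sfs$D_n == 0)
    return(list(alpha = NA_real_, expected_omega_na = NA_real_,
                flagged = "D_n is zero"))
  if (is.null(sfs$D_s) || sfs$D_s == 0)
    return(list(alpha = NA_real_, expected_omega_na = NA_real_,
                flagged = "D_s is zero"))
  f <- function(S) ifelse(S < 1e-8, 1, S / expm1(S))
  e_na <- gamma_expect(f, fit$shape, fit$mean_S)
  alpha <- 1 - (sfs$D_s * sfs$L_n / (sfs$D_n * sfs$L_s)) * e_na
  list(alpha = alpha, expected_omega_na = e_na, flagged = NA_character_)
}

#' Simulate an SFS pair from the DFE model
#'
#' Poisson counts around the model expectation with all r_i = 1;
#' the independent-sites analogue of summing many genes.
#'
#' @inheritParams expected_sfs
#' @param L_n,L_s site counts of the two categories
#' @param d_n,d_s optional per-site divergence, converted to Poisson
#'   substitution counts D = Pois(d * L)
#' @return sfs_pair object
#' @export
simulate_sfs_pair <- function(shape, mean_S, theta, n, L_n, L_s,
                              fold = TRUE, d_n = NULL, d_s = NULL) {
  en <- expected_sfs(shape, mean_S, theta, NULL, n, L_n, fold)
  es <- expected_sfs(1, 0, theta, NULL, n, L_s, fold)
  sfs_n <- stats::rpois(length(en), en)
  sfs_s <- stats::rpois(length(es), es)
  structure(list(n = n, fold = fold, sfs_n = sfs_n, sfs_s = sfs_s,
                 L_n = L_n, L_s = L_s, S_n = sum(sfs_n), S_s = sum(sfs_s),
                 D_n = if (is.null(d_n)) 0 else stats::rpois(1, d_n * L_n),
                 D_s = if (is.null(d_s)) 0 else stats::rpois(1, d_s * L_s),
                 n_triallelic = 0L),
            class = "sfs_pair")
}

#' Bootstrap a DFE fit over genes
#'
#' Resamples genes with replacement, sums their spectra, site and
#' divergence counts, and refits (warm-started at the point estimate);
#' percentile confidence intervals are computed per quantity. Fully
#' deterministic under the seed.
#'
#' @param gene_sfs list of per-gene sfs_pair objects (identical n, fold)
#' @param B number of bootstrap replicates (default 1000)
#' @param seed integer seed
#' @param conf confidence level (default 0.95)
#' @param r_free passed to \code{\link{fit_gamma_dfe}}
#' @param bin_edges Nes bin edges
#' @return list of class \code{dfe_bootstrap}: point (dfe_fit), ci
#'   (matrix with lower/upper rows), replicates (data.frame), B,
#'   n_failed
#' @export
dfe_bootstrap <- function(gene_sfs, B = 1000, seed = 1, conf = 0.95,
                          r_free = TRUE, bin_edges = c(0, 2, 10, 100, Inf)) {
  pooled <- sum_sfs_pairs(gene_sfs)
  point <- fit_gamma_dfe(pooled, r_free = r_free, bin_edges = bin_edges)
  warm <- cbind(shape = point$shape, mean_S = point$mean_S)
  G <- length(gene_sfs)
  set.seed(seed)
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(G, G, replace = TRUE)
    sp <- sum_sfs_pairs(gene_sfs[idx])
    fit <- tryCatch(
      fit_gamma_dfe(sp, r_free = r_free, starts = warm, bin_edges = bin_edges),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    al <- estimate_alpha(fit, sp)
    reps[[b]] <- c(shape = fit$shape, mean_S = fit$mean_S,
                   theta = fit$theta_hat, fit$bin_proportions,
                   alpha = al$alpha)
  }
  if (n_failed > 0.05 * B)
    warning(n_failed, " of ", B, " bootstrap replicate fits failed")
  reps <- as.data.frame(do.call(rbind, reps[!vapply(reps, is.null, logical(1))]))
  a <- (1 - conf) / 2
  ci <- vapply(reps, function(v) stats::quantile(v, c(a, 1 - a), na.rm = TRUE,
                                                 names = FALSE),
               numeric(2))
  rownames(ci) <- c("lower", "upper")
  structure(list(point = point, ci = ci, replicates = reps, B = B,
                 n_failed = n_failed, conf = conf, seed = seed),
            class = "dfe_bootstrap")
}

#' @export
print.dfe_bootstrap <- function(x, ...) {
  cat(sprintf("<dfe_bootstrap B=%d (%d failed) shape=%.3f [%.3f, %.3f]>\n",
              x$B, x$n_failed, x$point$shape,
              x$ci["lower", "shape"], x$ci["upper", "shape"]))
  invisible(x)
}
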