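# Gamma-DFE machinery: expected spectra, fitting, discretisation, alpha
# and the gene bootstrap. The heavy parameter-recovery and coverage runs
# live in the acceptance suite; these tests pin the model's limits and
# identities.

test_that("neutral weights are exactly 1/i, selected weights recover them as S -> 0", {
  n <- 20
  w0 <- sfs_weights(n, shape = 1, mean_S = 0)
  expect_equal(w0, 1 / seq_len(n - 1))
  w_tiny <- sfs_weights(n, shape = 1, mean_S = 1e-6)
  expect_equal(w_tiny, w0, tolerance = 1e-4)
  # deleterious selection skews the spectrum toward singletons
  w_sel <- sfs_weights(n, shape = 0.3, mean_S = 1000)
  expect_gt(w_sel[1] / sum(w_sel), w0[1] / sum(w0))
})

test_that("expected_sfs is proportional between categories in the neutral limit", {
  en <- expected_sfs(1, 0, theta = 0.01, n = 20, L = 3000, fold = TRUE)
  es <- expected_sfs(1, 0, theta = 0.01, n = 20, L = 1000, fold = TRUE)
  expect_equal(en / es, rep(3, length(en)))
  # unfolded neutral class i is theta L / i before r scaling
  eu <- expected_sfs(1, 0, theta = 0.01, n = 20, L = 1000, fold = FALSE)
  expect_equal(eu, 0.01 * 1000 / seq_len(19))
})

test_that("expected class weights match Monte-Carlo sampling from the generator", {
  n <- 20
  w <- sfs_weights(n, shape = 0.3, mean_S = 200)
  p <- w / sum(w)
  set.seed(51)
  N <- 2e5
  draws <- sample.int(n - 1, N, replace = TRUE, prob = p)
  counts <- tabulate(draws, nbins = n - 1)
  # goodness of fit of the sampled class counts against the expectation
  chi <- sum((counts - N * p)^2 / (N * p))
  expect_gt(pchisq(chi, df = n - 2, lower.tail = FALSE), 1e-3)
  # and no single class drifts far beyond its binomial error
  se <- sqrt(N * p * (1 - p))
  expect_true(all(abs(counts - N * p) <= 4 * se))
})

test_that("folding weights then summing equals summing then folding", {
  n <- 20
  w <- sfs_weights(n, 0.5, 100)
  expect_equal(fold_sfs(w, n),
               w[1:10] + c(w[19:11], 0)[1:10])
})

test_that("discretisation matches the exponential closed form and quadrature", {
  p <- dfe_discretize(shape = 1, mean_S = 10, bin_edges = c(0, 2, 10, Inf),
                      scale = "S")
  expect_equal(unname(p),
               c(1 - exp(-0.2), exp(-0.2) - exp(-1), exp(-1)))
  # near point mass at the mean: all mass where the mean lies
  p2 <- dfe_discretize(shape = 2000, mean_S = 5, bin_edges = c(0, 2, 10, Inf),
                       scale = "S")
  expect_gt(p2[2], 0.999)
  # independent quadrature oracle for a non-trivial shape
  shape <- 0.4; mean_S <- 300; edges <- c(0, 2, 10, 100, Inf)
  p3 <- dfe_discretize(shape, mean_S, edges, scale = "Nes")
  dens <- function(x) dgamma(x, shape = shape, scale = mean_S / shape)
  for (k in seq_len(length(edges) - 1)) {
    want <- integrate(dens, 4 * edges[k], min(4 * edges[k + 1], Inf),
                      rel.tol = 1e-10)$value
    expect_equal(unname(p3[k]), want, tolerance = 1e-6)
  }
})

test_that("a neutral-proportional spectrum is fitted as effectively neutral", {
  n <- 40
  w <- fold_sfs(1 / seq_len(n - 1), n)
  sp <- structure(list(n = n, fold = TRUE,
                       sfs_n = round(4000 * w), sfs_s = round(1000 * w),
                       L_n = 4000, L_s = 1000,
                       S_n = sum(round(4000 * w)), S_s = sum(round(1000 * w)),
                       D_n = 0, D_s = 0, n_triallelic = 0L),
                  class = "sfs_pair")
  fit <- fit_gamma_dfe(sp)
  expect_gt(dfe_discretize(fit, c(0, 1, Inf))[1], 0.95)
})

test_that("fits with r fixed to 1 agree with free-r fits on equilibrium data", {
  set.seed(52)
  sp <- simulate_sfs_pair(0.3, 400, 0.005, n = 40, L_n = 5e5, L_s = 2e5)
  f_free <- fit_gamma_dfe(sp, r_free = TRUE)
  f_fix <- fit_gamma_dfe(sp, r_free = FALSE)
  expect_equal(f_free$shape, f_fix$shape, tolerance = 0.1)
  expect_true(all(abs(f_free$r - 1) < 0.2))  # no demographic distortion simulated
})

test_that("the likelihood peaks near the generating parameters", {
  set.seed(53)
  sp <- simulate_sfs_pair(0.3, 400, 0.005, n = 40, L_n = 2e6, L_s = 5e5)
  ll <- function(shape, mean_S) {
    en <- expected_sfs(shape, mean_S, 0.005, n = 40, L = 2e6, fold = TRUE)
    es <- expected_sfs(1, 0, 0.005, n = 40, L = 5e5, fold = TRUE)
    sum(dpois(sp$sfs_n, en, log = TRUE)) + sum(dpois(sp$sfs_s, es, log = TRUE))
  }
  l0 <- ll(0.3, 400)
  expect_gt(l0, ll(0.45, 400))
  expect_gt(l0, ll(0.15, 400))
  expect_gt(l0, ll(0.3, 600))
  expect_gt(l0, ll(0.3, 200))
})

test_that("alpha limits: zero for neutral-equal rates, one for strong selection", {
  neutral_fit <- structure(list(shape = 1, mean_S = 0), class = "dfe_fit")
  sp <- structure(list(n = 20, fold = TRUE, sfs_n = 1, sfs_s = 1,
                       L_n = 1000, L_s = 500, D_n = 100, D_s = 50),
                  class = "sfs_pair")
  # D_n / L_n = D_s / L_s and E[omega_na] = 1: alpha = 0
  expect_equal(estimate_alpha(neutral_fit, sp)$alpha, 0)
  strong_fit <- structure(list(shape = 50, mean_S = 5e4), class = "dfe_fit")
  expect_gt(estimate_alpha(strong_fit, sp)$alpha, 0.999)
  sp$D_n <- 0
  expect_true(is.na(estimate_alpha(neutral_fit, sp)$alpha))
})

test_that("alpha is recovered on data with a known adaptive fraction", {
  set.seed(54)
  shape <- 0.3; mean_S <- 400; alpha_true <- 0.3
  e_na <- pollensel:::gamma_expect(function(S) ifelse(S < 1e-8, 1, S / expm1(S)),
                                   shape, mean_S)
  d_s <- 0.1
  d_n <- e_na * d_s / (1 - alpha_true)   # total dN = non-adaptive / (1 - alpha)
  sp <- simulate_sfs_pair(shape, mean_S, 0.005, n = 80, L_n = 2e6, L_s = 5e5,
                          d_n = d_n, d_s = d_s)
  fit <- fit_gamma_dfe(sp)
  got <- estimate_alpha(fit, sp)$alpha
  expect_lt(abs(got - alpha_true), 0.05)
})

test_that("the gene bootstrap is seeded and degenerates with one gene", {
  set.seed(55)
  genes <- replicate(12, simulate_sfs_pair(0.3, 300, 0.005, n = 20,
                                           L_n = 2e4, L_s = 5e3),
                     simplify = FALSE)
  b1 <- dfe_bootstrap(genes, B = 10, seed = 99)
  b2 <- dfe_bootstrap(genes, B = 10, seed = 99)
  expect_equal(b1$ci, b2$ci)
  expect_equal(b1$replicates, b2$replicates)
  # a single gene: every resample is the identity, interval degenerate
  b3 <- dfe_bootstrap(genes[1], B = 3, seed = 1)
  expect_equal(unname(b3$ci["lower", "shape"]), unname(b3$ci["upper", "shape"]))
  expect_equal(unname(b3$ci["lower", "shape"]), b3$point$shape, tolerance = 1e-6)
})
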