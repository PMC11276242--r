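# Subspace steps against numeric oracles, the iterative fit, prediction,
# one-shot learning, and grid search.

test_that("Gaussian step equals affiliation-weighted means and SDs", {
  # K = 1, full weights: plain mean and population SD
  th <- update_mu_sigma(matrix(c(1, 3), 1, 2), matrix(1, 1, 2))
  expect_equal(th$mu, matrix(2, 1, 1), ignore_attr = TRUE)
  expect_equal(th$sigma, matrix(1, 1, 1), ignore_attr = TRUE)
  # hard one-hot affiliations: per-cluster statistics of each cluster's points
  set.seed(31)
  X <- matrix(rnorm(20), 2, 10)
  hard <- rep(1:2, each = 5)
  G <- matrix(0, 2, 10); G[cbind(hard, 1:10)] <- 1
  th <- update_mu_sigma(X, G)
  for (k in 1:2) {
    idx <- hard == k
    expect_equal(th$mu[, k], rowMeans(X[, idx]))
    expect_equal(th$sigma[, k],
                 sqrt(rowMeans((X[, idx] - rowMeans(X[, idx]))^2)))
  }
  # empty cluster is reseeded with a warning, output stays finite
  G0 <- rbind(rep(1, 10), rep(0, 10))
  expect_warning(th0 <- update_mu_sigma(X, G0), "reseeding")
  expect_true(all(is.finite(th0$mu)) && all(th0$sigma > 0))
})

test_that("Gaussian step matches a derivative-free minimizer of the likelihood term", {
  set.seed(32)
  X <- matrix(rnorm(5), 1, 5)
  G <- rand_gamma(2, 5)
  th <- update_mu_sigma(X, G)
  for (k in 1:2) {
    o <- stats::optim(c(0, 0), function(p) {
      sum(G[k, ] * gaussian_nll(X[1, ], p[1], exp(p[2])))
    }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 5000))
    expect_equal(th$mu[1, k], o$par[1], tolerance = 1e-5)
    expect_equal(th$sigma[1, k], exp(o$par[2]), tolerance = 1e-5)
  }
})

test_that("classifier step normalizes the joint label-cluster mass", {
  # bijective one-hot case: identity classifier
  Pi <- rand_onehot_pi(2, 10)
  expect_equal(update_lambda(Pi, Pi), diag(2), ignore_attr = TRUE)
  # uniform affiliations: every column is the empirical label distribution
  # (hand case: 4 points, labels 1,1,1,2)
  Pi4 <- matrix(c(1, 0, 1, 0, 1, 0, 0, 1), 2, 4)
  G4 <- matrix(1 / 3, 3, 4)
  L <- update_lambda(Pi4, G4)
  expect_equal(L, matrix(c(0.75, 0.25), 2, 3), ignore_attr = TRUE)
  # columns always sum to one
  set.seed(33)
  L2 <- update_lambda(rand_onehot_pi(3, 12), rand_gamma(4, 12))
  expect_equal(colSums(L2), rep(1, 4))
})

test_that("feature-weight step is the entropic softmax with the right limits", {
  set.seed(34)
  # symmetric accumulated errors -> uniform weights
  X <- matrix(c(1, 1, -1, -1), 2, 2)   # both dims identical profiles
  G <- matrix(1, 1, 2)
  th <- update_mu_sigma(X, G)
  expect_equal(update_w(X, G, th$mu, th$sigma, 1), c(0.5, 0.5))
  # engineered two-dimension case: b = (0, log 3) at T = 1, eps_E = 1
  # (sigma chosen so the NLL at the mean is 0 resp. log 3)
  Xe <- matrix(0, 2, 1)
  mu <- matrix(0, 2, 1)
  sigma <- matrix(c(1 / sqrt(2 * pi), 3 / sqrt(2 * pi)), 2, 1)
  Ge <- matrix(1, 1, 1)
  expect_equal(update_w(Xe, Ge, mu, sigma, 1), c(0.75, 0.25),
               tolerance = 1e-12)
  # temperature limits: eps_E large -> uniform; eps_E -> 0 -> argmin one-hot
  inst <- rand_instance(D = 4, K = 2, Tn = 10)
  w_hot <- update_w(inst$X, inst$G, inst$mu, inst$sigma, 1e10)
  expect_equal(w_hot, rep(0.25, 4), tolerance = 1e-6)
  w_cold <- update_w(inst$X, inst$G, inst$mu, inst$sigma, 1e-12)
  expect_equal(sort(w_cold, decreasing = TRUE)[1], 1, tolerance = 1e-9)
})

test_that("feature-weight step matches a numeric constrained minimizer", {
  set.seed(35)
  for (i in 1:5) {
    inst <- rand_instance(D = sample(2:4, 1), K = 2, Tn = 8,
                          eps_E = runif(1, 0.05, 0.5))
    w <- update_w(inst$X, inst$G, inst$mu, inst$sigma, inst$hp$eps_E, inst$hp$eps_L)
    fW <- function(W) {
      l <- eval_loss(inst$X, inst$Pi, inst$G, inst$mu, inst$sigma,
                     inst$Lambda, W, inst$P, inst$hp, check = FALSE)
      l$likelihood + l$entropy
    }
    num <- simplex_numeric_min(fW, inst$D)
    expect_equal(fW(w), num$value, tolerance = 1e-5)
    expect_equal(w, num$x, tolerance = 1e-3)
  }
})

test_that("each analytic step is conditionally optimal against random feasible perturbations", {
  set.seed(36)
  inst <- rand_instance(D = 3, K = 3, Tn = 12)
  th <- update_mu_sigma(inst$X, inst$G)
  Lam <- update_lambda(inst$Pi, inst$G)
  W <- update_w(inst$X, inst$G, th$mu, th$sigma, inst$hp$eps_E, inst$hp$eps_L)
  base <- eval_loss(inst$X, inst$Pi, inst$G, th$mu, th$sigma, Lam, W,
                    inst$P, inst$hp, check = FALSE)
  for (r in 1:200) {
    # perturb theta
    l_th <- eval_loss(inst$X, inst$Pi, inst$G,
                      th$mu + matrix(rnorm(9, sd = 0.1), 3, 3),
                      th$sigma * exp(matrix(rnorm(9, sd = 0.1), 3, 3)),
                      Lam, W, inst$P, inst$hp, check = FALSE)
    expect_gte(l_th$likelihood, base$likelihood - 1e-12)
    # perturb Lambda on the feasible set
    Lp <- Lam * matrix(exp(rnorm(length(Lam), sd = 0.3)), nrow(Lam))
    Lp <- sweep(Lp, 2, colSums(Lp), "/")
    l_lam <- eval_loss(inst$X, inst$Pi, inst$G, th$mu, th$sigma, Lp, W,
                       inst$P, inst$hp, check = FALSE)
    expect_gte(l_lam$classification, base$classification - 1e-12)
    # perturb W on the simplex
    Wp <- W * exp(rnorm(3, sd = 0.3)); Wp <- Wp / sum(Wp)
    l_w <- eval_loss(inst$X, inst$Pi, inst$G, th$mu, th$sigma, Lam, Wp,
                     inst$P, inst$hp, check = FALSE)
    expect_gte(l_w$likelihood + l_w$entropy,
               base$likelihood + base$entropy - 1e-12)
  }
})

test_that("the coordinate-descent fit decreases the loss monotonically", {
  set.seed(37)
  for (i in 1:5) {
    D <- sample(1:3, 1); K <- sample(2:3, 1); Tn <- sample(10:25, 1)
    X <- matrix(rnorm(D * Tn), D, Tn)
    Pi <- rand_onehot_pi(2, Tn)
    m <- espa_markov(X, Pi, K = K, eps_L = runif(1, 0.1, 2),
                     eps_E = runif(1, 0.01, 0.2),
                     eps_CL = runif(1, 0.001, 0.05),
                     n_starts = 2, seed = i)
    expect_true(all(diff(m$trace) <= 1e-9))
    expect_lte(m$loss$total, m$initial_loss + 1e-12)
    expect_true(validate_feasible(m$Gamma, tol = 1e-6))
    expect_true(validate_feasible(m$Lambda))
    expect_true(validate_feasible(m$W))
  }
})

test_that("fit input validation catches dimension and finiteness errors", {
  X <- matrix(rnorm(10), 1, 10)
  Pi <- rand_onehot_pi(2, 10)
  expect_error(espa_markov(X, Pi, K = 11), "more clusters")
  expect_error(espa_markov(X[, 1, drop = FALSE], Pi[, 1, drop = FALSE],
                           K = 1), "T >= 2")
  Xb <- X; Xb[1] <- NA
  expect_error(espa_markov(Xb, Pi, K = 2), "non-finite")
  expect_error(espa_markov(X, Pi * 2, K = 2), "infeasible")
})

test_that("a well-separated variance switch is recovered with high training AUC", {
  sim <- sim_variance_switch(500, sigma_ratio = 4, D = 1, seed = 11)
  m <- espa_markov(sim$X, sim$Pi, K = 2, eps_L = 1, eps_E = 1e-2,
                   eps_CL = 1e-2, n_starts = 3, seed = 1)
  ph <- fitted(m)
  expect_gte(auc_score(ph[2, ], as.integer(sim$states == 2)), 0.95)
  # the two per-state SDs are recovered in some cluster order
  expect_equal(sort(m$sigma[1, ]), c(0.25, 1), tolerance = 0.15)
})

test_that("prediction returns column-stochastic label probabilities and is unique", {
  sim <- sim_variance_switch(400, sigma_ratio = 4, D = 1, seed = 13)
  m <- espa_markov(sim$X, sim$Pi, K = 2, eps_L = 1, eps_E = 1e-2,
                   eps_CL = 1e-2, n_starts = 2, seed = 1)
  new <- sim_variance_switch(200, sigma_ratio = 4, D = 1, seed = 14)
  p1 <- predict(m, new$X, seed = 5, tol = 1e-12, max_iter = 1e5)
  expect_equal(colSums(p1$Pi), rep(1, 200), tolerance = 1e-8)
  # distinct per-cluster likelihoods put b outside Im(H): unique solution,
  # so different random starts agree (both solved to tight tolerance)
  p2 <- predict(m, new$X, seed = 99, tol = 1e-12, max_iter = 1e5)
  expect_equal(p1$Pi, p2$Pi, tolerance = 1e-4)
  expect_error(predict(m, rbind(new$X, new$X)), "features")
})

test_that("identity classifier makes prediction pass affiliations through", {
  sim <- sim_nanopore_toy(n_bases = 10, seed = 41)
  m <- espa_oneshot(sim$X, sim$Pi, eps_L_grid = c(0.1, 1),
                    eps_E_grid = 1e-2)
  expect_equal(m$Lambda, diag(4), ignore_attr = TRUE)
  p <- predict(m, sim$X, seed = 2)
  expect_equal(p$Pi, p$Gamma)
})

test_that("one-shot learning builds the bijective model without iteration", {
  sim <- sim_variance_switch(300, sigma_ratio = 4, D = 1, seed = 15)
  m <- espa_oneshot(sim$X, sim$Pi, eps_L_grid = c(1e-2, 1),
                    eps_E_grid = c(1e-3, 1e-2))
  # the Kullback-Leibler classification term of the construction is zero
  l <- eval_loss(sim$X, sim$Pi, m$Gamma, m$mu, m$sigma, m$Lambda, m$W,
                 m$P, espa_hyper(1, 1e-2, 1e-2, 2))
  expect_identical(l$classification, 0)
  expect_identical(m$iterations, 0L)
  # one QP solve per grid combination
  expect_identical(m$n_qp_solves, 4L)
  expect_identical(nrow(m$selection), 4L)
  # K != M is rejected: the construction needs the cluster-label bijection
  Pi3 <- rbind(sim$Pi, 0)
  expect_error(espa_oneshot(sim$X, Pi3), "bijection")
})

test_that("grid search selects by validation AUC over contiguous splits", {
  sim <- sim_variance_switch(450, sigma_ratio = 4, D = 1, seed = 16)
  g1 <- espa_grid(eps_CL = 1e-2, eps_L = 1, eps_E = 1e-2, K = 2)
  gs <- espa_grid_search(sim$X, sim$Pi, grid = g1, seed = 1, n_starts = 2)
  expect_identical(nrow(gs$table), 1L)
  expect_identical(gs$best, 1L)
  expect_gte(gs$test_auc, 0.9)
  g2 <- espa_grid(eps_CL = 1e-2, eps_L = c(1e-2, 1), eps_E = 1e-2, K = 2)
  gs2 <- espa_grid_search(sim$X, sim$Pi, grid = g2, seed = 1, n_starts = 2)
  expect_identical(nrow(gs2$table), 2L)
  expect_false(any(is.na(gs2$table$val_auc)))
  # a split with one class only is rejected
  Pi_const <- matrix(c(1, 0), 2, 450)
  Pi_const[, 1:200] <- c(0, 1)
  expect_error(espa_grid_search(sim$X, Pi_const, grid = g1),
               "single class")
})
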