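# Shared fixtures and independent oracles for the test suite.

# strictly interior feasible affiliation (normalized positive uniforms);
# avoids zero-mass label/cluster pairings that legitimately produce Inf
rand_gamma <- function(K, Tn) {
  G <- matrix(stats::runif(K * Tn, 0.05, 1), K, Tn)
  sweep(G, 2L, colSums(G), "/")
}

rand_onehot_pi <- function(M, Tn) {
  s <- sample.int(M, Tn, replace = TRUE)
  s[seq_len(M)] <- seq_len(M)      # every label present
  Pi <- matrix(0, M, Tn)
  Pi[cbind(s, seq_len(Tn))] <- 1
  Pi
}

# a small random problem instance with all parameter blocks derived from a
# random interior affiliation
rand_instance <- function(D = 2, K = 2, Tn = 8, M = 2,
                          eps_L = 0.7, eps_E = 0.1, eps_CL = 0.3) {
  X <- matrix(stats::rnorm(D * Tn), D, Tn)
  Pi <- rand_onehot_pi(M, Tn)
  G <- rand_gamma(K, Tn)
  th <- update_mu_sigma(X, G)
  Lambda <- update_lambda(Pi, G)
  hp <- espa_hyper(eps_L, eps_E, eps_CL, K)
  W <- update_w(X, G, th$mu, th$sigma, eps_E, eps_L)
  list(X = X, Pi = Pi, G = G, mu = th$mu, sigma = th$sigma,
       Lambda = Lambda, W = W, P = diag(K), hp = hp,
       D = D, K = K, Tn = Tn, M = M)
}

# oracle: Markov penalty by direct double loop over the definition
brute_markov <- function(Gamma, P) {
  K <- nrow(Gamma); Tn <- ncol(Gamma)
  acc <- 0
  for (t in seq_len(Tn - 1)) {
    for (k1 in seq_len(K)) {
      acc <- acc + (Gamma[k1, t + 1] - sum(P[k1, ] * Gamma[, t]))^2
    }
  }
  acc / Tn
}

# oracle: general-purpose interior-point convex QP solver on the same
# problem min b'x + (1/T) x'Hx s.t. per-time simplex constraints.
# ipop needs a strictly definite Hessian, so it gets a small ridge; both
# solutions are always compared under the TRUE objective, which the ridge
# perturbs only at O(1e-6).
ipop_qp_objective <- function(H, b, K, Tn) {
  A <- kronecker(matrix(1, 1, K), diag(Tn))
  res <- kernlab::ipop(c = matrix(b), H = as.matrix(2 * H / Tn) +
                         1e-6 * diag(K * Tn),
                       A = A, b = rep(1, Tn), l = rep(0, K * Tn),
                       u = rep(2, K * Tn), r = rep(0, Tn), sigf = 7)
  x <- kernlab::primal(res)
  sum(b * x) + as.numeric(t(x) %*% H %*% x) / Tn
}

# oracle: slow per-column simplex projection (reference implementation,
# plain loop)
slow_project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - 1) / seq_along(u)))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

# oracle: numeric minimizer of f over the probability simplex via softmax
# reparametrization, multistart (wide inits reach near-vertex optima) with
# a Nelder-Mead polish after BFGS
simplex_numeric_min <- function(f, n, n_starts = 8) {
  obj <- function(z) {
    z <- z - max(z)
    w <- exp(z); w <- w / sum(w)
    f(w)
  }
  bestv <- Inf; bestx <- NULL
  starts <- c(list(rep(0, n)),
              lapply(seq_len(n_starts - 1),
                     function(s) stats::rnorm(n, sd = 1 + 2 * s)))
  for (z0 in starts) {
    o <- stats::optim(z0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    if (n > 1)
      o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    if (o$value < bestv) {
      z <- o$par - max(o$par)
      bestx <- exp(z) / sum(exp(z))
      bestv <- o$value
    }
  }
  list(x = bestx, value = bestv)
}
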