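# Model fitting: analytic subspace steps, the iterative coordinate-descent
# loop with multi-start, prediction on new data, direct one-shot learning,
# and hyperparameter grid search with chronological triple splitting.

#' Affiliation-weighted Gaussian parameters
#'
#' The exact minimizer of the likelihood term for fixed affiliations:
#' per cluster and dimension, the affiliation-weighted mean and the
#' affiliation-weighted (population-style) standard deviation,
#' \deqn{\mu^*_{d,k} = \frac{\sum_t \Gamma_{k,t} X_{d,t}}{\sum_t \Gamma_{k,t}},
#' \qquad
#' \sigma^*_{d,k} = \sqrt{\frac{\sum_t \Gamma_{k,t}(X_{d,t}-\mu^*_{d,k})^2}
#'   {\sum_t \Gamma_{k,t}}}.}
#' Standard deviations are floored at \code{SIGMA_FLOOR}. A cluster whose
#' total affiliation mass is below 1e-12 has no defined parameters; it is
#' reseeded at a randomly chosen data column with the per-dimension data
#' standard deviation, with a warning.
#'
#' @param X D x T data matrix.
#' @param Gamma K x T affiliation matrix.
#' @return list with \code{mu} and \code{sigma}, both D x K.
#' @export
update_mu_sigma <- function(X, Gamma) {
  D <- nrow(X); K <- nrow(Gamma); Tn <- ncol(X)
  mass <- rowSums(Gamma)
  empty <- mass < 1e-12
  safe_mass <- ifelse(empty, 1, mass)
  mu <- X %*% t(Gamma) / rep(safe_mass, each = D)
  sig2 <- (X^2 %*% t(Gamma)) / rep(safe_mass, each = D) - mu^2
  sigma <- sqrt(pmax(sig2, 0))
  if (any(empty)) {
    warning("reseeding ", sum(empty), " empty cluster(s)")
    sd_data <- apply(X, 1L, stats::sd)
    if (any(!is.finite(sd_data)) || Tn == 1L) sd_data <- rep(1, D)
    for (k in which(empty)) {
      mu[, k] <- X[, sample.int(Tn, 1L)]
      sigma[, k] <- sd_data
    }
  }
  sigma <- pmax(sigma, SIGMA_FLOOR)
  list(mu = mu, sigma = sigma)
}

#' Bayesian cluster-to-label classifier update
#'
#' The exact minimizer of the (Jensen-relaxed) classification term for
#' fixed affiliations: accumulate joint label-cluster mass
#' \eqn{\hat\Lambda_{m,k} = \sum_t \Pi_{m,t}\Gamma_{k,t}} and normalize
#' each column. A cluster with no mass gets the uniform label
#' distribution.
#'
#' @param Pi M x T label matrix.
#' @param Gamma K x T affiliation matrix.
#' @return M x K column-stochastic classifier.
#' @export
update_lambda <- function(Pi, Gamma) {
  A <- Pi %*% t(Gamma)
  cs <- colSums(A)
  zero <- cs <= 0
  if (any(zero)) {
    A[, zero] <- 1
    cs[zero] <- nrow(Pi)
  }
  sweep(A, 2L, cs, "/")
}

#' Entropic feature-weight update
#'
#' The exact minimizer of (likelihood + entropy) over the feature simplex:
#' a softmax over the per-dimension accumulated negative log-likelihoods,
#' \deqn{b_d = \sum_{t,k} \Gamma_{k,t}\,\ell(X_{d,t},\mu_{d,k},\sigma_{d,k}),
#' \qquad W^* = \mathrm{softmax}(-\varepsilon_L b / (T\,\varepsilon_E)),}
#' computed with max-subtraction for numerical stability. The likelihood
#' weight \code{eps_L} belongs in the temperature because it scales the
#' linear-in-W term of the objective; only with it is this the exact
#' conditional minimizer (verified against a numeric constrained
#' minimizer in the tests). Small \code{eps_E} concentrates the weights
#' on the most informative dimensions; large \code{eps_E} drives them to
#' uniform.
#'
#' @param X D x T data matrix.
#' @param Gamma K x T affiliation matrix.
#' @param mu,sigma D x K Gaussian parameters.
#' @param eps_E positive entropy weight.
#' @param eps_L nonnegative likelihood weight (default 1).
#' @return length-D feature-weight vector on the simplex.
#' @export
update_w <- function(X, Gamma, mu, sigma, eps_E, eps_L = 1) {
  stopifnot(eps_E > 0, eps_L >= 0)
  Tn <- ncol(X); K <- nrow(Gamma)
  b <- numeric(nrow(X))
  for (k in seq_len(K))
    b <- b + as.numeric(.nll_matrix(X, mu[, k], sigma[, k]) %*% Gamma[k, ])
  z <- -eps_L * b / (Tn * eps_E)
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

.random_feasible_gamma <- function(K, Tn) {
  project_simplex_columns(matrix(stats::runif(K * Tn), K, Tn))
}

.fit_control <- function(control = list()) {
  ctl <- list(tol = 1e-8, max_outer = 200L, qp_tol = NULL, qp_max_iter = NULL)
  ctl[names(control)] <- control
  ctl
}

#' Fit an eSPA-Markov model
#'
#' Minimizes the entropic classification objective (see
#' \code{\link{eval_loss}}) by coordinate descent over its four parameter
#' blocks. Each outer iteration solves, in order: the affiliation QP
#' (\code{\link{spgqp_solve}}, warm-started at the incumbent so the
#' objective cannot increase), then the closed-form Gaussian, classifier
#' and feature-weight steps, each an exact conditional minimizer. The
#' loop stops when the relative decrease of the total loss falls below
#' \code{control$tol} or after \code{control$max_outer} iterations.
#' The whole procedure is repeated from \code{n_starts} random feasible
#' affiliations (seeded deterministically from \code{seed} and the restart
#' index) and the restart with the lowest final total loss is returned.
#'
#' @param X D x T numeric data matrix; columns are time-ordered
#'   observations.
#' @param Pi M x T column-stochastic label-probability matrix (one-hot
#'   labels are the special case of 0/1 columns).
#' @param K number of clusters, or a full hyperparameter set from
#'   \code{\link{espa_hyper}} (then \code{eps_L}, \code{eps_E},
#'   \code{eps_CL} are ignored).
#' @param eps_L,eps_E,eps_CL scalar hyperparameters: likelihood weight,
#'   entropy weight (> 0), classification weight.
#' @param P K x K transition prior; default identity (persistence prior).
#' @param n_starts number of random restarts (default 10).
#' @param seed integer master seed for the restarts.
#' @param control list of loop controls: \code{tol} (relative loss
#'   decrease, default 1e-8), \code{max_outer} (default 200),
#'   \code{qp_tol}, \code{qp_max_iter} (passed to the QP solver).
#' @return object of class \code{"espa_markov"} with components
#'   \code{mu}, \code{sigma}, \code{Lambda}, \code{W}, \code{P},
#'   \code{hyper}, \code{Gamma} (training affiliations), \code{loss}
#'   (final \code{\link{eval_loss}} breakdown), \code{trace} (total loss
#'   per outer iteration of the winning restart), and fit metadata.
#' @seealso \code{\link{predict.espa_markov}}, \code{\link{espa_oneshot}},
#'   \code{\link{espa_grid_search}}
#' @export
espa_markov <- function(X, Pi, K, eps_L = 1, eps_E = 1e-2, eps_CL = 1e-3,
                        P = NULL, n_starts = 10L, seed = 1L,
                        control = list()) {
  X <- as.matrix(X); Pi <- as.matrix(Pi)
  hyper <- if (inherits(K, "espa_hyper")) K else espa_hyper(eps_L, eps_E, eps_CL, K)
  K <- hyper$K
  D <- nrow(X); Tn <- ncol(X); M <- nrow(Pi)
  if (ncol(Pi) != Tn) stop("X and Pi must have the same number of columns")
  if (Tn < 2) stop("need T >= 2 time points for the Markov regularizer")
  if (K > Tn) stop("more clusters (K = ", K, ") than time points (T = ", Tn, ")")
  if (any(!is.finite(X)) || any(!is.finite(Pi))) stop("non-finite input")
  .stop_infeasible(Pi, "label matrix Pi")
  if (is.null(P)) P <- diag(K)
  ctl <- .fit_control(control)
  H <- build_H(P, K, Tn)
  qp_tol <- if (is.null(ctl$qp_tol)) 1e-8 * K * Tn else ctl$qp_tol
  qp_max <- if (is.null(ctl$qp_max_iter)) max(2000L, 10L * K * Tn) else ctl$qp_max_iter

  best <- NULL
  for (r in seq_len(n_starts)) {
    set.seed((seed + 7919L * r) %% 2147483647L)
    Gamma <- .random_feasible_gamma(K, Tn)
    th <- update_mu_sigma(X, Gamma)
    Lambda <- update_lambda(Pi, Gamma)
    W <- update_w(X, Gamma, th$mu, th$sigma, hyper$eps_E, hyper$eps_L)
    loss <- eval_loss(X, Pi, Gamma, th$mu, th$sigma, Lambda, W, P, hyper,
                      check = FALSE)
    loss0 <- loss$total
    trace <- loss$total
    converged <- FALSE
    it <- 0L
    while (it < ctl$max_outer) {
      it <- it + 1L
      b <- build_linear_term(X, Pi, th$mu, th$sigma, Lambda, W, hyper)
      if (any(is.infinite(b))) {
        # a zero classifier entry can make some assignments infinitely bad;
        # forbid them by clamping, the Lambda step will repair the zeros
        b[is.infinite(b)] <- .Machine$double.xmax / (K * Tn)
      }
      sol <- spgqp_solve(H, b, K, Tn, Gamma0 = Gamma,
                         tol = qp_tol, max_iter = qp_max)
      Gamma <- sol$Gamma
      th <- update_mu_sigma(X, Gamma)
      Lambda <- update_lambda(Pi, Gamma)
      W <- update_w(X, Gamma, th$mu, th$sigma, hyper$eps_E, hyper$eps_L)
      loss <- eval_loss(X, Pi, Gamma, th$mu, th$sigma, Lambda, W, P, hyper,
                        check = FALSE)
      trace <- c(trace, loss$total)
      prev <- trace[length(trace) - 1L]
      if (is.finite(prev) && prev - loss$total <= ctl$tol * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || loss$total < best$loss$total) {
      best <- list(mu = th$mu, sigma = th$sigma, Lambda = Lambda, W = W,
                   Gamma = Gamma, loss = loss, trace = trace,
                   initial_loss = loss0, iterations = it,
                   converged = converged, restart = r)
    }
  }

  structure(c(best,
              list(P = P, hyper = hyper, D = D, K = K, M = M, T = Tn,
                   n_starts = n_starts, seed = seed, method = "iterative")),
            class = "espa_markov")
}

#' Predict label probabilities for new time-ordered data
#'
#' Solves the affiliation QP on the new data with the classification
#' weight set to zero (no labels are available at prediction time), using
#' the fitted Gaussian parameters, feature weights and transition prior,
#' from a seeded random feasible start. Label probabilities are then the
#' classifier applied to the affiliations, \eqn{\tilde\Pi = \Lambda\Gamma}.
#'
#' @param object fitted \code{"espa_markov"} model.
#' @param newdata D x T_test data matrix (same feature count as training).
#' @param seed seed for the random feasible start.
#' @param tol,max_iter optional QP solver overrides.
#' @param ... unused.
#' @return list of class \code{"espa_prediction"}: \code{Pi} (M x T_test
#'   column-stochastic label probabilities), \code{Gamma} (K x T_test
#'   affiliations), \code{report} (QP solver report).
#' @export
predict.espa_markov <- function(object, newdata, seed = 1L,
                                tol = NULL, max_iter = NULL, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) != object$D)
    stop("newdata has ", nrow(X), " features, model expects ", object$D)
  Tn <- ncol(X)
  if (Tn < 2) stop("need T >= 2 time points for prediction")
  K <- object$K
  hp <- object$hyper
  hp_pred <- espa_hyper(hp$eps_L, hp$eps_E, 0, K)
  b <- build_linear_term(X, NULL, object$mu, object$sigma, NULL,
                         object$W, hp_pred)
  H <- build_H(object$P, K, Tn)
  set.seed(seed %% 2147483647L)
  Gamma0 <- .random_feasible_gamma(K, Tn)
  if (is.null(tol)) tol <- 1e-8 * K * Tn
  if (is.null(max_iter)) max_iter <- max(2000L, 10L * K * Tn)
  sol <- spgqp_solve(H, b, K, Tn, Gamma0 = Gamma0,
                     tol = tol, max_iter = max_iter)
  Pi_hat <- object$Lambda %*% sol$Gamma
  structure(list(Pi = Pi_hat, Gamma = sol$Gamma, report = sol$report),
            class = "espa_prediction")
}

#' Direct one-shot learning
#'
#' When every cluster corresponds to exactly one label and vice versa
#' (K = M and all labels present), the full model is learnable without any
#' iterative loop: the training affiliations equal the label matrix, the
#' classifier is the identity (its Kullback-Leibler term is exactly zero),
#' and the Gaussian parameters follow in closed form. The entropy and
#' likelihood weights are then chosen over a grid: for each \code{eps_E}
#' the closed-form feature weights are computed, each (\code{eps_E},
#' \code{eps_L}) pair defines one affiliation QP on the training data
#' (solved once, with zero classification weight), and the pair whose
#' solution is closest to the labels in squared Frobenius distance is
#' selected. Ties go to the earliest pair in grid order.
#'
#' @param X D x T training data matrix.
#' @param Pi M x T one-hot (or column-stochastic) label matrix; K = M is
#'   required and every label must carry mass.
#' @param eps_L_grid,eps_E_grid candidate hyperparameter values.
#' @param P K x K transition prior; default identity.
#' @return an \code{"espa_markov"} model (with \code{method = "oneshot"},
#'   \code{eps_CL = 0} stored) whose extra fields record the selection:
#'   \code{selection} is a data.frame of (eps_E, eps_L, frobenius2),
#'   \code{n_qp_solves} the number of affiliation QPs solved.
#' @export
espa_oneshot <- function(X, Pi,
                         eps_L_grid = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1, 2, 5, 10),
                         eps_E_grid = c(1e-4, 1e-3, 1e-2, 1e-1),
                         P = NULL) {
  X <- as.matrix(X); Pi <- as.matrix(Pi)
  M <- nrow(Pi); Tn <- ncol(Pi); K <- M
  if (ncol(X) != Tn) stop("X and Pi must have the same number of columns")
  .stop_infeasible(Pi, "label matrix Pi")
  if (any(rowSums(Pi) <= 0))
    stop("one-shot learning requires a bijection between clusters and ",
         "labels: every label must occur in the training data (K = M)")
  if (is.null(P)) P <- diag(K)
  Gamma <- Pi
  th <- update_mu_sigma(X, Gamma)
  Lambda <- diag(K)
  H <- build_H(P, K, Tn)

  sel <- expand.grid(eps_L = eps_L_grid, eps_E = eps_E_grid,
                     KEEP.OUT.ATTRS = FALSE)
  sel <- sel[order(match(sel$eps_E, eps_E_grid),
                   match(sel$eps_L, eps_L_grid)), c("eps_E", "eps_L")]
  rownames(sel) <- NULL
  sel$frobenius2 <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(sel))) {
    eE <- sel$eps_E[i]; eL <- sel$eps_L[i]
    # the closed-form weights depend on the eps_L / eps_E temperature ratio,
    # so they are recomputed per grid pair (cost is negligible next to the QP)
    W <- update_w(X, Gamma, th$mu, th$sigma, eE, eL)
    hp <- espa_hyper(eL, eE, 0, K)
    b <- build_linear_term(X, NULL, th$mu, th$sigma, NULL, W, hp)
    sol <- spgqp_solve(H, b, K, Tn)
    err <- sum((Pi - sol$Gamma)^2)
    sel$frobenius2[i] <- err
    if (is.null(best) || err < best$err)
      best <- list(err = err, eps_E = eE, eps_L = eL, W = W)
  }

  hyper <- espa_hyper(best$eps_L, best$eps_E, 0, K)
  loss <- eval_loss(X, Pi, Gamma, th$mu, th$sigma, Lambda, best$W, P, hyper,
                    check = FALSE)
  structure(list(mu = th$mu, sigma = th$sigma, Lambda = Lambda, W = best$W,
                 Gamma = Gamma, loss = loss, trace = loss$total,
                 initial_loss = loss$total, iterations = 0L,
                 converged = TRUE, restart = 1L,
                 P = P, hyper = hyper, D = nrow(X), K = K, M = M, T = Tn,
                 n_starts = 1L, seed = NA_integer_, method = "oneshot",
                 selection = sel, n_qp_solves = nrow(sel)),
            class = "espa_markov")
}

#' Default hyperparameter grid
#'
#' The standard search grid for the iterative fit: classification weight
#' in \{1e-4, 1e-3, 1e-2\}, likelihood weight in \{1e-5, ..., 1e-1, 1, 2,
#' 5, 10\}, entropy weight in \{1e-4, ..., 1e-1\}, and cluster count in
#' \{2, 3, 5\}. Any axis can be overridden to search a reduced subgrid.
#'
#' @param eps_CL,eps_L,eps_E,K candidate values for each axis.
#' @return data.frame with one row per hyperparameter combination.
#' @export
espa_grid <- function(eps_CL = c(1e-4, 1e-3, 1e-2),
                      eps_L = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1, 2, 5, 10),
                      eps_E = c(1e-4, 1e-3, 1e-2, 1e-1),
                      K = c(2, 3, 5)) {
  g <- expand.grid(eps_CL = eps_CL, eps_L = eps_L, eps_E = eps_E, K = K,
                   KEEP.OUT.ATTRS = FALSE)
  stopifnot(nrow(g) >= 1)
  g
}

#' Hyperparameter grid search with chronological triple splitting
#'
#' Fits one model per grid row on the training block, scores each by AUC
#' on the validation block, selects the best, and reports that single
#' model's AUC on the held-out test block (no refitting). Splits must be
#' contiguous time blocks so the Markov structure is preserved. Binary
#' labels (M = 2) are required for the AUC; the score of the positive
#' class is its row of the predicted label-probability matrix.
#'
#' @param X D x T data matrix.
#' @param Pi 2 x T label matrix.
#' @param grid data.frame from \code{\link{espa_grid}} (or a subset).
#' @param split list with integer index vectors \code{train},
#'   \code{validation}, \code{test}; default \code{\link{triple_split}}.
#' @param seed master seed (restart seeds and prediction starts derive
#'   from it).
#' @param n_starts random restarts per fit.
#' @param P transition prior passed to each fit (identity by default).
#' @param control fit control list passed to \code{\link{espa_markov}}.
#' @return list of class \code{"espa_gridsearch"}: \code{model} (the
#'   selected fit), \code{table} (grid plus validation AUC), \code{best}
#'   (selected row index), \code{val_auc}, \code{test_auc}.
#' @export
espa_grid_search <- function(X, Pi, grid = espa_grid(),
                             split = triple_split(ncol(X)),
                             seed = 1L, n_starts = 10L, P = NULL,
                             control = list()) {
  X <- as.matrix(X); Pi <- as.matrix(Pi)
  if (nrow(Pi) != 2) stop("grid search scores by AUC and needs binary labels")
  lab <- function(idx) as.integer(Pi[2, idx] > 0.5)
  for (s in c("train", "validation", "test")) {
    if (length(unique(lab(split[[s]]))) < 2)
      stop("the ", s, " split contains a single class; AUC is undefined")
  }
  Xtr <- X[, split$train, drop = FALSE]
  Ptr <- Pi[, split$train, drop = FALSE]
  tab <- grid
  tab$val_auc <- NA_real_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    Pk <- if (is.null(P)) diag(grid$K[i]) else P
    fits[[i]] <- espa_markov(Xtr, Ptr, K = grid$K[i],
                             eps_L = grid$eps_L[i], eps_E = grid$eps_E[i],
                             eps_CL = grid$eps_CL[i], P = Pk,
                             n_starts = n_starts, seed = seed,
                             control = control)
    pv <- predict(fits[[i]], X[, split$validation, drop = FALSE],
                  seed = seed + i)
    tab$val_auc[i] <- auc_score(pv$Pi[2, ], lab(split$validation))
  }
  best <- which.max(tab$val_auc)
  pt <- predict(fits[[best]], X[, split$test, drop = FALSE],
                seed = seed + nrow(grid) + 1L)
  test_auc <- auc_score(pt$Pi[2, ], lab(split$test))
  structure(list(model = fits[[best]], table = tab, best = best,
                 val_auc = tab$val_auc[best], test_auc = test_auc),
            class = "espa_gridsearch")
}

#' @export
print.espa_gridsearch <- function(x, ...) {
  cat("eSPA-Markov grid search over", nrow(x$table), "hyperparameter",
      "combinations\n")
  cat(sprintf("selected row %d: K = %d, eps_L = %g, eps_E = %g, eps_CL = %g\n",
              x$best, x$model$hyper$K, x$model$hyper$eps_L,
              x$model$hyper$eps_E, x$model$hyper$eps_CL))
  cat(sprintf("validation AUC = %.4f, test AUC = %.4f\n",
              x$val_auc, x$test_auc))
  invisible(x)
}
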