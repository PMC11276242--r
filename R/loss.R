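# Exact evaluation of the eSPA-Markov objective and its four terms.
#
# Conventions used throughout the package:
#   X      D x T data matrix, columns are time-ordered observations
#   Pi     M x T column-stochastic label-probability matrix
#   Gamma  K x T column-stochastic fuzzy affiliation matrix
#   mu     D x K per-cluster, per-dimension Gaussian means
#   sigma  D x K per-cluster, per-dimension Gaussian standard deviations
#   Lambda M x K column-stochastic cluster-to-label classifier
#   W      length-D feature-weight probability vector
#   P      K x K transition prior (identity = persistence prior)
# The loss is reported in nats.

#' Smallest admissible Gaussian standard deviation
#'
#' The per-cluster negative log-likelihood diverges as a cluster's standard
#' deviation tends to zero (a cluster collapsing onto identical points).
#' All sigma estimates are floored at this value, in data units.
#' @keywords internal
SIGMA_FLOOR <- 1e-6

#' Univariate Gaussian negative log-likelihood
#'
#' Evaluates \eqn{\ell(x, \mu, \sigma) = \frac{1}{2}\log(2\pi\sigma^2) +
#' \frac{(x-\mu)^2}{2\sigma^2}}, the negative log-density of
#' \eqn{N(\mu, \sigma^2)} at \code{x}, in nats. Vectorized over all
#' arguments with the usual recycling rules.
#'
#' @param x numeric; observation(s).
#' @param mu numeric; mean(s).
#' @param sigma positive numeric; standard deviation(s).
#' @return numeric vector of negative log-likelihood values.
#' @examples
#' gaussian_nll(0, 0, 1)  # 0.5 * log(2 * pi)
#' @export
gaussian_nll <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("gaussian_nll: sigma must be > 0")
  0.5 * log(2 * pi * sigma^2) + (x - mu)^2 / (2 * sigma^2)
}

# D x T matrix of weighted nll's for one cluster k: entries l(X_dt, mu_dk, s_dk)
.nll_matrix <- function(X, mu_k, sigma_k) {
  0.5 * log(2 * pi * sigma_k^2) + (X - mu_k)^2 / (2 * sigma_k^2)
}

#' Markov smoothness penalty of an affiliation path
#'
#' The time-coupling term of the eSPA-Markov objective:
#' \deqn{\frac{1}{T}\sum_{t=1}^{T-1}\sum_{k_1}\Big(\Gamma_{k_1,t+1} -
#'   \sum_{k_2} P_{k_1,k_2}\Gamma_{k_2,t}\Big)^2.}
#' With \code{P} the identity this is the squared-difference (H1-seminorm
#' style) penalty on the affiliation path, which rewards persistent
#' (metastable) regime assignments.
#'
#' @param Gamma K x T affiliation matrix.
#' @param P K x K transition prior.
#' @return nonnegative scalar.
#' @export
markov_penalty <- function(Gamma, P) {
  K <- nrow(Gamma); Tn <- ncol(Gamma)
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stop("markov_penalty: P must be ", K, " x ", K)
  if (Tn < 2) return(0)
  R <- Gamma[, 2:Tn, drop = FALSE] - P %*% Gamma[, 1:(Tn - 1), drop = FALSE]
  sum(R^2) / Tn
}

#' Check feasibility of a stochastic-matrix parameter
#'
#' Verifies the box and normalization constraints shared by the affiliation
#' matrix (columns on the K-simplex), the classifier (columns on the
#' M-simplex) and the feature weights (a single point on the D-simplex):
#' entries in [0, 1] and unit column sums, within tolerance.
#'
#' @param x matrix with column-stochastic constraint, or a probability vector.
#' @param tol numeric tolerance (default 1e-8).
#' @return \code{TRUE} if feasible, otherwise \code{FALSE} with a
#'   \code{"why"} attribute naming the violated constraint.
#' @export
validate_feasible <- function(x, tol = 1e-8) {
  v <- as.matrix(x)
  if (is.vector(x)) v <- matrix(x, ncol = 1)
  if (any(!is.finite(v)))
    return(structure(FALSE, why = "non-finite entries"))
  if (any(v < -tol) || any(v > 1 + tol))
    return(structure(FALSE, why = "entries outside [0, 1]"))
  cs <- colSums(v)
  if (any(abs(cs - 1) > max(tol, 1e-8 * nrow(v))))
    return(structure(FALSE, why = "column sums differ from 1"))
  TRUE
}

.stop_infeasible <- function(x, what, tol = 1e-8) {
  ok <- validate_feasible(x, tol)
  if (!isTRUE(ok))
    stop("infeasible ", what, ": ", attr(ok, "why"), call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the eSPA-Markov objective
#'
#' Computes the Jensen-relaxed objective
#' \deqn{\frac{\varepsilon_L}{T}\sum_{d,k,t} W_d \Gamma_{k,t}
#'   \ell(X_{d,t},\mu_{d,k},\sigma_{d,k})
#'   + \varepsilon_E \sum_d W_d \log W_d
#'   - \frac{\varepsilon_{CL}}{T}\sum_{m,t}\Pi_{m,t}\sum_k
#'     \log(\Lambda_{m,k})\,\Gamma_{k,t}
#'   + \frac{1}{T}\sum_{t<T}\sum_{k_1}\big(\Gamma_{k_1,t+1} -
#'     {\textstyle\sum_{k_2}}P_{k_1,k_2}\Gamma_{k_2,t}\big)^2}
#' and returns the four addends plus their total, in nats. The
#' classification term is the Jensen relaxation of the Kullback-Leibler
#' discrepancy between \eqn{\Pi} and \eqn{\Lambda\Gamma}; it admits
#' closed-form classifier and feature-weight updates.
#'
#' Conventions: \eqn{0 \log 0 = 0}; a zero classifier entry carrying
#' positive weight \eqn{\Pi_{m,t}\Gamma_{k,t}} yields \code{+Inf}, never an
#' error.
#'
#' @param X D x T data matrix.
#' @param Pi M x T label-probability matrix (ignored when
#'   \code{hyper$eps_CL == 0}; may be \code{NULL} then).
#' @param Gamma K x T affiliation matrix.
#' @param mu,sigma D x K Gaussian parameters.
#' @param Lambda M x K classifier (ignored when \code{hyper$eps_CL == 0}).
#' @param W length-D feature weights.
#' @param P K x K transition prior.
#' @param hyper list with elements \code{eps_L}, \code{eps_E},
#'   \code{eps_CL}, \code{K} (see \code{\link{espa_hyper}}).
#' @param check validate feasibility of \code{Gamma}, \code{Lambda},
#'   \code{W} first (default \code{TRUE}).
#' @return list of class \code{"espa_loss"}: \code{likelihood},
#'   \code{entropy}, \code{classification}, \code{markov}, \code{total}.
#' @export
eval_loss <- function(X, Pi, Gamma, mu, sigma, Lambda, W, P, hyper,
                      check = TRUE) {
  Tn <- ncol(X); D <- nrow(X); K <- nrow(Gamma)
  if (ncol(Gamma) != Tn) stop("Gamma and X disagree in T")
  if (check) {
    .stop_infeasible(Gamma, "affiliation Gamma (constraints on [0,1] entries and unit column sums)")
    .stop_infeasible(W, "feature weights W")
    if (hyper$eps_CL > 0) .stop_infeasible(Lambda, "classifier Lambda")
  }

  lik <- 0
  if (hyper$eps_L != 0) {
    for (k in seq_len(K)) {
      nll <- .nll_matrix(X, mu[, k], sigma[, k])      # D x T
      lik <- lik + sum((W %*% nll) * Gamma[k, ])
    }
    lik <- hyper$eps_L / Tn * lik
  }

  ent <- hyper$eps_E * sum(ifelse(W > 0, W * log(W), 0))

  cls <- 0
  if (hyper$eps_CL > 0) {
    A <- Pi %*% t(Gamma)                              # M x K weights on log Lambda
    pos <- A > 0
    if (any(pos & Lambda == 0)) {
      cls <- Inf
    } else {
      cls <- -hyper$eps_CL / Tn * sum(A[pos] * log(Lambda[pos]))
    }
  }

  mar <- markov_penalty(Gamma, P)

  structure(list(likelihood = lik, entropy = ent, classification = cls,
                 markov = mar, total = lik + ent + cls + mar),
            class = "espa_loss")
}

#' @export
print.espa_loss <- function(x, ...) {
  cat("eSPA-Markov loss (nats):\n")
  cat(sprintf("  likelihood     %12.6g\n", x$likelihood))
  cat(sprintf("  entropy        %12.6g\n", x$entropy))
  cat(sprintf("  classification %12.6g\n", x$classification))
  cat(sprintf("  markov         %12.6g\n", x$markov))
  cat(sprintf("  total          %12.6g\n", x$total))
  invisible(x)
}

#' Hyperparameter set for an eSPA-Markov fit
#'
#' @param eps_L nonnegative weight of the Gaussian likelihood term.
#' @param eps_E positive weight of the feature-entropy regularizer (the
#'   softmax temperature of the feature-weight step is \code{T * eps_E}).
#' @param eps_CL nonnegative weight of the classification term; 0 switches
#'   to prediction mode, where labels and classifier are not used.
#' @param K positive integer number of clusters.
#' @return named list of class \code{"espa_hyper"}.
#' @export
espa_hyper <- function(eps_L, eps_E, eps_CL, K) {
  stopifnot(eps_L >= 0, eps_E > 0, eps_CL >= 0,
            K == as.integer(K), K >= 1)
  structure(list(eps_L = eps_L, eps_E = eps_E, eps_CL = eps_CL,
                 K = as.integer(K)),
            class = "espa_hyper")
}
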