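# The affiliation (Gamma) step: a convex quadratic program over a product of
# per-time-point probability simplices, solved by a spectral projected
# gradient method (SPG-QP).
#
# Vectorization is cluster-major: gamma = as.vector(t(Gamma)), i.e. each
# cluster's T time points are contiguous, matching the I_K (x) . Kronecker
# blocks of the Hessian.

#' Build the Markov-penalty Hessian
#'
#' Constructs the sparse symmetric KT x KT matrix \code{H} such that the
#' Markov smoothness penalty equals \eqn{\frac{1}{T}\gamma^\top H\gamma}
#' for \eqn{\gamma} the cluster-major vectorization of \eqn{\Gamma}:
#' \deqn{H = I_K \otimes \mathrm{diag}(0,1,\dots,1)
#'         + P^\top P \otimes \mathrm{diag}(1,\dots,1,0)
#'         + P \otimes OD^\top + P^\top \otimes OD,}
#' with \eqn{OD} the T x T matrix with \eqn{-1} on the superdiagonal.
#' With \code{P} the identity, \code{H} is block diagonal with K copies of
#' the T x T path-graph Laplacian; constant-in-time affiliations span its
#' null space, so persistent paths are penalty-free.
#'
#' @param P K x K transition prior.
#' @param K number of clusters.
#' @param Tn number of time points (>= 2).
#' @return sparse symmetric \code{\link[Matrix]{Matrix}} of size KT x KT.
#' @export
build_H <- function(P, K, Tn) {
  if (Tn < 2) stop("build_H: T must be >= 2 (no transitions to regularize)")
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stop("build_H: P must be ", K, " x ", K)
  d_late  <- Matrix::Diagonal(Tn, x = c(0, rep(1, Tn - 1)))
  d_early <- Matrix::Diagonal(Tn, x = c(rep(1, Tn - 1), 0))
  OD <- Matrix::bandSparse(Tn, Tn, k = 1, diagonals = list(rep(-1, Tn - 1)))
  H <- Matrix::kronecker(Matrix::Diagonal(K), d_late) +
    Matrix::kronecker(crossprod(P), d_early) +
    Matrix::kronecker(P, Matrix::t(OD)) +
    Matrix::kronecker(t(P), OD)
  methods::as(Matrix::forceSymmetric(H), "generalMatrix")
}

#' Build the linear term of the affiliation QP
#'
#' Returns the length-KT vector \code{b} (cluster-major) with
#' \deqn{b_{k,t} = \frac{\varepsilon_L}{T}\sum_d W_d\,
#'   \ell(X_{d,t},\mu_{d,k},\sigma_{d,k})
#'   - \frac{\varepsilon_{CL}}{T}\sum_m \Pi_{m,t}\log\Lambda_{m,k},}
#' so that \eqn{b^\top\gamma + \frac{1}{T}\gamma^\top H\gamma} reproduces
#' the likelihood, classification and Markov terms of the full objective
#' (the entropy term does not involve \eqn{\Gamma}). With
#' \code{hyper$eps_CL == 0} (prediction mode) the labels and classifier are
#' not consulted and may be \code{NULL}.
#'
#' A zero classifier entry weighted by a positive \eqn{\Pi} mass produces
#' \code{+Inf} entries in \code{b}; these are flagged with an attribute
#' rather than an error so callers can decide.
#'
#' @param X D x T data matrix.
#' @param Pi M x T label matrix or \code{NULL}.
#' @param mu,sigma D x K Gaussian parameters.
#' @param Lambda M x K classifier or \code{NULL}.
#' @param W length-D feature weights.
#' @param hyper hyperparameter list (\code{\link{espa_hyper}}).
#' @return numeric vector of length K*T, cluster-major.
#' @export
build_linear_term <- function(X, Pi, mu, sigma, Lambda, W, hyper) {
  Tn <- ncol(X); K <- ncol(mu)
  if (hyper$eps_CL > 0 && (is.null(Pi) || is.null(Lambda)))
    stop("build_linear_term: Pi and Lambda required when eps_CL > 0")
  B <- matrix(0, K, Tn)
  if (hyper$eps_L != 0) {
    for (k in seq_len(K))
      B[k, ] <- hyper$eps_L / Tn * as.numeric(W %*% .nll_matrix(X, mu[, k], sigma[, k]))
  }
  if (hyper$eps_CL > 0) {
    logL <- suppressWarnings(log(Lambda))      # M x K, may contain -Inf
    CT <- t(logL) %*% Pi                       # K x T; NaN where 0 * -Inf
    CT[is.nan(CT)] <- 0
    B <- B - hyper$eps_CL / Tn * CT
  }
  b <- as.vector(t(B))
  if (any(is.infinite(b))) attr(b, "has_inf") <- TRUE
  b
}

#' Euclidean projection of matrix columns onto the probability simplex
#'
#' Each column of \code{V} is replaced by its closest point (in Euclidean
#' distance) on the standard simplex, via the sort-and-threshold algorithm.
#' Fully vectorized over columns.
#'
#' @param V K x T numeric matrix.
#' @return K x T matrix with entries in [0, 1] and unit column sums.
#' @export
project_simplex_columns <- function(V) {
  if (!is.matrix(V)) V <- as.matrix(V)
  K <- nrow(V); Tn <- ncol(V)
  if (K == 1L) return(matrix(1, 1L, Tn))
  o <- order(col(V), -V)                       # within-column descending sort
  U <- matrix(V[o], K, Tn)
  CS <- apply(U, 2L, cumsum)                   # K x Tn (K small)
  thr <- (CS - 1) / seq_len(K)
  rho <- colSums(U > thr)                      # >= 1 always
  tau <- thr[cbind(rho, seq_len(Tn))]
  pmax(V - rep(tau, each = K), 0)
}

#' Solve the affiliation QP with a spectral projected gradient method
#'
#' Minimizes \eqn{f(\gamma) = b^\top\gamma + \frac{1}{T}\gamma^\top H\gamma}
#' over the product of per-time-point probability simplices. The method
#' takes Barzilai-Borwein spectral steps (safeguarded to
#' \eqn{[10^{-10}, 10^{10}]}), projects onto the feasible set, and applies
#' a nonmonotone line search with memory 10. Every iterate is feasible;
#' the best iterate seen is returned, so the result never has a larger
#' objective than the starting point.
#'
#' @param H sparse KT x KT Hessian from \code{\link{build_H}}.
#' @param b length-KT linear term from \code{\link{build_linear_term}}.
#' @param K,Tn problem dimensions.
#' @param Gamma0 feasible K x T starting affiliation (default: uniform).
#' @param tol stop when the projected-gradient infinity norm drops below
#'   this (default \code{1e-8 * K * Tn}).
#' @param max_iter iteration cap (default \code{max(2000, 10 * K * Tn)}; the floor keeps small problems fully converged, the linear term preserves the large-problem scaling).
#' @return list: \code{Gamma} (K x T solution), \code{objective} (at the
#'   solution), \code{report} (iterations, final projected-gradient norm,
#'   converged flag, objective trace).
#' @export
spgqp_solve <- function(H, b, K, Tn, Gamma0 = NULL,
                        tol = 1e-8 * K * Tn, max_iter = max(2000, 10 * K * Tn)) {
  if (any(!is.finite(b))) stop("spgqp_solve: non-finite linear term")
  if (any(!is.finite(H@x))) stop("spgqp_solve: non-finite Hessian")
  if (is.null(Gamma0)) Gamma0 <- matrix(1 / K, K, Tn)
  .stop_infeasible(Gamma0, "starting affiliation Gamma0")
  if (K == 1L) {
    g <- matrix(1, 1L, Tn)
    return(list(Gamma = g, objective = sum(b),
                report = list(iterations = 0L, pg_norm = 0, converged = TRUE,
                              trace = sum(b))))
  }

  fobj <- function(x, Hx) sum(b * x) + sum(x * Hx) / Tn
  x <- as.vector(t(Gamma0))
  Hx <- as.numeric(H %*% x)
  f <- fobj(x, Hx)
  g <- b + 2 / Tn * Hx

  memory <- 10L
  fhist <- rep(-Inf, memory); fhist[1L] <- f
  alpha <- 1
  best_x <- x; best_f <- f
  trace <- numeric(0)
  pg <- Inf
  it <- 0L
  delta <- 1e-4

  repeat {
    # projected gradient (unit step) for the stopping test
    pgvec <- as.vector(t(project_simplex_columns(t(matrix(x - g, Tn, K))))) - x
    pg <- max(abs(pgvec))
    trace <- c(trace, f)
    if (pg <= tol || it >= max_iter) break
    it <- it + 1L

    # spectral step, projection, nonmonotone Armijo backtracking
    xt <- as.vector(t(project_simplex_columns(t(matrix(x - alpha * g, Tn, K)))))
    d <- xt - x
    gd <- sum(g * d)
    if (gd >= -1e-15) {
      # not a descent direction numerically; a huge spectral step can cause
      # this spuriously, so retry once with a unit step before stopping
      if (alpha == 1) break
      alpha <- 1
      next
    }
    fmax <- max(fhist)
    lam <- 1
    repeat {
      xn <- x + lam * d
      Hxn <- as.numeric(H %*% xn)
      fn <- fobj(xn, Hxn)
      if (fn <= fmax + delta * lam * gd || lam < 1e-12) break
      lam <- lam / 2
    }
    s <- xn - x
    gn <- b + 2 / Tn * Hxn
    y <- gn - g
    sy <- sum(s * y)
    alpha <- if (sy > 0) min(max(sum(s * s) / sy, 1e-10), 1e10) else 1e10
    x <- xn; g <- gn; f <- fn
    fhist[(it %% memory) + 1L] <- f
    if (f < best_f) { best_f <- f; best_x <- x }
  }

  Gamma <- t(matrix(best_x, Tn, K))
  # clean tiny negative round-off and renormalize exactly
  Gamma[Gamma < 0] <- 0
  Gamma <- sweep(Gamma, 2L, colSums(Gamma), "/")
  list(Gamma = Gamma, objective = best_f,
       report = list(iterations = it, pg_norm = pg,
                     converged = pg <= tol, trace = trace))
}

#' Export a sparse Hessian in coordinate text format
#'
#' Writes one \code{row col value} triplet per line (1-based indices) for
#' debugging and external inspection.
#'
#' @param H sparse matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_H_coords <- function(H, path) {
  Htr <- methods::as(methods::as(H, "generalMatrix"), "TsparseMatrix")
  df <- data.frame(row = Htr@i + 1L, col = Htr@j + 1L, value = Htr@x)
  df <- df[order(df$row, df$col), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
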