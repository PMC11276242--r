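# Synthetic benchmark generators: a persistent two-state Markov chain with
# state-dependent emissions (variance switching and rotated bivariate
# regimes), a nanopore-inspired current-trace toy with k-mer dwell times,
# Takens delay embedding, and evaluation utilities.

#' Simulate a persistent two-state path
#'
#' Two modes. \code{"chain"} simulates a two-state Markov chain with
#' transition matrix \eqn{[[1-\epsilon, \epsilon], [\epsilon, 1-\epsilon]]}
#' (small \code{eps_trans} enforces persistence / metastability).
#' \code{"block"} instead alternates the two states in blocks with
#' stochastically determined lengths, drawn uniformly from
#' \eqn{[0.8c, 1.2c]} with \eqn{c = T/18}, which guarantees that both
#' states are visited in every third of the sequence — the property needed
#' so that chronological train/validation/test splits each contain both
#' classes.
#'
#' @param Tn sequence length.
#' @param eps_trans transition probability of the chain mode
#'   (default 0.01); must lie in (0, 0.5).
#' @param mode \code{"chain"} or \code{"block"}.
#' @param seed optional integer seed.
#' @return integer vector of length \code{Tn} with values in \{1, 2\}.
#' @export
sim_two_state_path <- function(Tn, eps_trans = 0.01,
                               mode = c("block", "chain"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(eps_trans > 0, eps_trans < 0.5, Tn >= 2)
  if (!is.null(seed)) set.seed(seed %% 2147483647L)
  if (mode == "chain") {
    flips <- stats::rbinom(Tn - 1L, 1L, eps_trans)
    s <- cumsum(c(sample(0:1, 1L), flips)) %% 2L
    return(as.integer(s) + 1L)
  }
  # block mode: alternating states, dwell ~ U[0.8c, 1.2c], c = T/18
  if (Tn < 36) stop("block mode needs T >= 36 to guarantee both states ",
                    "in every third of the sequence")
  cc <- Tn / 18
  s <- integer(0)
  state <- sample(1:2, 1L)
  while (length(s) < Tn) {
    dwell <- max(1L, round(stats::runif(1L, 0.8 * cc, 1.2 * cc)))
    s <- c(s, rep(state, dwell))
    state <- 3L - state
  }
  s[seq_len(Tn)]
}

.one_hot <- function(states, M = max(states)) {
  Pi <- matrix(0, M, length(states))
  Pi[cbind(states, seq_along(states))] <- 1
  Pi
}

#' Variance-switching benchmark (one informative dimension)
#'
#' The first dimension emits \eqn{N(0, \sigma_{s_t}^2)} driven by a
#' persistent two-state path: state 1 has standard deviation 1, state 2
#' has \eqn{1/\mathtt{sigma\_ratio}}. The two emission laws share their
#' mean, so the regimes differ only in variance — centroid-based
#' clustering cannot separate them, a likelihood-based model can once the
#' ratio departs from 1 (at ratio 1 the laws are identical and any
#' classifier is at chance). Dimensions 2..D are uninformative i.i.d.
#' Uniform[0, 1] confounders.
#'
#' @param Tn number of time points.
#' @param sigma_ratio ratio of the two state standard deviations
#'   (\eqn{\sigma_1/\sigma_2} with \eqn{\sigma_1 = 1}).
#' @param D total number of dimensions (informative: 1).
#' @param eps_trans,mode,seed passed to \code{\link{sim_two_state_path}}.
#' @return list: \code{X} (D x T), \code{Pi} (2 x T one-hot),
#'   \code{states} (integer path), \code{spec} (all parameters).
#' @export
sim_variance_switch <- function(Tn, sigma_ratio, D = 1L, eps_trans = 0.01,
                                mode = "block", seed = NULL) {
  stopifnot(sigma_ratio > 0, D >= 1)
  if (!is.null(seed)) set.seed(seed %% 2147483647L)
  states <- sim_two_state_path(Tn, eps_trans, mode)
  sigmas <- c(1, 1 / sigma_ratio)
  X <- matrix(0, D, Tn)
  X[1, ] <- stats::rnorm(Tn, 0, sigmas[states])
  if (D > 1)
    X[2:D, ] <- stats::runif((D - 1L) * Tn)
  list(X = X, Pi = .one_hot(states, 2L), states = states,
       spec = list(generator = "variance_switch", Tn = Tn,
                   sigma_ratio = sigma_ratio, D = D, eps_trans = eps_trans,
                   mode = mode, seed = seed))
}

#' Rotated bivariate benchmark (two informative dimensions)
#'
#' Both states emit centered bivariate Gaussians: state 1 with covariance
#' \eqn{\mathrm{diag}(\epsilon, 1)} (a thin ellipse), state 2 the same law
#' rotated by angle \code{alpha}. The means overlap by construction;
#' \code{alpha} sets how distinguishable the regimes are
#' (\eqn{\pi/2}: orthogonal ellipses, easy; near 0: coincident laws,
#' chance level). Dimensions 3..D are Uniform[0, 1] confounders.
#'
#' @param Tn number of time points.
#' @param alpha rotation angle in radians, in (0, pi/2].
#' @param eps_thick small variance of the thin axis (default 0.05).
#' @param D total dimensions (>= 2; informative: 2).
#' @param eps_trans,mode,seed passed to \code{\link{sim_two_state_path}}.
#' @return list as in \code{\link{sim_variance_switch}}.
#' @export
sim_rotated_regimes <- function(Tn, alpha, eps_thick = 0.05, D = 2L,
                                eps_trans = 0.01, mode = "block",
                                seed = NULL) {
  stopifnot(alpha > 0, alpha <= pi / 2, eps_thick > 0, D >= 2)
  if (!is.null(seed)) set.seed(seed %% 2147483647L)
  states <- sim_two_state_path(Tn, eps_trans, mode)
  Z <- rbind(stats::rnorm(Tn, 0, sqrt(eps_thick)), stats::rnorm(Tn))
  R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2L, 2L)
  X2 <- Z
  in2 <- states == 2L
  X2[, in2] <- R %*% Z[, in2, drop = FALSE]
  X <- matrix(0, D, Tn)
  X[1:2, ] <- X2
  if (D > 2)
    X[3:D, ] <- stats::runif((D - 2L) * Tn)
  list(X = X, Pi = .one_hot(states, 2L), states = states,
       spec = list(generator = "rotated_regimes", Tn = Tn, alpha = alpha,
                   eps_thick = eps_thick, D = D, eps_trans = eps_trans,
                   mode = mode, seed = seed))
}

#' Default k-mer emission/dwell parameters for the nanopore toy
#'
#' A two-letter alphabet \{A, B\} read with a window of 2 gives four
#' k-mers, each with its own current distribution and dwell-time law.
#' Current means are well separated relative to their common standard
#' deviation; dwell times are geometric (memoryless persistence) with
#' k-mer-specific means chosen so that "BA" dwells are typically much
#' shorter than "BB" dwells.
#'
#' @return data.frame with columns \code{kmer}, \code{mean}, \code{sd},
#'   \code{dwell_mean}.
#' @export
nanopore_kmer_table <- function() {
  data.frame(kmer = c("AA", "AB", "BA", "BB"),
             mean = c(80, 100, 120, 140),
             sd = c(8, 8, 8, 8),
             dwell_mean = c(40, 30, 15, 60),
             stringsAsFactors = FALSE)
}

#' Nanopore-inspired current-trace toy
#'
#' Slides a width-2 window over a two-letter base sequence; each k-mer
#' occupies the pore for a random dwell time (geometric, k-mer-specific
#' mean, at least one sample) during which single-dimensional current
#' samples are drawn from its Gaussian. The labels are the 4-way one-hot
#' k-mer identity per current sample, so a classifier must recover the
#' (semi-Markov) k-mer path from the noisy current alone.
#'
#' @param sequence character string over \{A, B\} (length >= 2), or an
#'   integer \code{n_bases} to draw a random sequence.
#' @param n_bases length of the random sequence when \code{sequence} is
#'   \code{NULL}.
#' @param kmer_table parameter table, see \code{\link{nanopore_kmer_table}}.
#' @param seed optional integer seed.
#' @return list: \code{X} (1 x T currents), \code{Pi} (4 x T one-hot),
#'   \code{states} (k-mer index path, 1..4 in table order), \code{kmers}
#'   (the k-mer sequence along the molecule), \code{spec}.
#' @export
sim_nanopore_toy <- function(sequence = NULL, n_bases = 30L,
                             kmer_table = nanopore_kmer_table(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed %% 2147483647L)
  if (is.null(sequence))
    sequence <- paste(sample(c("A", "B"), n_bases, replace = TRUE),
                      collapse = "")
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 2) stop("sequence shorter than the k-mer length (2)")
  if (!all(bases %in% c("A", "B"))) stop("sequence must use the {A, B} alphabet")
  kmers <- paste0(bases[-length(bases)], bases[-1])
  idx <- match(kmers, kmer_table$kmer)
  dwell <- pmax(1L, stats::rgeom(length(idx), 1 / kmer_table$dwell_mean[idx]) + 1L)
  states <- rep(idx, dwell)
  Tn <- length(states)
  X <- matrix(stats::rnorm(Tn, kmer_table$mean[states],
                           kmer_table$sd[states]), 1L, Tn)
  list(X = X, Pi = .one_hot(states, 4L), states = states, kmers = kmers,
       spec = list(generator = "nanopore_toy", sequence = sequence,
                   kmer_table = kmer_table, seed = seed))
}

#' Takens delay embedding
#'
#' Stacks each observation with its \code{l} predecessors:
#' column \eqn{t'} of the output is
#' \eqn{[x(:,t), x(:,t-1), \dots, x(:,t-l)]} for \eqn{t = t' + l}. Only
#' time points with a complete window are kept, so a D x T input becomes
#' a D(l+1) x (T - l) output. Used to hand temporal context to models
#' without a native notion of time ordering.
#'
#' @param X D x T data matrix.
#' @param l embedding window length (number of lags, >= 0).
#' @return D*(l+1) x (T-l) matrix.
#' @export
takens_embed <- function(X, l) {
  X <- as.matrix(X)
  Tn <- ncol(X)
  stopifnot(l >= 0)
  if (Tn <= l) stop("T must exceed the embedding window length l")
  if (l == 0) return(X)
  do.call(rbind, lapply(0:l, function(j)
    X[, (l + 1 - j):(Tn - j), drop = FALSE]))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties counted one half. 0.5 is chance
#' level, 1 perfect ranking.
#'
#' @param scores numeric scores for the positive class.
#' @param labels 0/1 (or logical) class labels; both classes must occur.
#' @return scalar in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                 # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Chronological triple split
#'
#' Splits 1..T into three contiguous, disjoint, order-preserving blocks
#' (train, validation, test) whose sizes differ by at most one.
#'
#' @param Tn total number of time points (>= 6).
#' @return list of integer index vectors \code{train},
#'   \code{validation}, \code{test}.
#' @export
triple_split <- function(Tn) {
  stopifnot(Tn >= 6)
  sizes <- rep(Tn %/% 3L, 3L)
  extra <- Tn %% 3L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  list(train = seq_len(ends[1]),
       validation = (ends[1] + 1L):ends[2],
       test = (ends[2] + 1L):ends[3])
}
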