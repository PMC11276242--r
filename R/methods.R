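# S3 methods for fitted eSPA-Markov models.

#' @export
print.espa_markov <- function(x, ...) {
  cat("eSPA-Markov model (", x$method, " fit)\n", sep = "")
  cat(sprintf("  D = %d features, T = %d time points, K = %d clusters, M = %d labels\n",
              x$D, x$T, x$K, x$M))
  cat(sprintf("  eps_L = %g, eps_E = %g, eps_CL = %g\n",
              x$hyper$eps_L, x$hyper$eps_E, x$hyper$eps_CL))
  cat(sprintf("  total loss = %.6g nats (%d outer iteration%s%s)\n",
              x$loss$total, x$iterations,
              if (x$iterations == 1L) "" else "s",
              if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' @export
summary.espa_markov <- function(object, ...) {
  hard <- apply(object$Gamma, 2L, which.max)
  occ <- tabulate(hard, object$K) / object$T
  structure(list(model = object, loss = object$loss,
                 cluster_occupancy = occ,
                 top_features = order(object$W, decreasing = TRUE)[
                   seq_len(min(5L, object$D))],
                 W = object$W),
            class = "summary.espa_markov")
}

#' @export
print.summary.espa_markov <- function(x, ...) {
  print(x$model)
  print(x$loss)
  cat("hard cluster occupancy:",
      paste(sprintf("%.3f", x$cluster_occupancy), collapse = " "), "\n")
  cat("largest feature weights (dimension: weight):\n")
  for (d in x$top_features)
    cat(sprintf("  %d: %.4f\n", d, x$W[d]))
  invisible(x)
}

#' Extract model coefficients
#'
#' Returns the learned parameter blocks: Gaussian means and standard
#' deviations, the cluster-to-label classifier and the feature weights.
#'
#' @param object fitted \code{"espa_markov"} model.
#' @param ... unused.
#' @export
coef.espa_markov <- function(object, ...) {
  list(mu = object$mu, sigma = object$sigma,
       Lambda = object$Lambda, W = object$W)
}

#' Fitted label probabilities on the training data
#'
#' @param object fitted \code{"espa_markov"} model.
#' @param ... unused.
#' @return M x T column-stochastic matrix \eqn{\Lambda\Gamma}.
#' @export
fitted.espa_markov <- function(object, ...) {
  object$Lambda %*% object$Gamma
}

#' Diagnostic plots for a fitted model
#'
#' Draws the total-loss trace of the winning restart and a barplot of the
#' learned feature weights.
#'
#' @param x fitted \code{"espa_markov"} model.
#' @param ... passed to the base plotting calls.
#' @export
plot.espa_markov <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(seq_along(x$trace) - 1L, x$trace, type = "b", pch = 16,
       xlab = "outer iteration", ylab = "total loss (nats)",
       main = "coordinate-descent trace", ...)
  graphics::barplot(x$W, names.arg = seq_len(x$D),
                    xlab = "dimension", ylab = "feature weight W",
                    main = "entropic feature weights", ...)
  invisible(x)
}

#' @export
print.espa_prediction <- function(x, ...) {
  cat("eSPA-Markov prediction:", ncol(x$Pi), "time points,",
      nrow(x$Pi), "labels\n")
  cat("hard label counts:",
      paste(tabulate(apply(x$Pi, 2L, which.max), nrow(x$Pi)),
            collapse = " "), "\n")
  invisible(x)
}
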