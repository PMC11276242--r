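# Delimited-text matrix IO and human-readable model serialization.
#
# File orientation follows the internal convention: rows are
# features/labels/clusters, columns are time points. A `transpose` flag
# accommodates samples-as-rows files.

#' Read a numeric matrix from delimited text
#'
#' Parses comma- or tab-separated numeric text (delimiter auto-detected
#' from the first data line). Rows are features/labels/clusters, columns
#' are time points unless \code{transpose}. Ragged or non-numeric input
#' is reported with the offending row/column.
#'
#' @param path file to read.
#' @param header skip a single header line (default FALSE).
#' @param transpose transpose after reading (for samples-as-rows files).
#' @param expect_stochastic_columns validate that every column lies on the
#'   probability simplex (within 1e-6) and error otherwise.
#' @return numeric matrix.
#' @export
read_matrix <- function(path, header = FALSE, transpose = FALSE,
                        expect_stochastic_columns = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    stop("ragged rows in ", path, ": row ", which(n != n[1L])[1L],
         " has ", n[n != n[1L]][1L], " fields, expected ", n[1L])
  m <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("non-numeric value in ", path, " at row ", bad[1L],
         ", column ", bad[2L])
  }
  if (transpose) m <- t(m)
  if (expect_stochastic_columns) {
    ok <- validate_feasible(m, tol = 1e-6)
    if (!isTRUE(ok))
      stop("columns of ", path, " are not stochastic: ", attr(ok, "why"))
  }
  m
}

#' Write a numeric matrix as delimited text
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to a structured text file
#'
#' Writes all model parameters (Gaussian means/SDs, classifier, feature
#' weights, transition prior, hyperparameters, seed, loss trace) as JSON
#' at full double precision, so a round-trip reload reproduces the loss
#' exactly.
#'
#' @param model fitted \code{"espa_markov"} object.
#' @param path output file.
#' @param include_gamma also store the training affiliations (default
#'   TRUE; they are needed to re-evaluate the training loss).
#' @return \code{path}, invisibly.
#' @export
write_espa_model <- function(model, path, include_gamma = TRUE) {
  stopifnot(inherits(model, "espa_markov"))
  doc <- list(
    format = "espa-markov-model",
    version = 1L,
    dims = list(D = model$D, T = model$T, K = model$K, M = model$M),
    hyper = unclass(model$hyper),
    mu = model$mu, sigma = model$sigma, Lambda = model$Lambda,
    W = model$W, P = model$P,
    method = model$method, seed = model$seed,
    n_starts = model$n_starts, restart = model$restart,
    iterations = model$iterations, converged = model$converged,
    loss = unclass(model$loss), trace = model$trace)
  if (include_gamma) doc$Gamma <- model$Gamma
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a fitted model written by \code{\link{write_espa_model}}
#'
#' @param path file to read.
#' @return object of class \code{"espa_markov"}.
#' @export
read_espa_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "espa-markov-model"))
    stop(path, " is not an eSPA-Markov model file")
  as_mat <- function(x) matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
  m <- list(mu = as_mat(doc$mu), sigma = as_mat(doc$sigma),
            Lambda = as_mat(doc$Lambda), W = as.numeric(doc$W),
            Gamma = if (!is.null(doc$Gamma)) as_mat(doc$Gamma),
            loss = structure(as.list(doc$loss), class = "espa_loss"),
            trace = as.numeric(doc$trace),
            initial_loss = NA_real_,
            iterations = doc$iterations, converged = doc$converged,
            restart = doc$restart, P = as_mat(doc$P),
            hyper = espa_hyper(doc$hyper$eps_L, doc$hyper$eps_E,
                               doc$hyper$eps_CL, doc$hyper$K),
            D = doc$dims$D, K = doc$dims$K, M = doc$dims$M, T = doc$dims$T,
            n_starts = doc$n_starts, seed = doc$seed, method = doc$method)
  structure(m, class = "espa_markov")
}

#' Write a simulated dataset as delimited files plus a sidecar
#'
#' Writes \code{X.tsv}, \code{Pi.tsv}, \code{states.tsv} and a JSON
#' sidecar \code{spec.json} capturing the generator parameters and seed.
#'
#' @param sim a generator result (list with \code{X}, \code{Pi},
#'   \code{states}, \code{spec}).
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$X, file.path(dir, "X.tsv"))
  write_matrix(sim$Pi, file.path(dir, "Pi.tsv"))
  write_matrix(matrix(sim$states, nrow = 1L), file.path(dir, "states.tsv"))
  jsonlite::write_json(sim$spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
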