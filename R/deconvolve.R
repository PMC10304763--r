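#' Deconvolute a bulk methylation profile into cell-type proportions
#'
#' Estimates the cell-type-of-origin composition of a bulk (e.g. plasma
#' ccfDNA) methylation profile against a cell-type-specific signature matrix
#' by regressing the bulk betas on the signature columns. Four interchangeable
#' models are offered:
#'
#' * `"nnls"` — non-negative least squares (Lawson–Hanson);
#' * `"qp"` — quadratic program minimizing `||S x - b||^2` subject to
#'   `x >= 0` and `sum(x) = 1`;
#' * `"svr"` — linear-kernel nu support-vector regression (`nu = 0.5`,
#'   `C = 1`), coefficients extracted from the support vectors;
#' * `"rlm"` — robust M-estimation (Huber) linear fit without intercept.
#'
#' For all models except `"qp"` (whose constraints already enforce it),
#' negative coefficients are truncated at zero and the vector is renormalized
#' to sum to one, so the result is always a probability vector over cell
#' types.
#'
#' @param bulk named numeric vector of beta values indexed by probe ID
#'   (missing values allowed; they are dropped probewise), or a one-column
#'   data.frame/matrix with probe IDs as names/rownames.
#' @param signature a [SignatureMatrix-class] (or [MethylationAtlas-class])
#'   whose columns are the candidate cell types.
#' @param model one of `"nnls"`, `"svr"`, `"qp"`, `"rlm"`.
#' @param minProbes minimum number of shared non-missing probes required;
#'   default `max(10, number of cell types)`.
#' @param sampleID label stored in the result.
#' @return A one-row data.frame with columns `sample`, `model`,
#'   `n_probes_used`, `residual_rss`, and one proportion column per cell
#'   type; attribute `"proportions"` holds the named proportion vector.
#' @examples
#' b <- diag(2); dimnames(b) <- list(c("cg1", "cg2"), c("A", "B"))
#' sig <- MethylationAtlas(b)
#' deconvolute(c(cg1 = 0.3, cg2 = 0.7), sig, "nnls", minProbes = 2)
#' @export
deconvolute <- function(bulk, signature, model = c("nnls", "svr", "qp", "rlm"),
                        minProbes = NULL, sampleID = "sample") {
  model <- match.arg(model)
  if (is.data.frame(bulk) || is.matrix(bulk)) {
    nm <- rownames(bulk)
    bulk <- stats::setNames(as.numeric(bulk[, 1]), nm)
  }
  S <- betaValues(signature)
  shared <- intersect(names(bulk)[!is.na(bulk)], rownames(S))
  need <- minProbes %||% max(10L, ncol(S))
  if (length(shared) < need)
    stop(sprintf("only %d shared probes between bulk and signature (need >= %d)",
                 length(shared), need))
  X <- S[shared, , drop = FALSE]
  y <- bulk[shared]
  if (qr(X)$rank < ncol(X))
    warning("signature is rank-deficient on the shared probes; ",
            "solution follows the solver's minimum-norm behavior")
  coefs <- switch(model,
    nnls = pracma::lsqnonneg(X, y)$x,
    qp = .solve_qp_simplex(X, y),
    svr = .solve_svr(X, y),
    rlm = .solve_rlm(X, y)
  )
  coefs <- pmax(coefs, 0)
  if (sum(coefs) == 0) {
    warning("all coefficients zero; returning uniform proportions")
    coefs <- rep(1, ncol(X))
  }
  p <- coefs / sum(coefs)
  names(p) <- colnames(X)
  rss <- sum((y - as.vector(X %*% p))^2)
  out <- data.frame(sample = sampleID, model = model,
                    n_probes_used = length(shared), residual_rss = rss,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(p), check.names = FALSE))
  attr(out, "proportions") <- p
  out
}

# QP on the probability simplex: min ||Xx - y||^2 s.t. sum(x) = 1, x >= 0.
.solve_qp_simplex <- function(X, y) {
  D <- crossprod(X)
  d <- crossprod(X, y)
  k <- ncol(X)
  # small ridge keeps D numerically positive definite for near-collinear
  # signatures without visibly moving the solution
  sc <- mean(diag(D))
  fit <- tryCatch(
    quadprog::solve.QP(D, d, cbind(rep(1, k), diag(k)), c(1, rep(0, k)), meq = 1),
    error = function(e)
      quadprog::solve.QP(D + diag(1e-10 * sc, k), d,
                         cbind(rep(1, k), diag(k)), c(1, rep(0, k)), meq = 1)
  )
  fit$solution
}

.solve_svr <- function(X, y) {
  fit <- e1071::svm(x = X, y = y, type = "nu-regression", kernel = "linear",
                    cost = 1, nu = 0.5, scale = FALSE)
  as.vector(t(fit$coefs) %*% fit$SV)
}

.solve_rlm <- function(X, y) {
  fit <- suppressWarnings(MASS::rlm(X, y, psi = MASS::psi.huber, maxit = 100))
  unname(stats::coef(fit))
}

#' Deconvolute a cohort of bulk profiles
#'
#' Runs [deconvolute()] on every sample, keeping cohort order stable.
#' Per-sample failures are recorded (with the error message) and do not halt
#' the cohort run.
#'
#' @param bulks named list of bulk profiles (each as accepted by
#'   [deconvolute()]).
#' @param signature a [SignatureMatrix-class].
#' @param model deconvolution model name.
#' @param minProbes see [deconvolute()].
#' @return list with `results` (row-bound wide table, one row per successful
#'   sample), `long` (tidy long table: sample, cell_type, proportion, model,
#'   n_probes_used) and `failures` (named character vector of error
#'   messages).
#' @export
deconvoluteCohort <- function(bulks, signature, model = "nnls",
                              minProbes = NULL) {
  if (!length(bulks)) stop("empty cohort")
  ids <- names(bulks) %||% paste0("sample", seq_along(bulks))
  rows <- list(); failures <- character(0)
  for (i in seq_along(bulks)) {
    r <- tryCatch(
      deconvolute(bulks[[i]], signature, model, minProbes, sampleID = ids[i]),
      error = function(e) e
    )
    if (inherits(r, "error")) failures[ids[i]] <- conditionMessage(r)
    else rows[[ids[i]]] <- r
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  long <- NULL
  if (!is.null(results)) {
    cts <- cellTypes(signature)
    long <- do.call(rbind, lapply(rownames(results), function(s) {
      data.frame(sample = results[s, "sample"], cell_type = cts,
                 proportion = as.numeric(results[s, cts]),
                 model = model,
                 n_probes_used = results[s, "n_probes_used"],
                 stringsAsFactors = FALSE)
    }))
    rownames(long) <- NULL
  }
  list(results = results, long = long, failures = failures)
}

#' Extract the proportion matrix from a cohort deconvolution
#'
#' @param cohortResult value of [deconvoluteCohort()].
#' @param signature the signature used (for the cell-type column order).
#' @return numeric matrix, samples in rows, cell types in columns.
#' @export
proportionMatrix <- function(cohortResult, signature) {
  res <- cohortResult$results
  if (is.null(res)) stop("no successful deconvolutions")
  m <- as.matrix(res[, cellTypes(signature), drop = FALSE])
  rownames(m) <- res$sample
  m
}
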