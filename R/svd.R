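#' Reduced-rank continuous features by singular value decomposition
#'
#' Decomposes a (sparse) document by n-gram matrix \eqn{X = U D V'} and
#' represents each transcript by its leading \eqn{k} left-singular
#' coordinates scaled by the singular values, \eqn{U_k D_k} — the standard
#' latent-semantic-analysis document coordinates, identical to
#' \eqn{X V_k}. Rows outside the fit set are projected onto the fitted
#' right-singular basis with the same \eqn{X_{new} V_k} map, so held-out
#' transcripts never influence the basis.
#'
#' @param x Document-term matrix (rows = transcripts); dense or sparse.
#' @param k Number of retained dimensions, or \code{"auto"} for the full
#'   admissible rank \code{min(nrow(fit set), ncol(x))}.
#' @param fit_rows Row names or indices defining the fit set. \code{NULL}
#'   (default) fits on all rows (\code{fit_scope = "full_corpus"}); a subset
#'   gives \code{fit_scope = "train_only"} with the remaining rows projected.
#' @return An object of class \code{"reduced_features"}: list with
#'   \code{scores} (matrix, all rows of \code{x} in input order, k columns),
#'   \code{singular_values} (nonincreasing, length k), \code{basis} (the
#'   right-singular matrix \eqn{V_k}), \code{fit_rows}, \code{fit_scope}
#'   and \code{k}.
#' @examples
#' x <- diag(4)
#' rownames(x) <- paste0("t", 1:4)
#' svd_reduce(x, k = 4)
#' @export
svd_reduce <- function(x, k = "auto", fit_rows = NULL) {
  xm <- as.matrix(x)
  if (is.null(rownames(xm))) rownames(xm) <- as.character(seq_len(nrow(xm)))
  if (is.null(fit_rows)) {
    fit_idx <- seq_len(nrow(xm))
    fit_scope <- "full_corpus"
  } else {
    fit_idx <- if (is.character(fit_rows)) match(fit_rows, rownames(xm))
               else as.integer(fit_rows)
    if (anyNA(fit_idx)) stop("unknown fit rows", call. = FALSE)
    fit_scope <- "train_only"
  }
  kmax <- min(length(fit_idx), ncol(xm))
  if (identical(k, "auto")) k <- kmax
  k <- as.integer(k)
  if (k < 1L || k > kmax)
    stop("`k` must be between 1 and min(#fit rows, #columns) = ", kmax,
         call. = FALSE)
  dec <- svd(xm[fit_idx, , drop = FALSE], nu = 0L, nv = k)
  basis <- dec$v
  rownames(basis) <- colnames(xm)
  scores <- xm %*% basis
  colnames(scores) <- paste0("dim", seq_len(k))
  structure(list(scores = scores,
                 singular_values = dec$d[seq_len(k)],
                 basis = basis,
                 fit_rows = rownames(xm)[fit_idx],
                 fit_scope = fit_scope, k = k),
            class = "reduced_features")
}

#' @export
print.reduced_features <- function(x, ...) {
  cat(sprintf("<reduced_features: %d rows x %d dims (%s; top sv %.3g)>\n",
              nrow(x$scores), x$k, x$fit_scope, x$singular_values[1]))
  invisible(x)
}

#' Project new document vectors into a fitted reduced space
#'
#' @param object A \code{\link{svd_reduce}} result.
#' @param newx New rows over the same vocabulary columns.
#' @param ... Unused.
#' @return Matrix of k-dimensional coordinates.
#' @export
predict.reduced_features <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != nrow(object$basis))
    stop("new data has ", ncol(newx), " columns; expected ",
         nrow(object$basis), call. = FALSE)
  scores <- newx %*% object$basis
  colnames(scores) <- colnames(object$scores)
  scores
}

#' Reconstruction from a truncated SVD
#'
#' Rank-k least-squares reconstruction \eqn{U_k D_k V_k'} of the fit rows;
#' used to check truncation error monotonicity.
#'
#' @param object A \code{\link{svd_reduce}} result.
#' @return Dense matrix with the fit rows reconstructed.
#' @export
svd_reconstruct <- function(object) {
  sc <- object$scores[object$fit_rows, , drop = FALSE]
  sc %*% t(object$basis)
}
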