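#' Mean spatial covariance of a set of epochs
#'
#' The arithmetic mean of the per-epoch spatial covariance matrices
#' `X X' / t` (sample-normalised by the epoch length `t`; the
#' normalisation is a global scale that cancels in the relative band
#' energies downstream and keeps the post-alignment identity invariant in
#' natural units).
#'
#' @param epochs an [epoch_recordings()] result.
#' @param scope_key identifier recorded on the reference (e.g. "sub01/ses1").
#' @param shrinkage optional shrinkage `lambda` towards the scaled identity:
#'   `(1 - lambda) R + lambda * mean(diag(R)) * I`, for rank-deficient scopes.
#' @return Object of class `cov_reference`: `mean_cov` (`R`), `inv_sqrt`
#'   (`R^(-1/2)`), `n_epochs_used`, `scope_key`.
#' @export
mean_covariance <- function(epochs, scope_key = "all", shrinkage = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 1) stop("empty scope: no epochs")
  if (d[2] < 2) stop("need at least 2 channels")
  stopifnot_finite(epochs$data, "epoch data")
  ## sum_n X_n X_n' computed in one crossproduct over stacked samples
  M <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
  R <- crossprod(M) / (d[1] * d[3])
  if (shrinkage > 0)
    R <- (1 - shrinkage) * R + shrinkage * mean(diag(R)) * diag(d[2])
  structure(list(mean_cov = R, inv_sqrt = inv_sqrtm(R),
                 n_epochs_used = d[1], scope_key = scope_key),
            class = "cov_reference")
}

#' Inverse matrix square root of a symmetric PSD matrix
#'
#' Eigendecomposition route: eigenvalues are floored at
#' `1e-10 * max(eigenvalue)` before taking `lambda^(-1/2)`, so
#' rank-deficient inputs yield a finite (pseudo-inverse-like) result.
#'
#' @param R symmetric matrix (checked to tolerance).
#' @param floor_ratio relative eigenvalue floor.
#' @return Symmetric matrix `W` with `W R W` equal to the identity whenever
#'   `R` is well-conditioned.
#' @export
inv_sqrtm <- function(R, floor_ratio = 1e-10) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square")
  tol <- 1e-8 * max(1, max(abs(R)))
  if (max(abs(R - t(R))) > tol) stop("R must be symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) stop("R has no positive eigenvalues; cannot whiten")
  lam <- pmax(e$values, floor_ratio * lmax)
  W <- e$vectors %*% (t(e$vectors) * lam^(-0.5))
  (W + t(W)) / 2
}

#' Euclidean alignment (per-scope covariance whitening)
#'
#' For every scope (by default each subject-session), computes the mean
#' spatial covariance `R` of the scope's epochs and replaces every epoch
#' `X` by `R^(-1/2) X`. After alignment each scope's mean sample-normalised
#' covariance is the identity matrix, so subjects (and databases) share
#' their average second-order statistics. The procedure is fully
#' unsupervised: labels are never used, so test-side data may be aligned
#' with its own references without leakage.
#'
#' @param epochs an `eeg_epochs` object.
#' @param scope `"subject_session"` (default) or `"subject"`: how epochs are
#'   grouped when computing references.
#' @param shrinkage optional shrinkage towards the identity (see
#'   [mean_covariance()]); default 0.
#' @param return_references if `TRUE`, attach the list of per-scope
#'   `cov_reference` objects as attribute `"references"`.
#' @return An `eeg_epochs` object with whitened data; metadata unchanged.
#' @export
ea_align <- function(epochs, scope = c("subject_session", "subject"),
                     shrinkage = 0, return_references = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  scope <- match.arg(scope)
  key <- if (scope == "subject") epochs$meta$subject_id
         else paste(epochs$meta$subject_id, epochs$meta$session_id, sep = "/")
  d <- dim(epochs$data)
  out <- epochs
  refs <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    ref <- mean_covariance(epochs_subset(epochs, idx), scope_key = k,
                           shrinkage = shrinkage)
    refs[[k]] <- ref
    ## whiten all of the scope's epochs in one GEMM:
    ## channels x (samples * n_idx) layout
    M <- matrix(aperm(epochs$data[idx, , , drop = FALSE], c(2, 3, 1)),
                nrow = d[2])
    out$data[idx, , ] <- aperm(array(ref$inv_sqrt %*% M,
                                     dim = c(d[2], d[3], length(idx))),
                               c(3, 1, 2))
  }
  if (return_references) attr(out, "references") <- refs
  out
}
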