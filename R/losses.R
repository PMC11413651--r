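# The four harmonization losses.  All log terms clip probabilities at
# LOSS_EPS for numerical safety; every loss is a mean over the batch, which
# is what makes the procedure robust to the highly variable per-center batch
# sizes of a traveling-model setup.

LOSS_EPS <- 1e-7

.clip01 <- function(p) pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)

#' Disease classification loss (binary cross-entropy)
#'
#' Mean binary cross-entropy between binary labels and predicted
#' probabilities: `-(1/N) sum(y*log(p) + (1-y)*log(1-p))`.
#'
#' @param y binary vector (0/1) of length N.
#' @param p probability vector of length N with entries in (0, 1);
#'   probabilities are clipped at `1e-7` inside the logs.
#' @return Nonnegative scalar.
#' @export
loss_pd <- function(y, p) {
  if (length(y) == 0) stop("empty batch")
  if (length(y) != length(p)) stop("y and p must have equal length")
  if (any(!y %in% c(0, 1))) stop("y must be binary")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("p must lie in (0, 1)")
  }
  p <- .clip01(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Scanner classification loss (categorical cross-entropy)
#'
#' `-(1/N) sum_n sum_j Y[n,j] * log(P[n,j])` for one-hot labels `Y` and
#' row-stochastic predictions `P`.
#'
#' @param Y one-hot N x M label matrix (rows sum to 1).
#' @param P row-stochastic N x M prediction matrix.
#' @return Nonnegative scalar; 0 (up to clipping) iff `P` puts all mass on
#'   the true classes.
#' @export
loss_scanner <- function(Y, P) {
  if (is.null(dim(Y)) || is.null(dim(P)) || !all(dim(Y) == dim(P)))
    stop("Y and P must be matrices of equal shape")
  if (nrow(Y) == 0) stop("empty batch")
  if (any(abs(rowSums(Y) - 1) > 1e-8) || any(!Y %in% c(0, 1)))
    stop("Y must be one-hot")
  -mean(rowSums(Y * log(.clip01(P))))
}

#' Adversarial confusion loss
#'
#' Cross-entropy of the scanner-head output against the uniform distribution
#' over the M scanner types: `-(1/(N*M)) sum_n sum_j log(P[n,j])`.  By Gibbs'
#' inequality the value is at least `log(M)`, with equality exactly when
#' every row is uniform, i.e. when the scanner head is at chance level.
#' Minimizing this loss with respect to the encoder scrubs scanner-specific
#' information from the feature representation.
#'
#' @param P row-stochastic N x M prediction matrix.
#' @return Scalar `>= log(M)`.
#' @export
loss_confusion <- function(P) {
  if (is.null(dim(P)) || nrow(P) == 0) stop("P must be a nonempty matrix")
  -mean(log(.clip01(P)))
}

#' Total harmonization loss
#'
#' Exact sum of the disease, scanner and confusion losses.  Reported as a
#' per-batch diagnostic; the three sub-updates of [harmonization_step()] are
#' applied sequentially.
#'
#' @param l_pd,l_sc,l_conf finite scalars.
#' @return `l_pd + l_sc + l_conf`.
#' @export
loss_total <- function(l_pd, l_sc, l_conf) {
  stopifnot(is.finite(l_pd), is.finite(l_sc), is.finite(l_conf))
  l_pd + l_sc + l_conf
}

#' Per-batch loss record
#'
#' @param l_pd,l_sc,l_conf the three component losses.
#' @return A list with components `l_pd`, `l_sc`, `l_conf` and their exact
#'   sum `l_total`.
#' @export
loss_record <- function(l_pd, l_sc, l_conf) {
  list(l_pd = l_pd, l_sc = l_sc, l_conf = l_conf,
       l_total = loss_total(l_pd, l_sc, l_conf))
}

# One-hot encode scanner ids (1..M) as an N x M matrix.
one_hot <- function(ids, M) {
  ids <- as.integer(ids)
  if (any(ids < 1 | ids > M)) stop("scanner id outside the label space 1..M")
  Y <- matrix(0, length(ids), M)
  Y[cbind(seq_along(ids), ids)] <- 1
  Y
}
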