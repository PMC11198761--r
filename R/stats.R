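#' Cohen's kappa for a square contingency table
#'
#' Unweighted kappa \eqn{\kappa = (P_o - P_e)/(1 - P_e)} with observed
#' agreement \eqn{P_o} on the diagonal and chance agreement \eqn{P_e} from
#' the margins. The standard error uses the Fleiss–Cohen–Everitt
#' asymptotic variance, and the 95\% CI is \eqn{\kappa \pm 1.96\,SE}.
#' Same-index row/column categories count as agreement; pass
#' \code{colOrder} to align categories when the table's column ordering
#' does not match the rows (e.g. mapping a "complete cleft" rating to the
#' "non-adhesion" outcome instead of the layout diagonal).
#'
#' @param counts k x k matrix of non-negative integer counts (raters in
#'   rows/columns).
#' @param colOrder optional integer permutation of columns applied before
#'   computing agreement (default identity, the layout diagonal).
#' @return list with \code{kappa}, \code{se}, \code{ci95} (length-2),
#'   \code{po}, \code{pe}, \code{n}.
#' @examples
#' csfCleftVsSurgery <- matrix(c(4, 7, 6, 5, 9, 10, 2, 3, 6),
#'                             nrow = 3, byrow = TRUE)
#' cohensKappa(csfCleftVsSurgery)$kappa  # ~0.057
#' @export
cohensKappa <- function(counts, colOrder = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contingency table must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[, colOrder, drop = FALSE]
  n <- sum(counts)
  if (n <= 0) stop("empty table")
  p <- counts / n
  a <- rowSums(p)  # rater-1 margins
  b <- colSums(p)  # rater-2 margins
  po <- sum(diag(p))
  pe <- sum(a * b)
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    stop("degenerate margins: chance agreement is 1")
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance of kappa-hat
  k <- nrow(p)
  A <- sum(diag(p) * (1 - (a + b) * (1 - kappa))^2)
  B <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    B <- B + p[i, j] * (b[i] + a[j])^2
  }
  B <- (1 - kappa)^2 * B
  C <- (kappa - pe * (1 - kappa))^2
  varK <- (A + B - C) / (n * (1 - pe)^2)
  se <- sqrt(max(0, varK))
  list(kappa = kappa, se = se,
       ci95 = c(kappa - 1.96 * se, kappa + 1.96 * se),
       po = po, pe = pe, n = n)
}

#' Mann–Whitney AUC
#'
#' Probability that a positive case scores above a negative case, ties
#' counted half: \eqn{AUC = (\#\{pos > neg\} + \tfrac12 \#ties)/(n_+ n_-)}.
#' Equals the area under the empirical ROC curve and the normalized
#' Mann–Whitney U statistic.
#'
#' @param scores numeric case scores.
#' @param labels binary labels (coercible to logical; TRUE/1 = positive).
#' @return AUC in [0, 1].
#' @examples
#' aucMannWhitney(c(3, 1, 2, 4), c(0, 0, 1, 1))  # 0.75
#' @export
aucMannWhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  r <- rank(c(pos, neg), ties.method = "average")
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# DeLong structural components: V10 over positives, V01 over negatives.
.delongComponents <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same cases using the
#' DeLong structural-components estimator of the covariance of the paired
#' AUCs; the z statistic is the AUC difference over the standard error of
#' the difference, with a two-sided normal p-value. A degenerate zero
#' variance of the difference (e.g. identical scores) yields z = 0,
#' p = 1, flagged.
#'
#' @param labels binary case labels (TRUE/1 = positive).
#' @param scoresA,scoresB the two per-case scores.
#' @return list with \code{aucA}, \code{aucB}, \code{varA}, \code{varB},
#'   \code{cov}, \code{z}, \code{p}, \code{degenerate}.
#' @export
delongTest <- function(labels, scoresA, scoresB) {
  labels <- as.logical(labels)
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stop("length mismatch")
  if (sum(labels) == 0L || sum(!labels) == 0L)
    stop("both classes must be present")
  ca <- .delongComponents(scoresA, labels)
  cb <- .delongComponents(scoresB, labels)
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  varA <- s10[1, 1] / m + s01[1, 1] / n
  varB <- s10[2, 2] / m + s01[2, 2] / n
  covAB <- s10[1, 2] / m + s01[1, 2] / n
  varDiff <- varA + varB - 2 * covAB
  if (varDiff <= .Machine$double.eps) {
    return(list(aucA = ca$auc, aucB = cb$auc, varA = varA, varB = varB,
                cov = covAB, z = 0, p = 1, degenerate = TRUE))
  }
  z <- (ca$auc - cb$auc) / sqrt(varDiff)
  list(aucA = ca$auc, aucB = cb$auc, varA = varA, varB = varB,
       cov = covAB, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measure, absolute-agreement ICC from the two-way ANOVA mean
#' squares of an n-subjects by m-raters grid:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (m-1) MS_E +
#'   \tfrac{m}{n}(MS_C - MS_E)}}
#'
#' @param measurements n x m numeric matrix, no missing entries.
#' @return the ICC(2,1) estimate.
#' @examples
#' m <- cbind(c(9, 2, 5, 8), c(9, 2, 5, 8))
#' iccTwoWay(m)  # identical raters: 1
#' @export
iccTwoWay <- function(measurements) {
  x <- as.matrix(measurements)
  if (anyNA(x)) stop("no missing entries allowed")
  n <- nrow(x); m <- ncol(x)
  if (n < 2L || m < 2L) stop("need >= 2 subjects and >= 2 raters")
  g <- mean(x)
  ssTotal <- sum((x - g)^2)
  if (ssTotal <= .Machine$double.eps) stop("zero total variance")
  rowM <- rowMeans(x)
  colM <- colMeans(x)
  ssRows <- m * sum((rowM - g)^2)
  ssCols <- n * sum((colM - g)^2)
  ssErr <- ssTotal - ssRows - ssCols
  msR <- ssRows / (n - 1)
  msC <- ssCols / (m - 1)
  msE <- ssErr / ((n - 1) * (m - 1))
  (msR - msE) / (msR + (m - 1) * msE + (m / n) * (msC - msE))
}
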