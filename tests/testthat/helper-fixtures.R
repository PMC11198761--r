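# Shared fixtures and independent oracles, built in code at test time.

# Small, fast phantom conditions for unit tests (the full-size defaults are
# exercised in the acceptance suite).
smallPhantomSpec <- function(...) {
  phantomSpec(gridShape = c(32L, 32L, 24L), spacing = c(2, 2, 2),
              tumorRadiusMM = 10, ...)
}

# Independent principal-strain OSS oracle: assemble the symmetric tensor,
# take eigenvalues, and use (2/3) sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2).
ossEigenOracle <- function(exx, eyy, ezz, exy, exz, eyz) {
  m <- matrix(c(exx, exy, exz, exy, eyy, eyz, exz, eyz, ezz), 3, 3)
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  (2 / 3) * sqrt((e[1] - e[2])^2 + (e[2] - e[3])^2 + (e[3] - e[1])^2)
}

# Random star-shaped (hole-free) ROI on an n x n slice.
randomBlobRoi <- function(n) {
  cr <- runif(1, n * 0.35, n * 0.65)
  cc <- runif(1, n * 0.35, n * 0.65)
  base <- runif(1, n * 0.12, n * 0.25)
  nharm <- 3L
  amp <- runif(nharm, 0, 0.25 * base)
  ph <- runif(nharm, 0, 2 * pi)
  roi <- matrix(FALSE, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    ang <- atan2(c - cc, r - cr)
    rad <- base + sum(amp * cos(seq_len(nharm) * ang + ph))
    roi[r, c] <- sqrt((r - cr)^2 + (c - cc)^2) <= rad
  }
  roi
}

# Exhaustive, self-contained re-evaluation of the SIR decision function on
# one slice: RP extraction, standardization, patch selection and the three
# conditions written out directly, independent of the package internals.
sirSliceOracle <- function(nossSlice, roi, pad = 3L, delta = 0.065,
                           c1max = 0.85, c1min = 1.15, c2 = 0.20,
                           c3 = 0.80) {
  idx <- which(roi, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(nossSlice), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1c <- min(ncol(nossSlice), max(idx[, 2]) + pad)
  sub <- nossSlice[r0:r1, c0:c1c, drop = FALSE]
  mx <- suppressWarnings(max(sub, na.rm = TRUE))
  if (is.finite(mx) && mx > 0) sub <- sub / mx
  rpMax <- max(sub, na.rm = TRUE)
  rpMin <- min(sub, na.rm = TRUE)
  nr <- nrow(roi); nc <- ncol(roi)
  patchStats <- function(pr, pc, size) {
    half <- (size - 1L) / 2L
    vals <- c()
    for (dr in -half:half) for (dc in -half:half) {
      rr <- min(nrow(sub), max(1L, pr + dr))
      cc <- min(ncol(sub), max(1L, pc + dc))
      vals <- c(vals, sub[rr, cc])
    }
    vals
  }
  out <- list()
  for (q in seq_len(nrow(idx))) {
    r <- idx[q, 1]; c <- idx[q, 2]
    nbrOutside <- (r == 1 || !roi[r - 1, c]) || (r == nr || !roi[r + 1, c]) ||
                  (c == 1 || !roi[r, c - 1]) || (c == nc || !roi[r, c + 1])
    if (!nbrOutside) next
    pr <- r - r0 + 1L; pc <- c - c0 + 1L
    iA <- sub[pr, pc]
    if (is.na(iA)) next
    v3 <- patchStats(pr, pc, 3L)
    m3 <- mean(v3, na.rm = TRUE)
    vals <- if (is.finite(m3) && abs(m3 - iA) < delta) patchStats(pr, pc, 5L) else v3
    vv <- vals[!is.na(vals)]
    pMin <- min(vv); pMax <- max(vv); pMean <- mean(vv)
    if (iA > c1max * rpMax || iA < c1min * rpMin) cond <- "I"
    else if (abs(iA - pMean) > c2 * (pMax - pMin)) cond <- "II"
    else if ((pMax - pMin) > c3 * iA) cond <- "III"
    else cond <- "none"
    out[[length(out) + 1L]] <- data.frame(row = r, col = c,
      nonAdherent = cond != "none", condition = cond)
  }
  do.call(rbind, out)
}

# Wrap a single slice as a one-slice NOSS volume + mask for runSIR.
sliceAsVolume <- function(nossSlice, roi) {
  d <- c(dim(nossSlice), 1L)
  list(noss = ScalarMap(array(nossSlice, d), "NOSS", c(1, 1, 1)),
       mask = array(roi, d))
}
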