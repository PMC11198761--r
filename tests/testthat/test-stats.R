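csfCleftTable <- matrix(c(4, 7, 6,
                          5, 9, 10,
                          2, 3, 6), nrow = 3, byrow = TRUE)

test_that("Cohen's kappa reproduces known values", {
  k <- cohensKappa(csfCleftTable)
  expect_equal(round(k$kappa, 3), 0.057)
  expect_true(k$ci95[1] <= k$kappa && k$kappa <= k$ci95[2])
  # CI close to the published (-0.13, 0.24); the SE formula used by the
  # original software is unknown, so agreement is approximate
  expect_lt(abs(k$ci95[1] - (-0.13)), 0.02)
  expect_lt(abs(k$ci95[2] - 0.24), 0.02)

  expect_equal(cohensKappa(diag(c(10, 10, 10)))$kappa, 1)
  expect_equal(cohensKappa(matrix(1, 2, 2))$kappa, 0)
  # chance-level: counts equal to the outer product of margins
  expect_equal(cohensKappa(outer(c(2, 6), c(4, 4)) / 2)$kappa, 0)

  expect_error(cohensKappa(matrix(c(5, 0, 0, 0), 2, 2)), "degenerate")
  expect_error(cohensKappa(matrix(1, 2, 3)), "square")
})

test_that("kappa is invariant under simultaneous category permutation", {
  set.seed(12)
  for (rep in 1:10) {
    tab <- matrix(rpois(9, 5), 3, 3)
    if (sum(diag(tab)) == 0) tab <- tab + diag(3)
    perm <- sample(3)
    k1 <- cohensKappa(tab)$kappa
    k2 <- cohensKappa(tab[perm, perm])$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
    expect_gte(k1, -1); expect_lte(k1, 1)
  }
})

test_that("kappa standard error agrees with Monte-Carlo resampling", {
  p <- csfCleftTable / sum(csfCleftTable)
  N <- 400L
  set.seed(42)
  kk <- replicate(600, {
    counts <- matrix(stats::rmultinom(1, N, as.vector(p)), 3, 3)
    cohensKappa(counts)$kappa
  })
  analytic <- cohensKappa(round(p * N))$se
  expect_lt(abs(stats::sd(kk) - analytic) / analytic, 0.15)
})

test_that("column re-mapping changes the agreement pairing", {
  # reversing the outcome ordering pairs complete cleft with non-adhesion
  kDiag <- cohensKappa(csfCleftTable)$kappa
  kClin <- cohensKappa(csfCleftTable, colOrder = c(3, 2, 1))$kappa
  expect_false(isTRUE(all.equal(kDiag, kClin)))
})

test_that("Mann-Whitney AUC equals exhaustive pair counting", {
  expect_equal(aucMannWhitney(c(3, 1, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(aucMannWhitney(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)

  pairCountOracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    s <- 0
    for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(pos) * length(neg))
  }
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:6, n, replace = TRUE)  # ties likely
    a <- aucMannWhitney(scores, labels)
    expect_equal(a, pairCountOracle(scores, labels), tolerance = 1e-12)
    expect_gte(a, 0); expect_lte(a, 1)
    # U-statistic cross-check
    u <- suppressWarnings(stats::wilcox.test(scores[labels == 1],
                                             scores[labels == 0]))$statistic
    expect_equal(a, unname(u) / (sum(labels) * sum(!labels)),
                 tolerance = 1e-12)
    if (!any(duplicated(scores)))
      expect_equal(a + aucMannWhitney(-scores, labels), 1)
  }
  expect_error(aucMannWhitney(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong components match exhaustive enumeration", {
  enumOracle <- function(labels, scores) {
    pos <- scores[labels]; neg <- scores[!labels]
    m <- length(pos); n <- length(neg)
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) {
      s <- 0
      for (j in seq_len(n)) s <- s + (pos[i] > neg[j]) + 0.5 * (pos[i] == neg[j])
      v10[i] <- s / n
    }
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(m)) s <- s + (pos[i] > neg[j]) + 0.5 * (pos[i] == neg[j])
      v01[j] <- s / m
    }
    auc <- mean(v10)
    varAuc <- stats::var(v10) / m + stats::var(v01) / n
    list(auc = auc, varAuc = varAuc)
  }
  labels <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  sA <- c(0.9, 0.8, 0.35, 0.7, 0.2, 0.4, 0.3, 0.6)
  sB <- c(0.7, 0.6, 0.5, 0.4, 0.45, 0.2, 0.55, 0.1)
  dl <- delongTest(labels, sA, sB)
  oA <- enumOracle(labels, sA)
  oB <- enumOracle(labels, sB)
  expect_equal(dl$aucA, oA$auc, tolerance = 1e-12)
  expect_equal(dl$varA, oA$varAuc, tolerance = 1e-12)
  expect_equal(dl$varB, oB$varAuc, tolerance = 1e-12)

  # antisymmetry and degenerate identical scores
  dlSwap <- delongTest(labels, sB, sA)
  expect_equal(dlSwap$z, -dl$z, tolerance = 1e-12)
  expect_equal(dlSwap$p, dl$p, tolerance = 1e-12)
  dlSame <- delongTest(labels, sA, sA)
  expect_true(dlSame$degenerate)
  expect_equal(dlSame$z, 0); expect_equal(dlSame$p, 1)
  expect_error(delongTest(rep(TRUE, 4), 1:4, 1:4), "both classes")
})

test_that("DeLong z and p agree with pROC on random paired scores", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (rep in 1:5) {
    n <- 30L
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    sA <- rnorm(n, mean = ifelse(labels, 0.8, 0))
    sB <- 0.5 * sA + rnorm(n, mean = ifelse(labels, 0.3, 0))
    dl <- delongTest(labels, sA, sB)
    rt <- pROC::roc.test(
      pROC::roc(labels, sA, quiet = TRUE, direction = "<"),
      pROC::roc(labels, sB, quiet = TRUE, direction = "<"),
      method = "delong")
    expect_equal(abs(dl$z), abs(unname(rt$statistic)), tolerance = 1e-8)
    expect_equal(dl$p, rt$p.value, tolerance = 1e-8)
  }
})

test_that("DeLong variance matches Hanley-McNeil under the exponential model", {
  # for exponential scores, Q1 = A/(2-A) and Q2 = 2A^2/(1+A) hold exactly
  set.seed(77)
  m <- 30L; n <- 30L
  theta <- 3  # scale ratio, true AUC = theta/(1+theta)
  A <- theta / (1 + theta)
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  hm <- (A * (1 - A) + (m - 1) * (q1 - A^2) + (n - 1) * (q2 - A^2)) / (m * n)
  vars <- replicate(300, {
    pos <- stats::rexp(m, rate = 1 / theta)
    neg <- stats::rexp(n, rate = 1)
    labels <- rep(c(TRUE, FALSE), c(m, n))
    delongTest(labels, c(pos, neg), c(pos, neg) * 2)$varA
  })
  expect_lt(abs(mean(vars) - hm) / hm, 0.15)
})

test_that("ICC(2,1) behaves as a two-way absolute-agreement index", {
  # identical raters
  expect_equal(iccTwoWay(cbind(c(9, 2, 5, 8), c(9, 2, 5, 8))), 1)

  # constant offset: absolute agreement penalized, consistency would be 1
  x <- c(1, 4, 7, 10)
  m2 <- cbind(x, x + 3)
  iccAbs <- iccTwoWay(m2)
  # consistency version from the same ANOVA mean squares (oracle via aov)
  df <- data.frame(y = as.vector(m2),
                   subj = factor(rep(1:4, 2)), rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msR <- ms[1]; msC <- ms[2]; msE <- ms[3]
  iccCons <- (msR - msE) / (msR + (2 - 1) * msE)
  expect_lt(iccAbs, 1)
  expect_equal(iccCons, 1, tolerance = 1e-12)
  # and the absolute-agreement assembly matches the aov mean squares
  iccOracle <- (msR - msE) / (msR + (2 - 1) * msE + (2 / 4) * (msC - msE))
  expect_equal(iccAbs, iccOracle, tolerance = 1e-12)

  # identical subjects, raters pure noise: ICC near 0
  set.seed(6)
  noise <- matrix(rnorm(40), 20, 2)
  expect_lt(abs(iccTwoWay(noise)), 0.35)

  # random grids match the aov-mean-square oracle
  for (rep in 1:5) {
    g <- matrix(rnorm(24, sd = 2) + rep(rnorm(8, sd = 3), 3), 8, 3)
    dfg <- data.frame(y = as.vector(g), subj = factor(rep(1:8, 3)),
                      rater = factor(rep(1:3, each = 8)))
    msg <- summary(stats::aov(y ~ subj + rater, data = dfg))[[1]][["Mean Sq"]]
    oracle <- (msg[1] - msg[3]) /
      (msg[1] + (3 - 1) * msg[3] + (3 / 8) * (msg[2] - msg[3]))
    expect_equal(iccTwoWay(g), oracle, tolerance = 1e-10)
  }

  expect_error(iccTwoWay(matrix(1, 4, 2)), "zero total variance")
  expect_error(iccTwoWay(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})
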