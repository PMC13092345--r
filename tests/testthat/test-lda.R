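test_that("Wilks lambda matches a brute-force scatter computation", {
  set.seed(2)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  lab <- rep(c("g1", "g2", "g3"), each = 10)
  X[lab == "g2", 1] <- X[lab == "g2", 1] + 2
  # independent route: explicit elementwise scatter sums
  sc <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    t(M) %*% M
  }
  W <- sc(X[1:10, ]) + sc(X[11:20, ]) + sc(X[21:30, ])
  Tm <- sc(X)
  expect_equal(wilksLambda(X, lab), det(W) / det(Tm), tolerance = 1e-12)
  expect_lt(wilksLambda(X, lab), 1)
})

test_that("identical class means give lambda of one and separation drives it to zero", {
  X <- cbind(f = c(1, 2, 3, 1, 2, 3))
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(wilksLambda(X, lab), 1, tolerance = 1e-12)
  # near-zero within-class variance with distinct means
  X2 <- cbind(f = c(0, 1e-8, 10, 10 + 1e-8))
  expect_lt(wilksLambda(X2, rep(c("a", "b"), each = 2)), 1e-10)
  # collinear features make the scatter singular
  X3 <- cbind(f1 = rnorm(10), f2 = 0)
  X3[, 2] <- X3[, 1]
  expect_error(wilksLambda(X3, rep(c("a", "b"), each = 5)), "collinear")
})

test_that("a perfectly separating feature is selected first and duplicates never enter", {
  set.seed(3)
  n <- 40
  X <- cbind(signal = c(rnorm(n, 0, 0.3), rnorm(n, 5, 0.3)),
             noise1 = rnorm(2 * n), noise2 = rnorm(2 * n))
  X <- cbind(X, dup = X[, "signal"])
  lab <- rep(c("a", "b"), each = n)
  sel <- greedyWilks(X, lab)
  # "signal" and "dup" are identical columns: exactly one of the pair is
  # admitted (first, by the lexicographic tie-break), never both
  expect_equal(sel$features[1], "dup")
  expect_false("signal" %in% sel$features)
  expect_true(all(diff(c(1, sel$trace$lambda)) < 0))
  expect_true(all(sel$trace$pvalue <= 0.05))
})

test_that("greedy selection recovers planted informative features across seeds", {
  hits <- 0L
  nSeeds <- 20
  for (seed in seq_len(nSeeds)) {
    set.seed(seed)
    n <- 60
    mu <- rbind(c1 = c(0, 0, rep(0, 8)),
                c2 = c(2.5, 0, rep(0, 8)),
                c3 = c(0, 2.5, rep(0, 8)))
    colnames(mu) <- c("inf1", "inf2", paste0("noise", 1:8))
    tab <- makeSyntheticFeatureTable(mu, diag(10), n)
    sel <- greedyWilks(tab$X, tab$labels)
    if (all(c("inf1", "inf2") %in% sel$features[1:2])) hits <- hits + 1L
  }
  expect_gte(hits / nSeeds, 0.95)
})

test_that("the fitted discriminant agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  mu <- rbind(A = c(0, 0), B = c(2, 0), C = c(0, 2))
  colnames(mu) <- c("x", "y")
  train <- makeSyntheticFeatureTable(mu, diag(2), 40)
  test <- makeSyntheticFeatureTable(mu, diag(2), 25)
  own <- fitLDA(train$X, train$labels)
  ref <- MASS::lda(train$X, grouping = train$labels)
  predOwn <- predict(own, test$X)
  predRef <- predict(ref, test$X)$class
  expect_equal(as.character(predOwn), as.character(predRef))
})

test_that("two separated 1-D Gaussians split at the midpoint of the means", {
  set.seed(10)
  mu <- rbind(lo = 0, hi = 4)
  colnames(mu) <- "f"
  tab <- makeSyntheticFeatureTable(mu, matrix(1), 200)
  fit <- fitLDA(tab$X, tab$labels)
  # equal variances and priors: boundary at 2
  grid <- matrix(seq(1.8, 2.2, by = 0.01), ncol = 1,
                 dimnames = list(NULL, "f"))
  pr <- predict(fit, grid)
  boundary <- unname(grid[max(which(pr == "lo")), 1])
  expect_equal(boundary, 2, tolerance = 0.2)
  expect_error(fitLDA(tab$X[tab$labels == "lo", , drop = FALSE],
                      droplevels(tab$labels[tab$labels == "lo"])),
               "2 classes")
})

test_that("held-out accuracy approaches the closed-form Bayes accuracy", {
  set.seed(11)
  mu <- rbind(a = -1, b = 1)
  colnames(mu) <- "f"
  train <- makeSyntheticFeatureTable(mu, matrix(1), 400)
  test <- makeSyntheticFeatureTable(mu, matrix(1), 4000)
  fit <- fitLDA(train$X, train$labels)
  ev <- evaluateLDA(fit, test$X, test$labels)
  bayes <- pnorm(1)  # ~0.8413
  se <- sqrt(bayes * (1 - bayes) / 8000)
  expect_lt(abs(ev$meanAccuracy - bayes), 4 * se + 0.01)
})

test_that("training accuracy matches a brute-force plug-in Bayes oracle", {
  set.seed(12)
  mu <- matrix(rnorm(10, sd = 3), 5, 2,
               dimnames = list(paste0("k", 1:5), c("x", "y")))
  tab <- makeSyntheticFeatureTable(mu, diag(2) * 0.5, 50)
  fit <- fitLDA(tab$X, tab$labels)
  pred <- predict(fit, tab$X)
  # oracle: plug-in Bayes rule with the same estimates, coded independently
  Sinv <- solve(fit@pooledCov)
  oracle <- apply(tab$X, 1, function(x) {
    sc <- vapply(seq_len(5), function(k) {
      m <- fit@classMeans[k, ]
      -0.5 * t(x - m) %*% Sinv %*% (x - m) + log(fit@priors[k])
    }, numeric(1))
    rownames(mu)[which.max(sc)]
  })
  expect_equal(as.character(pred), unname(oracle))
})

test_that("confusion matrices are row-normalised with balanced mean accuracy", {
  set.seed(13)
  mu <- rbind(A = c(0, 0), B = c(8, 0), C = c(0, 8))
  colnames(mu) <- c("x", "y")
  train <- makeSyntheticFeatureTable(mu, diag(2), 30)
  test <- makeSyntheticFeatureTable(mu, diag(2), 30)
  fit <- fitLDA(train$X, train$labels)
  ev <- evaluateLDA(fit, test$X, test$labels)
  expect_equal(unname(rowSums(ev$confusion)), rep(1, 3))
  expect_gte(ev$meanAccuracy, 0.99)  # means 8 pooled sds apart
  expect_equal(ev$perClass, diag(ev$confusion))
  # label permutation destroys performance
  set.seed(14)
  perm <- sample(test$labels)
  evPerm <- evaluateLDA(fit, test$X, perm)
  se <- sqrt((1 / 3) * (2 / 3) / 90)
  expect_lt(abs(evPerm$meanAccuracy - 1 / 3), 3 * se + 0.05)
})

test_that("collinear NCD (TF = 0.5) features are tolerated or dropped", {
  set.seed(15)
  n <- 30
  base <- c(rnorm(n, 0, 0.5), rnorm(n, 3, 0.5))
  lab <- rep(c("a", "b"), each = n)
  # exactly collinear basic and standardized NCD at TF 0.5: the second
  # copy can never be admitted, other features still enter
  X <- cbind(ncd_tf50_w0_end_summer = base,
             ncd_std_tf50_w0_end_summer = base * 2 + 1,
             pi_w0_end_summer = base + rnorm(2 * n, 0, 0.2))
  sel <- greedyWilks(X, lab)
  expect_false(all(c("ncd_tf50_w0_end_summer", "ncd_std_tf50_w0_end_summer")
                   %in% sel$features))
  # a selection that cannot start at all removes the TF=0.5 features
  # (logged) before giving up on the remaining degenerate input
  Xdeg <- cbind(ncd_tf50_w0_end_summer = rep(1, 2 * n),
                pi_w0_end_summer = rep(2, 2 * n))
  expect_message(try(greedyWilks(Xdeg, lab), silent = TRUE), "NCD")
})
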