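test_that("shape PCA spans the data and reports variance fractions", {
  # data on a line: PC1 explains everything
  set.seed(1)
  t <- rnorm(40)
  X <- cbind(2 * t, -t) + 5
  sp <- shape_pca(X, rep(c("a", "b"), 20), n_retain = 1)
  expect_equal(sp$explained[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(sp$scores))), 1e-12)

  # isotropic Gaussian: explained fractions ~ (1/2, 1/2)
  set.seed(2)
  Y <- matrix(rnorm(20000), ncol = 2)
  spy <- shape_pca(Y, rep("a", 10000), n_retain = 2)
  expect_equal(unname(spy$explained), c(.5, .5), tolerance = 0.02)

  # full-rank scores preserve pairwise distances (isometry)
  set.seed(3)
  Z <- matrix(rnorm(60), 12, 5)
  spz <- shape_pca(Z, rep(c("a", "b"), 6), n_retain = 5)
  expect_equal(as.matrix(dist(spz$scores)), as.matrix(dist(Z)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # retaining beyond the rank warns and reduces
  flat <- cbind(t, 2 * t, 3 * t)
  expect_warning(sp2 <- shape_pca(flat, rep(c("a", "b"), 20), n_retain = 3),
                 "rank")
  expect_equal(sp2$n_retained, 1L)
})

test_that("discriminant analysis finds separation axes with correct shares", {
  set.seed(4)
  # two species separated along x only: one DF, 100% of variance
  X <- rbind(cbind(rnorm(30), rnorm(30)), cbind(rnorm(30) + 6, rnorm(30)))
  lb <- rep(c("a", "b"), each = 30)
  dm <- discriminant_analysis(list(scores = X, labels = lb))
  expect_equal(length(dm$df_variance_fractions), 1L)
  expect_equal(sum(dm$df_variance_fractions), 1, tolerance = 1e-12)
  # the single axis points along x (up to sign)
  ax <- dm$axes[, 1] / sqrt(sum(dm$axes[, 1]^2))
  expect_gt(abs(ax[1]), 0.99)

  # factor map invariant (up to sign) under invertible linear transforms
  set.seed(5)
  X3 <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40) + 1.5, 20),
              matrix(rnorm(40) - 1.5, 20))
  lb3 <- rep(c("a", "b", "c"), each = 20)
  m1 <- discriminant_analysis(list(scores = X3, labels = lb3))
  A <- matrix(c(2, .5, -1, 3), 2, 2)
  m2 <- discriminant_analysis(list(scores = X3 %*% A, labels = lb3))
  for (j in 1:2) {
    agree <- max(abs(m1$factor_map[, j] - m2$factor_map[, j]),
                 abs(m1$factor_map[, j] + m2$factor_map[, j]))
    flip <- min(max(abs(m1$factor_map[, j] - m2$factor_map[, j])),
                max(abs(m1$factor_map[, j] + m2$factor_map[, j])))
    expect_lt(flip, 1e-6)
  }
  expect_equal(m1$df_variance_fractions, m2$df_variance_fractions,
               tolerance = 1e-9)
})

test_that("null discriminant analysis shows no structure", {
  set.seed(6)
  X <- matrix(rnorm(3000), 1500, 2)
  lb <- sample(rep(letters[1:5], 300))
  dm <- discriminant_analysis(list(scores = X, labels = lb))
  # group means nearly coincide relative to within-group spread
  expect_lt(max(dist(dm$group_means)), 0.3)
  # eigenvalue shares near uniform over k-1 = 4... with 2 dims: 2 axes
  expect_lt(dm$df_variance_fractions[1], 0.85)
})

test_that("Mahalanobis distances match closed forms and affine invariance", {
  # 1-D: exact means 0 and 2, exact pooled variance 1 -> D = 2
  x <- c(1, -1, 3, 1) / sqrt(2)            # groups (+-1/sqrt2), shifted
  x[3:4] <- x[1:2] + 2
  lb <- rep(c("a", "b"), each = 2)
  D <- mahalanobis_matrix(list(scores = matrix(x, ncol = 1), labels = lb))
  expect_equal(unname(D["a", "b"]), 2, tolerance = 1e-12)

  # identical group means -> 0
  set.seed(7)
  pts <- matrix(rnorm(40), 20, 2)
  D0 <- mahalanobis_matrix(list(scores = rbind(pts, pts),
                                labels = rep(c("a", "b"), each = 20)))
  expect_equal(unname(D0["a", "b"]), 0, tolerance = 1e-9)

  # 2-D exact identity pooled covariance, means (0,0) and (3,4) -> D = 5
  cc <- sqrt(1.5)
  G1 <- rbind(c(cc, 0), c(-cc, 0), c(0, cc), c(0, -cc))
  G2 <- sweep(G1, 2, c(3, 4), `+`)
  D5 <- mahalanobis_matrix(list(scores = rbind(G1, G2),
                                labels = rep(c("a", "b"), each = 4)))
  expect_equal(unname(D5["a", "b"]), 5, tolerance = 1e-12)

  # affine invariance
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  X[34:66, 1] <- X[34:66, 1] + 2
  lb3 <- rep(c("a", "b", "c"), times = c(33, 33, 34))
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  D1 <- mahalanobis_matrix(list(scores = X, labels = lb3))
  D2 <- mahalanobis_matrix(list(scores = sweep(X %*% A, 2, c(1, -2, 3), `+`),
                                labels = lb3))
  expect_equal(D1, D2, tolerance = 1e-6)
  expect_true(isSymmetric(D1))
  expect_equal(unname(diag(D1)), rep(0, 3))
})

test_that("permutation p-values respect their bounds and detect separation", {
  # identical values in both groups: every permutation ties, p = 1
  lb <- rep(c("a", "b"), each = 10)
  p1 <- permutation_test(rep(3.3, 20), lb, "mean_difference", B = 200,
                         seed = 1)
  expect_equal(p1$p_value, 1)

  # complete separation: no permuted statistic can exceed the observed
  set.seed(2)
  v <- c(rnorm(20), rnorm(20, 10))
  p2 <- permutation_test(v, rep(c("a", "b"), each = 20), B = 1000, seed = 3)
  expect_equal(p2$p_value, 1 / 1001, tolerance = 1e-12)
  expect_true(p2$significant)

  # add-one lower bound holds for every pair, all statistics
  set.seed(4)
  X <- matrix(rnorm(120), 60, 2)
  lbs <- rep(c("a", "b", "c"), each = 20)
  pm <- permutation_test(X, lbs, "mahalanobis", B = 49, seed = 5)
  expect_true(all(pm$p_value >= 1 / 50 - 1e-12))
  expect_true(all(pm$p_value <= 1))
  expect_equal(attr(pm, "bonferroni_alpha"), 0.05 / 3)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(10)
  pvals <- replicate(200, {
    v <- rnorm(24)
    permutation_test(v, rep(c("a", "b"), each = 12), B = 99)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("LOO shape classification matches independent oracles", {
  # perfectly separated tight clusters: 100% everywhere
  set.seed(11)
  X <- rbind(matrix(rnorm(30, 0, .05), ncol = 2),
             matrix(rnorm(30, 5, .05), ncol = 2),
             matrix(rnorm(30, 10, .05), ncol = 2))
  lb <- rep(c("a", "b", "c"), each = 15)
  rep100 <- loo_classify_shape(list(scores = X, labels = lb))
  expect_equal(rep100$total_accuracy_percent, 100)
  expect_equal(rep100$per_species$accuracy_percent, rep(100, 3))

  # 12-specimen instance: agree with a naive brute-force reimplementation
  set.seed(12)
  Y <- matrix(rnorm(24, sd = 1.2), 12, 2) +
    cbind(rep(c(0, 2, 4), each = 4), rep(c(0, 1, 0), each = 4))
  lby <- rep(c("a", "b", "c"), each = 4)
  mine <- loo_classify_shape(list(scores = Y, labels = lby))
  naive <- character(12)
  for (i in 1:12) {
    tr <- Y[-i, , drop = FALSE]; gl <- lby[-i]
    sps <- sort(unique(gl))
    mus <- lapply(sps, function(g) colMeans(tr[gl == g, , drop = FALSE]))
    Sp <- matrix(0, 2, 2)
    for (g in sps) {
      cg <- sweep(tr[gl == g, , drop = FALSE], 2,
                  colMeans(tr[gl == g, , drop = FALSE]))
      Sp <- Sp + t(cg) %*% cg
    }
    Sp <- Sp / (11 - length(sps))
    d2 <- sapply(mus, function(mu)
      drop(t(Y[i, ] - mu) %*% solve(Sp) %*% (Y[i, ] - mu)))
    naive[i] <- sps[which.min(d2)]
  }
  naive_correct <- sapply(sort(unique(lby)), function(g)
    sum(lby == g & naive == g))
  expect_equal(mine$per_species$assigned_correct, unname(naive_correct))

  # and with MASS::lda leave-one-out under equal priors on a larger instance
  set.seed(13)
  Z <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60) + 1.2, ncol = 2))
  lbz <- rep(c("a", "b"), each = 30)
  mine2 <- loo_classify_shape(list(scores = Z, labels = lbz))
  lda_cv <- MASS::lda(Z, grouping = lbz, prior = c(.5, .5), CV = TRUE)
  lda_correct <- sapply(c("a", "b"), function(g)
    sum(lbz == g & as.character(lda_cv$class) == g))
  expect_equal(mine2$per_species$assigned_correct, unname(lda_correct))
})

test_that("LOO size classification uses Gaussian likelihoods with priors", {
  # non-overlapping ranges: 100%
  set.seed(14)
  sizes <- c(runif(10, 1, 2), runif(10, 5, 6), runif(10, 9, 10))
  lb <- rep(c("a", "b", "c"), each = 10)
  expect_equal(loo_classify_size(sizes, lb)$total_accuracy_percent, 100)

  # two groups, equal sampling: agreement with an independent
  # likelihood-ratio oracle (equal priors cancel; with near-equal
  # variances the boundary sits at the midpoint of the held-out means)
  set.seed(15)
  s2 <- c(rnorm(40, 10, 1), rnorm(40, 14, 1))
  lb2 <- rep(c("a", "b"), each = 40)
  rep2 <- loo_classify_size(s2, lb2)
  naive <- character(80)
  for (i in 1:80) {
    ma <- mean(s2[-i][lb2[-i] == "a"]); va <- var(s2[-i][lb2[-i] == "a"])
    mb <- mean(s2[-i][lb2[-i] == "b"]); vb <- var(s2[-i][lb2[-i] == "b"])
    na_ <- sum(lb2[-i] == "a"); nb_ <- sum(lb2[-i] == "b")
    la <- log(na_ / 79) + dnorm(s2[i], ma, sqrt(va), log = TRUE)
    lbv <- log(nb_ / 79) + dnorm(s2[i], mb, sqrt(vb), log = TRUE)
    naive[i] <- if (la >= lbv) "a" else "b"
  }
  expect_equal(sum(diag(rep2$confusion)), sum(naive == lb2))
  # midpoint property: well-separated points classify to the nearer mean
  expect_equal(unname(rep2$per_species$assigned_correct),
               unname(sapply(c("a", "b"), function(g)
                 sum(naive == lb2 & lb2 == g))))

  # all species identically distributed, k groups: accuracy near chance
  set.seed(16)
  k <- 15
  s3 <- rnorm(45 * k, 10, 1)
  lb3 <- rep(sprintf("s%02d", 1:k), each = 45)
  acc <- loo_classify_size(s3, lb3)$total_accuracy_percent / 100
  expect_lt(abs(acc - 1 / k), 3 * sqrt((1 / k) * (1 - 1 / k) / (45 * k)) + 0.02)
})

test_that("chance-level shuffling drives shape accuracy to the chance criterion", {
  set.seed(17)
  X <- rbind(matrix(rnorm(100, 0, .1), ncol = 2),
             matrix(rnorm(100, 3, .1), ncol = 2),
             matrix(rnorm(100, 6, .1), ncol = 2))
  lb <- sample(rep(c("a", "b", "c"), each = 50))   # labels shuffled
  acc <- loo_classify_shape(list(scores = X, labels = lb))
  chance <- proportional_chance(c(50, 50, 50))
  se <- sqrt(chance * (1 - chance) / 150)
  expect_lt(abs(acc$total_accuracy_percent / 100 - chance), 4 * se + 0.02)
})

test_that("chance-adjusted accuracy reproduces the published quadruple", {
  ref <- tabanus_reference()
  expect_equal(adjusted_accuracy(0.9733, ref$n_landmark), 97)
  expect_equal(adjusted_accuracy(0.3208, ref$n_landmark), 27)
  expect_equal(adjusted_accuracy(0.9637, ref$n_outline), 96)
  expect_equal(adjusted_accuracy(0.2812, ref$n_outline), 23)
  # chance level maps to zero
  expect_equal(adjusted_accuracy(proportional_chance(ref$n_landmark),
                                 ref$n_landmark), 0)
  expect_error(adjusted_accuracy(0.5, 45), "single group")
})

test_that("LOO accuracy increases with between-species separation", {
  for (seed in 1:3) {
    accs <- sapply(c(0.002, 0.006, 0.018), function(sep) {
      ds <- cluster_dataset(k = 4, n_each = 10, sep = sep, within = 0.006,
                            seed = seed * 100)
      res <- analyze_wing_data(ds, "landmark", n_pcs = 10, permutation_B = 0)
      res$shape_report$total_accuracy_percent
    })
    expect_true(all(diff(accs) >= -1e-9))
  }
})
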