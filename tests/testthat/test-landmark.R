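test_that("centroid size matches closed forms and scales like a size", {
  sq <- rbind(c(.5, .5), c(-.5, .5), c(.5, -.5), c(-.5, -.5))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(sweep(sq, 2, c(10, 3), `+`)), sqrt(2),
               tolerance = 1e-12)
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))   # centroid (1, 4/3)
  expect_equal(centroid_size(tri), sqrt(150 / 9), tolerance = 1e-12)

  # invariance under rotation, linear scaling
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- matrix(rnorm(12), 6, 2)
    s <- exp(rnorm(1))
    moved <- cfg %*% rot2(runif(1, 0, 2 * pi)) * s + 7
    expect_equal(centroid_size(moved), s * centroid_size(cfg),
                 tolerance = 1e-9)
  }
  expect_error(centroid_size(matrix(1, 4, 2)), "coincident")
})

test_that("ordinary Procrustes recovers similarity transforms, no reflections", {
  a <- triangle()
  b <- a %*% rot2(pi / 2) * 2 + 5
  fit <- ordinary_procrustes(a, b)
  expect_lt(fit$residual, 1e-6)
  expect_equal(fit$fitted, a, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # mirror image of an asymmetric shape cannot be matched
  mirrored <- a %*% diag(c(-1, 1))
  expect_gt(ordinary_procrustes(a, mirrored)$residual, 0.1)

  expect_error(ordinary_procrustes(a, matrix(0:7, 4, 2)), "mismatch")
})

test_that("ordinary Procrustes attains the grid-search minimum", {
  set.seed(42)
  a <- matrix(rnorm(8), 4, 2)
  b <- matrix(rnorm(8), 4, 2)
  fit <- ordinary_procrustes(a, b)

  # independent oracle: enumerate rotations, optimal scale in closed form
  A <- sweep(a, 2, colMeans(a)); B <- sweep(b, 2, colMeans(b))
  ss <- sapply(seq(0, 2 * pi, length.out = 20000), function(ang) {
    BR <- B %*% rot2(ang)
    s <- max(0, sum(A * BR) / sum(B^2))
    sum((A - s * BR)^2)
  })
  expect_equal(fit$residual^2, min(ss), tolerance = 1e-4)
  expect_lte(fit$residual^2, min(ss) + 1e-8)
})

test_that("GPA aligns similarity-transformed copies to identical shapes", {
  arr <- similarity_family(triangle(), 8, seed = 2)
  fit <- gpa(arr)
  expect_true(fit$converged)
  for (i in 2:8)
    expect_lt(full_procrustes_distance(fit$aligned[, , i],
                                       fit$aligned[, , 1]), 1e-7)
  # centroid sizes recorded before scaling are those of the inputs
  expect_equal(fit$centroid_sizes,
               apply(arr, 3, centroid_size), tolerance = 1e-9)
})

test_that("GPA satisfies its geometric invariants", {
  set.seed(5)
  arr <- similarity_family(triangle(), 10, seed = 3, noise_sd = 0.05)
  fit <- gpa(arr, project_tangent = FALSE)

  # aligned shapes centred and unit centroid size (before tangent projection)
  for (i in 1:10) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-9)
    expect_equal(centroid_size(fit$aligned[, , i]), 1, tolerance = 1e-9)
  }
  # consensus equals mean of aligned shapes after the final iteration
  cons <- apply(fit$aligned, c(1, 2), mean)
  cons <- cons / sqrt(sum(sweep(cons, 2, colMeans(cons))^2))
  expect_equal(cons, fit$consensus, tolerance = 1e-6)

  # optimality: summed squared distance to the consensus is no larger than
  # around any single aligned specimen
  ssd <- function(ref) sum(apply(fit$aligned, 3, function(s)
    full_procrustes_distance(s, ref)^2))
  to_consensus <- ssd(fit$consensus)
  for (i in 1:10) expect_lte(to_consensus, ssd(fit$aligned[, , i]) + 1e-9)
})

test_that("GPA output is invariant to per-specimen similarity transforms and idempotent", {
  set.seed(6)
  base <- similarity_family(triangle(), 6, seed = 4, noise_sd = 0.08)
  fit1 <- gpa(base)
  # re-transform each input randomly; shapes are unchanged
  moved <- base
  for (i in 1:6) {
    moved[, , i] <- base[, , i] %*% rot2(runif(1, 0, 2 * pi)) *
      exp(runif(1, -.5, .5)) + 3
  }
  fit2 <- gpa(moved)
  for (i in 1:6)
    expect_lt(full_procrustes_distance(fit1$aligned[, , i],
                                       fit2$aligned[, , i]), 1e-6)

  # idempotence: re-running the alignment on aligned shapes changes nothing
  # beyond tol (checked pre-projection; projecting twice is not a no-op)
  fit1p <- gpa(base, project_tangent = FALSE)
  fit3 <- gpa(fit1p$aligned, project_tangent = FALSE)
  for (i in 1:6)
    expect_lt(full_procrustes_distance(fit3$aligned[, , i],
                                       fit1p$aligned[, , i]), 1e-6)
})

test_that("two-shape GPA consensus is equidistant from both shapes", {
  set.seed(7)
  arr <- array(c(triangle() + matrix(rnorm(6, sd = .1), 3, 2),
                 triangle() %*% rot2(1) * 2), c(3, 2, 2))
  fit <- gpa(arr)
  d1 <- full_procrustes_distance(fit$aligned[, , 1], fit$consensus)
  d2 <- full_procrustes_distance(fit$aligned[, , 2], fit$consensus)
  expect_equal(d1, d2, tolerance = 1e-7)
})

test_that("Procrustes ANOVA repeatability recovers known variance ratios", {
  # identical replicates: R = 1
  ds <- cluster_dataset(k = 2, n_each = 6, seed = 10)
  rep0 <- generate_replicates(ds, 0, seed = 11)
  expect_equal(length(rep0$records), 2L * length(ds$records))
  expect_equal(procrustes_anova_repeatability(rep0)$repeatability_fraction, 1)

  # 9:1 among:within variance -> R ~ 0.9 (ICC closed form), built directly:
  # equal-size specimens so mm noise maps to shape noise uniformly
  set.seed(12)
  tmpl <- template_wing_landmarks() * 10          # ~10 unit wings
  sd_a <- 0.09; sd_w <- 0.03                      # 9:1 variance ratio
  recs <- list()
  for (i in 1:200) {
    spec_shape <- tmpl + matrix(rnorm(42, sd = sd_a), 21, 2)
    for (r in 1:2) {
      noisy <- spec_shape + matrix(rnorm(42, sd = sd_w), 21, 2)
      ang <- runif(1, 0, 2 * pi)
      recs[[length(recs) + 1]] <- specimen_record(
        paste0("s", i), "sp1", landmarks = noisy %*% rot2(ang),
        replicate_index = r)
    }
  }
  rr <- procrustes_anova_repeatability(wing_dataset(recs))
  expect_equal(rr$repeatability_fraction, 0.9, tolerance = 0.05)
  expect_equal(rr$n_specimens, 200L)
  expect_equal(rr$n_replicates, 2L)

  # specimens without replication are rejected with their ids
  bad <- wing_dataset(c(rep0$records,
                        list(specimen_record("lonely", "x",
                                             landmarks = tmpl))))
  expect_error(procrustes_anova_repeatability(bad), "lonely")
})

test_that("noise-dominated replicates give near-zero repeatability", {
  set.seed(13)
  tmpl <- template_wing_landmarks() * 10
  recs <- list()
  for (i in 1:80) for (r in 1:2)
    recs[[length(recs) + 1]] <- specimen_record(
      paste0("s", i), "sp1",
      landmarks = tmpl + matrix(rnorm(42, sd = 0.05), 21, 2),
      replicate_index = r)
  rr <- procrustes_anova_repeatability(wing_dataset(recs))
  expect_lt(rr$repeatability_fraction, 0.2)
})

test_that("allometry r-squared matches its closed form", {
  # exact linear dependence
  set.seed(14)
  sz <- runif(50, 7, 14)
  a1 <- allometry_r2(2 * sz + 1, sz)
  expect_equal(a1$r_squared, 1, tolerance = 1e-12)
  expect_equal(a1$slope, 2, tolerance = 1e-9)
  expect_equal(a1$intercept, 1, tolerance = 1e-6)

  # independence: r^2 near zero at large n
  set.seed(15)
  sz <- runif(1000, 7, 14)
  expect_lt(allometry_r2(rnorm(1000), sz)$r_squared, 0.01)

  # r^2 ~ s^2 var(x) / (s^2 var(x) + var(e))
  set.seed(16)
  x <- rnorm(4000, sd = 2); e <- rnorm(4000, sd = 3); s <- 1.5
  expected <- s^2 * 4 / (s^2 * 4 + 9)
  expect_equal(allometry_r2(s * x + e, x)$r_squared, expected,
               tolerance = 0.05)

  expect_error(allometry_r2(rnorm(5), rep(3, 5)), "constant")
})
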