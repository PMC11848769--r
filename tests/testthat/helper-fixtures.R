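# Small fixtures shared across test files. Everything is built in code.

# a scalene triangle (no symmetry, convenient for alignment tests)
triangle <- function() rbind(c(0, 0), c(3, 0), c(1, 2))

# dataset of one base shape under random similarity transforms
similarity_family <- function(base, n, seed = 1, noise_sd = 0) {
  set.seed(seed)
  arr <- array(NA_real_, c(nrow(base), 2, n))
  for (i in seq_len(n)) {
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    s <- exp(runif(1, -1, 1))
    arr[, , i] <- (base + matrix(rnorm(2 * nrow(base), sd = noise_sd),
                                 nrow(base), 2)) %*% R * s +
      matrix(runif(2, -5, 5), nrow(base), 2, byrow = TRUE)
  }
  arr
}

# landmark wing_dataset of gaussian clusters in shape space
cluster_dataset <- function(k = 3, n_each = 8, sep = 0.02, within = 0.004,
                            seed = 1) {
  generate_landmark_dataset(suppressWarnings(synthetic_wing_spec(
    n_species = k, n_per_species = n_each,
    between_shape_sd = sep, within_shape_sd = within,
    size_means = seq(8, 12, length.out = k), seed = seed)))
}

# closed circle contour
circle_contour <- function(r = 1, n = 360, phase = 0) {
  t <- 2 * pi * (seq_len(n) - 1) / n + phase
  cbind(r * cos(t), r * sin(t))
}

rot2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

# full Procrustes distance between two configurations (independent helper)
full_procrustes_distance <- function(a, b) {
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  ca <- ca / sqrt(sum(ca^2)); cb <- cb / sqrt(sum(cb^2))
  sv <- svd(crossprod(ca, cb))
  d <- sign(det(sv$u %*% t(sv$v)))
  sqrt(max(0, 2 - 2 * sum(sv$d * c(1, d))))
}
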