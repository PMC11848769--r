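#' Principal components of shape variables
#'
#' Eigen-decomposition of the covariance of the centred shape variables
#' (Procrustes-aligned coordinates or normalized elliptic Fourier
#' coefficients); the leading scores are the final shape variables of the
#' downstream discriminant analysis.
#'
#' @param variables Numeric n x q matrix, one row per specimen.
#' @param labels Character vector of species labels, length n.
#' @param n_retain Number of components to keep (defaults used in the wing
#'   analyses: 24 for landmark shape, 23 for outline shape). Reduced with a
#'   warning when it exceeds the rank of the centred data.
#' @return Object of class `shape_space`: list with `scores` (n x k, centred),
#'   `explained` (per-PC variance fractions over all PCs), `rotation`,
#'   `center`, `n_retained`, `labels`, `ids`.
#' @export
shape_pca <- function(variables, labels, n_retain = min(dim(variables) - c(1L, 0L))) {
  variables <- as.matrix(variables)
  stopifnot(nrow(variables) >= 2L, length(labels) == nrow(variables))
  pc <- prcomp(variables, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > ev[1L] * 1e-10)
  if (n_retain > rank) {
    warning("n_retain = ", n_retain, " exceeds data rank ", rank,
            "; reduced to ", rank)
    n_retain <- rank
  }
  structure(list(scores = pc$x[, seq_len(n_retain), drop = FALSE],
                 explained = ev / sum(ev),
                 rotation = pc$rotation[, seq_len(n_retain), drop = FALSE],
                 center = pc$center, n_retained = as.integer(n_retain),
                 labels = as.character(labels),
                 ids = rownames(variables)),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("shape_space: ", nrow(x$scores), " specimens x ", x$n_retained,
      " PCs (", round(100 * sum(x$explained[seq_len(x$n_retained)]), 1),
      "% of variance), ", length(unique(x$labels)), " species\n", sep = "")
  invisible(x)
}

group_stats <- function(scores, labels) {
  groups <- split(seq_len(nrow(scores)), labels)
  k <- length(groups)
  means <- do.call(rbind, lapply(groups, function(g)
    colMeans(scores[g, , drop = FALSE])))
  W <- matrix(0, ncol(scores), ncol(scores))
  for (g in groups) {
    cg <- sweep(scores[g, , drop = FALSE], 2L,
                colMeans(scores[g, , drop = FALSE]))
    W <- W + crossprod(cg)
  }
  W <- W / (nrow(scores) - k)
  list(means = means, pooled_cov = W, groups = groups,
       n = lengths(groups), k = k)
}

regularize_if_singular <- function(S) {
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || rcond_est(S) < 1e-12) {
    warning("singular pooled covariance; ridge-regularized")
    S <- S + diag(1e-8 * mean(diag(S)) + 1e-300, nrow(S))
  }
  S
}

rcond_est <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Canonical discriminant analysis
#'
#' Canonical variates of the between-group covariance relative to the pooled
#' within-group covariance: axes successively maximize group separation
#' scaled by within-group variation. Specimen projections on the first two
#' axes give the factor map used to visualize species separation.
#'
#' @param space A `shape_space` from [shape_pca()] (or any list with
#'   `scores` and `labels`).
#' @return Object of class `discriminant_model`: list with `group_means`,
#'   `pooled_covariance`, `axes` (columns = discriminant axes in score
#'   space), `df_variance_fractions`, `factor_map` (n x n_axes specimen
#'   coordinates), `labels`, `eigenvalues`.
#' @export
discriminant_analysis <- function(space) {
  scores <- space$scores; labels <- space$labels
  require_two_species(labels)
  gs <- group_stats(scores, labels)
  if (any(gs$n < 2L)) stop("every species needs >= 2 specimens")
  W <- regularize_if_singular(gs$pooled_cov)
  grand <- colMeans(scores)
  B <- matrix(0, ncol(scores), ncol(scores))
  for (j in seq_len(gs$k)) {
    dmu <- gs$means[j, ] - grand
    B <- B + gs$n[j] * tcrossprod(dmu)
  }
  B <- B / (gs$k - 1L)

  # generalized symmetric eigenproblem B v = lambda W v via Cholesky
  L <- chol(W)                         # W = L'L
  Linv <- backsolve(L, diag(ncol(W)))
  M <- t(Linv) %*% B %*% Linv
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(gs$k - 1L, ncol(scores))
  axes <- Linv %*% eg$vectors[, seq_len(n_axes), drop = FALSE]
  # unit within-group variance along each axis (standard CVA scaling)
  axes <- sweep(axes, 2L, sqrt(colSums((L %*% axes)^2)), `/`)
  lambda <- pmax(eg$values[seq_len(n_axes)], 0)

  structure(list(group_means = gs$means, pooled_covariance = gs$pooled_cov,
                 axes = axes,
                 df_variance_fractions = if (sum(lambda) > 0)
                   lambda / sum(lambda) else rep(1 / n_axes, n_axes),
                 factor_map = sweep(scores, 2L, grand) %*% axes,
                 eigenvalues = lambda, labels = labels),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  fr <- round(100 * x$df_variance_fractions, 1)
  cat("discriminant_model: ", nrow(x$group_means), " species, ",
      length(fr), " axes; DF1 = ", fr[1L], "%",
      if (length(fr) > 1L) paste0(", DF2 = ", fr[2L], "%"), "\n", sep = "")
  invisible(x)
}

#' Pairwise Mahalanobis distance matrix between species
#'
#' `D(i, j) = sqrt((mu_i - mu_j)' S^-1 (mu_i - mu_j))` with `S` the pooled
#' within-group covariance — between-group mean distances scaled by the
#' common within-group variation. Invariant under any invertible affine map
#' of the score space.
#'
#' @inheritParams discriminant_analysis
#' @return k x k symmetric matrix with zero diagonal, dimnames = species.
#' @export
mahalanobis_matrix <- function(space) {
  scores <- space$scores; labels <- space$labels
  require_two_species(labels)
  gs <- group_stats(scores, labels)
  S <- regularize_if_singular(gs$pooled_cov)
  k <- gs$k
  D <- matrix(0, k, k, dimnames = list(rownames(gs$means), rownames(gs$means)))
  Sinv <- solve(S)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    dmu <- gs$means[i, ] - gs$means[j, ]
    D[i, j] <- D[j, i] <- sqrt(max(0, dmu %*% Sinv %*% dmu))
  }
  D
}

#' Pairwise permutation tests with Bonferroni correction
#'
#' For every species pair, compares the observed statistic (absolute mean
#' difference of a scalar, or the squared Mahalanobis distance of vector
#' scores) with its distribution under `B` random relabelings of the pair's
#' pooled specimens. The p-value uses the add-one estimator
#' `p = (1 + #(permuted >= observed)) / (B + 1)`, so `p >= 1/(B+1)` always.
#' Significance is declared at the Bonferroni-corrected threshold
#' `alpha / n_pairs`.
#'
#' @param values Numeric vector (statistic `"mean_difference"`) or matrix
#'   (statistic `"mahalanobis"`), one row/element per specimen.
#' @param labels Species labels.
#' @param statistic `"mean_difference"` or `"mahalanobis"`.
#' @param B Number of permutation replicates (default 1000).
#' @param alpha Uncorrected significance threshold (default 0.05).
#' @param seed Optional integer seed for reproducible permutations.
#' @return Object of class `permutation_test_result`: data frame `pairs`
#'   with columns `species_1`, `species_2`, `observed`, `p_value`,
#'   `significant`; plus attributes `bonferroni_alpha`, `replicates`.
#' @export
permutation_test <- function(values, labels,
                             statistic = c("mean_difference", "mahalanobis"),
                             B = 1000, alpha = 0.05, seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(B >= 1)
  labels <- as.character(labels)
  values <- if (statistic == "mean_difference") as.numeric(values)
            else as.matrix(values)
  n_obs <- if (is.matrix(values)) nrow(values) else length(values)
  stopifnot(n_obs == length(labels))
  sp <- sort(unique(labels))
  require_two_species(labels)
  pairs <- utils::combn(sp, 2L)
  n_pairs <- ncol(pairs)
  thr <- alpha / n_pairs

  stat_fun <- if (statistic == "mean_difference") {
    function(v, g1) abs(mean(v[g1]) - mean(v[!g1]))
  } else {
    function(v, g1) {
      m1 <- colMeans(v[g1, , drop = FALSE])
      m2 <- colMeans(v[!g1, , drop = FALSE])
      c1 <- sweep(v[g1, , drop = FALSE], 2L, m1)
      c2 <- sweep(v[!g1, , drop = FALSE], 2L, m2)
      S <- (crossprod(c1) + crossprod(c2)) / (nrow(v) - 2L)
      S <- S + diag(1e-10 * mean(diag(S)) + 1e-300, ncol(v))
      dmu <- m1 - m2
      as.numeric(dmu %*% solve(S, dmu))
    }
  }

  res <- data.frame(species_1 = pairs[1L, ], species_2 = pairs[2L, ],
                    observed = NA_real_, p_value = NA_real_,
                    significant = NA)
  for (q in seq_len(n_pairs)) {
    in_pair <- labels %in% pairs[, q]
    v <- if (is.matrix(values)) values[in_pair, , drop = FALSE]
         else values[in_pair]
    g1 <- labels[in_pair] == pairs[1L, q]
    if (statistic == "mahalanobis" && (sum(g1) < 2L || sum(!g1) < 2L)) {
      warning("pair ", pairs[1L, q], " / ", pairs[2L, q],
              " skipped: group with < 2 specimens")
      next
    }
    obs <- stat_fun(v, g1)
    m <- sum(g1); nn <- length(g1)
    exceed <- 0L
    for (b in seq_len(B)) {
      perm <- logical(nn)
      perm[sample.int(nn, m)] <- TRUE
      if (stat_fun(v, perm) >= obs - 1e-12) exceed <- exceed + 1L
    }
    res$observed[q] <- obs
    res$p_value[q] <- (1 + exceed) / (B + 1)
    res$significant[q] <- res$p_value[q] <= thr
  }
  structure(res, bonferroni_alpha = thr, replicates = as.integer(B),
            class = c("permutation_test_result", "data.frame"))
}

#' Leave-one-out classification by Mahalanobis distance (shape)
#'
#' Each specimen is removed, the species means and pooled within-group
#' covariance are recomputed from the remaining specimens, and the held-out
#' specimen is assigned to the species with the smallest Mahalanobis
#' distance. Ties go to the first species in label order and are counted.
#'
#' @inheritParams discriminant_analysis
#' @return A `classification_report`; see [classification_report()].
#' @export
loo_classify_shape <- function(space) {
  scores <- space$scores; labels <- as.character(space$labels)
  sp <- sort(unique(labels))
  require_two_species(labels)
  if (any(table(labels) < 3L)) stop("every species needs >= 3 specimens")
  n <- nrow(scores)
  assigned <- character(n)
  ties <- 0L
  for (i in seq_len(n)) {
    sc <- scores[-i, , drop = FALSE]; lb <- labels[-i]
    gs <- group_stats(sc, lb)
    S <- regularize_if_singular(gs$pooled_cov)
    d2 <- mahalanobis(gs$means, scores[i, ], S)   # one distance per species
    best <- which(d2 <= min(d2) + 1e-12)
    if (length(best) > 1L) ties <- ties + 1L
    assigned[i] <- rownames(gs$means)[best[1L]]
  }
  classification_report(labels, assigned, method = "shape_mahalanobis",
                        ties = ties)
}

#' Leave-one-out classification by Gaussian maximum likelihood (size)
#'
#' Each specimen is removed and assigned to the species maximizing the
#' univariate normal likelihood of its size under the species' held-out
#' mean and variance, weighted by the species' relative frequency as the
#' prior (so unbalanced sampling is accounted for).
#'
#' @param sizes Positive per-specimen size values (centroid size or cell
#'   perimeter, mm).
#' @param labels Species labels.
#' @return A `classification_report`.
#' @export
loo_classify_size <- function(sizes, labels) {
  sizes <- as.numeric(sizes); labels <- as.character(labels)
  stopifnot(length(sizes) == length(labels), all(sizes > 0))
  require_two_species(labels)
  if (any(table(labels) < 3L)) stop("every species needs >= 3 specimens")
  sp <- sort(unique(labels))
  n <- length(sizes)
  assigned <- character(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    s <- sizes[-i]; lb <- labels[-i]
    ll <- vapply(sp, function(g) {
      x <- s[lb == g]
      v <- var(x)
      if (!is.finite(v) || v <= 0) {
        if (!warned) { warning("zero within-species size variance; ",
                               "epsilon floor applied"); warned <<- TRUE }
        v <- 1e-12 * mean(x)^2
      }
      log(length(x) / (n - 1L)) + dnorm(sizes[i], mean(x), sqrt(v), log = TRUE)
    }, numeric(1))
    assigned[i] <- sp[which.max(ll)]
  }
  classification_report(labels, assigned, method = "size_ml")
}

#' Classification report
#'
#' Tallies leave-one-out assignments into the per-species and total
#' accuracies, plus the chance-adjusted total accuracy (see
#' [adjusted_accuracy()]).
#'
#' @param labels True species labels.
#' @param assigned Assigned species labels (same length).
#' @param method Label recorded in the report.
#' @param ties Number of tied assignments encountered.
#' @return Object of class `classification_report`: list with `per_species`
#'   (data frame: species, n, assigned_correct, accuracy_percent),
#'   `total_accuracy_percent` (2 decimals), `adjusted_accuracy_percent`
#'   (integer), `confusion` (table), `method`, `ties`.
#' @export
classification_report <- function(labels, assigned, method = "custom",
                                  ties = 0L) {
  stopifnot(length(labels) == length(assigned))
  sp <- sort(unique(labels))
  correct <- vapply(sp, function(g)
    sum(labels == g & assigned == g), integer(1))
  nsp <- vapply(sp, function(g) sum(labels == g), integer(1))
  per <- data.frame(species = sp, n = nsp, assigned_correct = correct,
                    accuracy_percent = round(100 * correct / nsp, 2L),
                    row.names = NULL)
  total <- sum(correct) / sum(nsp)
  structure(list(per_species = per,
                 total_accuracy_percent = round(100 * total, 2L),
                 adjusted_accuracy_percent =
                   adjusted_accuracy(total, nsp),
                 confusion = table(true = labels,
                                   assigned = factor(assigned, levels = sp)),
                 method = method, ties = as.integer(ties)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report (", x$method, "):\n", sep = "")
  print(x$per_species, row.names = FALSE)
  cat("Total accuracy: ", sprintf("%.2f", x$total_accuracy_percent),
      "%  (chance-adjusted: ", x$adjusted_accuracy_percent, "%)\n", sep = "")
  invisible(x)
}

#' Proportional chance criterion
#'
#' Expected accuracy of random assignment that respects the observed group
#' frequencies: `sum((n_i / N)^2)`.
#'
#' @param group_sizes Positive per-species sample sizes.
#' @return Fraction in (0, 1].
#' @export
proportional_chance <- function(group_sizes) {
  group_sizes <- as.numeric(group_sizes)
  stopifnot(all(group_sizes > 0))
  p <- group_sizes / sum(group_sizes)
  sum(p^2)
}

#' Chance-adjusted classification accuracy
#'
#' Corrects a raw leave-one-out accuracy for the assignments that random
#' labelling would get right, using the proportional chance criterion:
#' `adjusted = (A_obs - A_chance) / (1 - A_chance)` with
#' `A_chance = sum((n_i / N)^2)`. Reported as a percentage rounded to the
#' nearest integer, the conventional presentation.
#'
#' @param accuracy Raw accuracy as a fraction in `[0, 1]`.
#' @param group_sizes Per-species sample sizes.
#' @return Integer percent (can be negative if below chance).
#' @export
adjusted_accuracy <- function(accuracy, group_sizes) {
  stopifnot(length(accuracy) == 1L, accuracy >= 0, accuracy <= 1)
  a_chance <- proportional_chance(group_sizes)
  if (a_chance >= 1) stop("single group: chance adjustment undefined")
  round_half_up(100 * (accuracy - a_chance) / (1 - a_chance))
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
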