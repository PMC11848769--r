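#' Centroid size of a landmark configuration
#'
#' The standard isometric size measure in geometric morphometrics: the square
#' root of the summed squared distances of the landmarks from their centroid.
#' Invariant to rotation and translation; scales linearly with the
#' configuration.
#'
#' @param config Numeric p x 2 matrix of landmark coordinates (p >= 3).
#' @return Positive scalar, in the coordinate unit (mm).
#' @export
centroid_size <- function(config) {
  config <- as_coord_matrix(config, "landmarks", "<config>")
  if (nrow(config) < 3L) stop("need >= 3 landmarks")
  centered <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincident")
  cs
}

#' Ordinary Procrustes superimposition of one configuration onto another
#'
#' Finds the similarity transform (rotation, uniform scale, translation;
#' reflections excluded) of `b` that minimizes the summed squared distances
#' to `a`, by the standard singular-value-decomposition solution.
#'
#' @param a,b Numeric p x 2 matrices with equal landmark counts.
#' @param scale Estimate the optimal scale (default) or fix it to 1.
#' @return List with `rotation` (2 x 2, det +1), `scale`, `translation`
#'   (length-2; the fit is `b %*% rotation * scale + translation`),
#'   `residual` (square root of the minimized sum of squares) and
#'   `fitted` (the transformed `b`).
#' @export
ordinary_procrustes <- function(a, b, scale = TRUE) {
  a <- as_coord_matrix(a, "landmarks", "a")
  b <- as_coord_matrix(b, "landmarks", "b")
  if (nrow(a) != nrow(b))
    stop("landmark count mismatch: ", nrow(a), " vs ", nrow(b))
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  if (sum(A^2) == 0 || sum(B^2) == 0) stop("degenerate configuration")
  sv <- svd(crossprod(A, B))          # M = A'B ; rotation maps B onto A
  d <- sign(det(sv$u %*% t(sv$v)))    # exclude reflections
  S <- diag(c(1, d))
  R <- sv$v %*% S %*% t(sv$u)
  traceRM <- sum(diag(S) * sv$d)
  s <- if (scale) traceRM / sum(B^2) else 1
  ss <- if (scale) sum(A^2) - traceRM^2 / sum(B^2)
        else sum(A^2) + sum(B^2) - 2 * traceRM
  fitted <- sweep(B %*% R * s, 2L, ca, `+`)
  list(rotation = R, scale = s,
       translation = as.vector(ca - (cb %*% R) * s),
       residual = sqrt(max(0, ss)), fitted = fitted)
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes all configurations onto an evolving consensus:
#' each shape is centred, scaled to unit centroid size, and rotated onto the
#' current consensus; the consensus is re-estimated as the mean of the
#' aligned shapes (re-normalized to unit size) until its root-mean-square
#' change falls below `tol`. Aligned shapes are then orthogonally projected
#' to the tangent space at the consensus, where ordinary multivariate
#' statistics apply. Centroid sizes are recorded before scaling.
#'
#' @param dataset A [wing_dataset()] with landmark records, or a p x 2 x n
#'   array.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum number of alignment sweeps.
#' @param project_tangent Orthogonally project aligned shapes to the tangent
#'   space at the consensus (default TRUE).
#' @return Object of class `procrustes_fit`: list with `aligned` (p x 2 x n
#'   array), `consensus` (p x 2), `centroid_sizes` (mm), `species`, `ids`,
#'   `replicate_index`, `iterations_used`, `converged`.
#' @export
gpa <- function(dataset, tol = 1e-8, max_iter = 100, project_tangent = TRUE) {
  if (inherits(dataset, "wing_dataset")) {
    la <- landmark_array(dataset)
  } else {
    stopifnot(is.array(dataset), length(dim(dataset)) == 3L)
    la <- list(coords = dataset, species = rep(NA_character_, dim(dataset)[3L]),
               ids = as.character(seq_len(dim(dataset)[3L])),
               replicate_index = rep(NA_integer_, dim(dataset)[3L]))
  }
  coords <- la$coords
  n <- dim(coords)[3L]; p <- dim(coords)[1L]
  if (n < 2L) stop("GPA needs >= 2 specimens")

  cs <- numeric(n)
  X <- coords
  for (i in seq_len(n)) {
    cent <- sweep(coords[, , i], 2L, colMeans(coords[, , i]))
    cs[i] <- sqrt(sum(cent^2))
    if (cs[i] == 0) stop("degenerate configuration: specimen ", la$ids[i])
    if (qr(cent)$rank < 2L)
      warning("collinear landmark configuration: specimen ", la$ids[i])
    X[, , i] <- cent / cs[i]
  }

  consensus <- X[, , 1L]
  consensus <- consensus / sqrt(sum(consensus^2))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      sv <- svd(crossprod(consensus, X[, , i]))
      d <- sign(det(sv$u %*% t(sv$v)))
      R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
      X[, , i] <- X[, , i] %*% R
    }
    new_cons <- apply(X, c(1L, 2L), mean)
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")

  if (project_tangent) {
    cvec <- as.vector(consensus)                 # unit norm
    for (i in seq_len(n)) {
      xv <- as.vector(X[, , i])
      X[, , i] <- X[, , i] - sum(xv * cvec) * consensus + consensus
    }
  }

  structure(list(aligned = X, consensus = consensus, centroid_sizes = cs,
                 species = la$species, ids = la$ids,
                 replicate_index = la$replicate_index,
                 iterations_used = iter, converged = converged,
                 tangent_projected = project_tangent),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("procrustes_fit: ", dim(x$aligned)[3L], " specimens, ",
      dim(x$aligned)[1L], " landmarks; ",
      x$iterations_used, " iterations (converged: ", x$converged, ")\n",
      sep = "")
  invisible(x)
}

#' Flatten aligned shapes to a specimen-by-variable matrix
#'
#' Rows are specimens, columns interleave x and y per landmark — the shape
#' variables that feed [shape_pca()].
#'
#' @param fit A `procrustes_fit` from [gpa()].
#' @return Numeric n x 2p matrix with specimen ids as row names.
#' @export
shape_variables <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  m <- t(apply(fit$aligned, 3L, function(s) as.vector(t(s))))
  rownames(m) <- fit$ids
  m
}

#' Digitization repeatability by Procrustes ANOVA
#'
#' All replicates are aligned in a single GPA; the aligned coordinates are
#' then decomposed into among-specimen and within-specimen (digitization
#' error) variance, with sums of squares pooled over all landmark
#' coordinates (Goodall-style). Repeatability is the intraclass-correlation
#' estimate
#' `R = (MS_among - MS_within) / (MS_among + (m - 1) * MS_within)`,
#' the fraction of shape variance attributable to real specimen differences
#' rather than digitization; negative estimates are clamped to zero.
#'
#' @param dataset A [wing_dataset()] in which every specimen id occurs with
#'   `m >= 2` replicate records (`replicate_index` populated).
#' @param ... Passed to [gpa()].
#' @return Object of class `repeatability_result`: list with
#'   `repeatability_fraction`, `ms_among`, `ms_within`, `n_specimens`,
#'   `n_replicates`.
#' @export
procrustes_anova_repeatability <- function(dataset, ...) {
  fit <- gpa(dataset, ...)
  ids <- fit$ids
  tab <- table(ids)
  bad <- names(tab)[tab < 2L]
  if (length(bad))
    stop("specimens with < 2 replicates: ", paste(head(bad, 10L), collapse = ", "))
  m <- unique(as.integer(tab))
  if (length(m) > 1L)
    stop("unbalanced replicate counts (", paste(m, collapse = ", "),
         "); the ANOVA expects equal replication")
  n <- length(tab)

  V <- shape_variables(fit)
  grand <- colMeans(V)
  groups <- split(seq_along(ids), ids)
  ss_among <- 0; ss_within <- 0
  for (g in groups) {
    mu <- colMeans(V[g, , drop = FALSE])
    ss_among <- ss_among + m * sum((mu - grand)^2)
    ss_within <- ss_within + sum(sweep(V[g, , drop = FALSE], 2L, mu)^2)
  }
  q <- ncol(V)
  ms_among <- ss_among / ((n - 1) * q)
  ms_within <- ss_within / (n * (m - 1) * q)
  R <- (ms_among - ms_within) / (ms_among + (m - 1) * ms_within)
  structure(list(repeatability_fraction = min(1, max(0, R)),
                 ms_among = ms_among, ms_within = ms_within,
                 n_specimens = n, n_replicates = m),
            class = "repeatability_result")
}

#' Allometry: regression of the first discriminant factor on size
#'
#' Ordinary least squares of DF1 scores on centroid size; the coefficient of
#' determination summarizes how much discriminable shape variation tracks
#' size.
#'
#' @param df1_scores Per-specimen first-discriminant-factor scores.
#' @param sizes Per-specimen centroid sizes (mm), non-constant.
#' @return List with `r_squared`, `slope`, `intercept`, class
#'   `allometry_result`.
#' @export
allometry_r2 <- function(df1_scores, sizes) {
  stopifnot(length(df1_scores) == length(sizes), length(sizes) >= 3L)
  if (sd(sizes) == 0) stop("sizes are constant; regression is degenerate")
  fit <- lm(df1_scores ~ sizes)
  structure(list(r_squared = unname(cor(df1_scores, sizes)^2),
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L])),
            class = "allometry_result")
}
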