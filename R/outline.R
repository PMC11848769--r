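#' Perimeter of a closed contour
#'
#' Sum of consecutive segment lengths, including the closing segment from
#' the last point back to the first.
#'
#' @param contour Numeric m x 2 matrix (m >= 3) of ordered boundary points.
#' @return Positive scalar, in the coordinate unit (mm).
#' @export
contour_perimeter <- function(contour) {
  contour <- as_coord_matrix(contour, "contour", "<contour>")
  if (nrow(contour) < 3L) stop("contour needs >= 3 points")
  d <- diff(rbind(contour, contour[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

signed_area <- function(contour) {
  x <- contour[, 1L]; y <- contour[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Resample a closed contour to equally spaced points
#'
#' Places `n_points` pseudo-landmarks at equal arc-length spacing along the
#' closed polygon, starting at the original first point. Orientation is
#' normalized to counter-clockwise (positive signed area); a clockwise input
#' is reversed (keeping the same starting point) before spacing.
#'
#' @param contour Numeric m x 2 matrix.
#' @param n_points Number of output points (>= 8).
#' @return n_points x 2 matrix, counter-clockwise.
#' @export
resample_contour <- function(contour, n_points = 300) {
  contour <- as_coord_matrix(contour, "contour", "<contour>")
  if (n_points < 8L) stop("n_points must be >= 8")
  if (nrow(contour) < 3L) stop("contour needs >= 3 points")
  if (signed_area(contour) < 0)
    contour <- contour[c(1L, nrow(contour):2L), , drop = FALSE]
  closed <- rbind(contour, contour[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  t_cum <- c(0, cumsum(seg))
  total <- t_cum[length(t_cum)]
  target <- total * (seq_len(n_points) - 1L) / n_points
  idx <- findInterval(target, t_cum, rightmost.closed = TRUE)
  frac <- (target - t_cum[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
}

#' Elliptic Fourier decomposition of a closed contour
#'
#' Computes elliptic Fourier coefficients (the Kuhl–Giardina formulation)
#' from the piecewise-linear parameterization of the contour by cumulative
#' chord length. Harmonic `n` contributes the quadruple `(a_n, b_n)` for
#' x(t) and `(c_n, d_n)` for y(t); `A0`/`C0` carry the contour centroid.
#' Coefficients are returned unnormalized (size, rotation and starting
#' point still encoded); see [efa_normalize()].
#'
#' @param contour Numeric m x 2 matrix, ideally arc-length resampled and
#'   counter-clockwise (use [resample_contour()]).
#' @param n_harmonics Number of harmonics, between 1 and `floor(m / 2)`.
#' @return Object of class `efa_harmonics`: list with `coefficients`
#'   (n_harmonics x 4 matrix, columns a, b, c, d), `dc` (A0, C0),
#'   `normalized = FALSE`, `size_scalar = NA`, `perimeter` of the input.
#' @export
efa <- function(contour, n_harmonics = 20) {
  contour <- as_coord_matrix(contour, "contour", "<contour>")
  m <- nrow(contour)
  if (n_harmonics < 1L || n_harmonics > floor(m / 2))
    stop("n_harmonics must be in [1, ", floor(m / 2), "] for ", m, " points")
  closed <- rbind(contour, contour[1L, , drop = FALSE])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  if (any(dt == 0)) {
    keep <- dt > 0
    dxy <- dxy[keep, , drop = FALSE]; dt <- dt[keep]
  }
  t1 <- c(0, cumsum(dt))       # parameter at segment endpoints
  T_ <- t1[length(t1)]
  t0 <- t1[-length(t1)]; t1 <- t1[-1L]

  H <- n_harmonics
  coefs <- matrix(0, H, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(H)) {
    w <- 2 * pi * n / T_
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    k <- T_ / (2 * pi^2 * n^2)
    coefs[n, "a"] <- k * sum(dxy[, 1L] / dt * dcos)
    coefs[n, "b"] <- k * sum(dxy[, 1L] / dt * dsin)
    coefs[n, "c"] <- k * sum(dxy[, 2L] / dt * dcos)
    coefs[n, "d"] <- k * sum(dxy[, 2L] / dt * dsin)
  }

  # DC terms: mean of x(t), y(t) over one period of the piecewise-linear path
  xi <- cumsum(c(0, dxy[-nrow(dxy), 1L]))
  yi <- cumsum(c(0, dxy[-nrow(dxy), 2L]))
  A0 <- contour[1L, 1L] + sum(dxy[, 1L] / (2 * dt) * (t1^2 - t0^2) / T_ +
                              (xi - dxy[, 1L] / dt * t0) * dt / T_)
  C0 <- contour[1L, 2L] + sum(dxy[, 2L] / (2 * dt) * (t1^2 - t0^2) / T_ +
                              (yi - dxy[, 2L] / dt * t0) * dt / T_)

  structure(list(coefficients = coefs, dc = c(A0 = A0, C0 = C0),
                 n_harmonics = H, normalized = FALSE, size_scalar = NA_real_,
                 perimeter = T_),
            class = "efa_harmonics")
}

#' @export
print.efa_harmonics <- function(x, ...) {
  cat("efa_harmonics: ", x$n_harmonics, " harmonics, ",
      if (x$normalized) "normalized" else "unnormalized",
      if (x$normalized) paste0(" (size scalar ", signif(x$size_scalar, 6), ")"),
      "\n", sep = "")
  invisible(x)
}

#' First-harmonic normalization of elliptic Fourier coefficients
#'
#' Standardizes coefficients so that they are invariant to the contour's
#' size, rotation, and traversal starting point: the parameter origin is
#' shifted to a vertex of the first-harmonic ellipse's major axis, the
#' coordinate frame is rotated to align that major axis with x, and all
#' coefficients are divided by the semi-major magnitude (recorded as
#' `size_scalar`). After normalization `a_1 = 1` and `b_1 = c_1 = 0`; shape
#' information lives in `d_1` (first-ellipse aspect ratio) and the higher
#' harmonics.
#'
#' The two major-axis vertices leave a residual two-fold ambiguity that
#' flips the sign of even harmonics. It is resolved intrinsically: the
#' candidate whose first nonzero even-harmonic coefficient is positive is
#' returned, unless `align_to` supplies a reference coefficient matrix, in
#' which case the candidate with the larger dot product onto the reference
#' is chosen (use this to make signs consistent across a dataset).
#'
#' @param h An unnormalized `efa_harmonics` from [efa()]. A normalized input
#'   is returned unchanged (the operation is idempotent).
#' @param align_to Optional reference coefficient matrix (same dimensions).
#' @return A normalized `efa_harmonics`; `dc` is zeroed (position removed).
#' @export
efa_normalize <- function(h, align_to = NULL) {
  stopifnot(inherits(h, "efa_harmonics"))
  if (isTRUE(h$normalized)) return(h)
  C1 <- h$coefficients[1L, ]
  a1 <- C1["a"]; b1 <- C1["b"]; c1 <- C1["c"]; d1 <- C1["d"]
  if (a1^2 + b1^2 + c1^2 + d1^2 < .Machine$double.eps)
    stop("degenerate first harmonic; cannot normalize")

  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  # theta locates an axis of the first-harmonic ellipse; probing the four
  # quarter turns finds the two major-axis vertices regardless of sign
  # conventions, including the circular case where the axis is undefined
  cand <- lapply(theta + c(0, pi / 2, pi, 3 * pi / 2), function(th) {
    rotated <- rotate_start(h$coefficients, th)
    a1s <- rotated[1L, "a"]; c1s <- rotated[1L, "c"]
    E <- sqrt(a1s^2 + c1s^2)
    if (E < .Machine$double.eps) return(NULL)
    psi <- atan2(c1s, a1s)
    out <- rotate_frame(rotated, -psi) / E
    list(coefs = out, E = E)
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) stop("degenerate first harmonic; cannot normalize")
  Emax <- max(vapply(cand, `[[`, numeric(1), "E"))
  cand <- Filter(function(cc) cc$E >= Emax * (1 - 1e-9), cand)

  pick <- if (length(cand) == 1L) 1L
    else if (!is.null(align_to)) {
      which.max(vapply(cand, function(cc) sum(cc$coefs * align_to), numeric(1)))
    } else {
      # intrinsic tie-break: first nonzero even-harmonic coefficient positive
      scores <- vapply(cand, function(cc) {
        v <- as.vector(t(cc$coefs[seq(2L, nrow(cc$coefs), by = 2L), ,
                                  drop = FALSE]))
        nz <- which(abs(v) > 1e-9)
        if (length(nz)) sign(v[nz[1L]]) else 1
      }, numeric(1))
      which.max(scores)
    }
  chosen <- cand[[pick]]
  structure(list(coefficients = chosen$coefs, dc = c(A0 = 0, C0 = 0),
                 n_harmonics = h$n_harmonics, normalized = TRUE,
                 size_scalar = unname(chosen$E), perimeter = h$perimeter),
            class = "efa_harmonics")
}

# shift the traversal starting point by parameter angle theta
rotate_start <- function(coefs, theta) {
  out <- coefs
  for (n in seq_len(nrow(coefs))) {
    cn <- cos(n * theta); sn <- sin(n * theta)
    M <- matrix(c(cn, sn, -sn, cn), 2L, 2L)   # acts on each (cos, sin) pair
    out[n, c("a", "b")] <- coefs[n, c("a", "b")] %*% M
    out[n, c("c", "d")] <- coefs[n, c("c", "d")] %*% M
  }
  out
}

# rotate the coordinate frame by angle psi
rotate_frame <- function(coefs, psi) {
  cp <- cos(psi); sp <- sin(psi)
  rbind_a <- cp * coefs[, "a"] - sp * coefs[, "c"]
  rbind_b <- cp * coefs[, "b"] - sp * coefs[, "d"]
  rbind_c <- sp * coefs[, "a"] + cp * coefs[, "c"]
  rbind_d <- sp * coefs[, "b"] + cp * coefs[, "d"]
  out <- cbind(a = rbind_a, b = rbind_b, c = rbind_c, d = rbind_d)
  out
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values.
#'
#' @param h An `efa_harmonics`.
#' @param n_points Number of points to evaluate.
#' @param n_harmonics Optionally truncate to the first so-many harmonics.
#' @return n_points x 2 coordinate matrix.
#' @export
efa_reconstruct <- function(h, n_points = 300, n_harmonics = h$n_harmonics) {
  stopifnot(inherits(h, "efa_harmonics"),
            n_harmonics >= 1L, n_harmonics <= h$n_harmonics)
  t <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  x <- rep(h$dc[["A0"]], n_points)
  y <- rep(h$dc[["C0"]], n_points)
  for (n in seq_len(n_harmonics)) {
    cn <- cos(n * t); sn <- sin(n * t)
    x <- x + h$coefficients[n, "a"] * cn + h$coefficients[n, "b"] * sn
    y <- y + h$coefficients[n, "c"] * cn + h$coefficients[n, "d"] * sn
  }
  cbind(x, y)
}

#' Harmonic power and the cumulative-power cutoff
#'
#' The power of harmonic `n` is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`.
#' `harmonic_power_cutoff` returns the smallest number of leading harmonics
#' whose cumulative power reaches `threshold` of the total — the usual rule
#' for choosing how many harmonics to keep.
#'
#' @param h An `efa_harmonics`.
#' @param threshold Fraction of total power in (0, 1].
#' @return Integer harmonic count.
#' @export
harmonic_power_cutoff <- function(h, threshold = 0.999) {
  stopifnot(inherits(h, "efa_harmonics"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  pow <- rowSums(h$coefficients^2) / 2
  cum <- cumsum(pow) / sum(pow)
  which(cum >= threshold - 1e-12)[1L]
}

#' Dataset-level elliptic Fourier coefficients
#'
#' Resamples, decomposes and normalizes every contour in a dataset, aligning
#' the residual sign ambiguity to the first specimen's coefficients so that
#' conspecific coefficient vectors are directly comparable. Returns the
#' matrix of shape variables that feeds [shape_pca()], plus the raw
#' (pre-resampling) perimeter of each contour as the size variable.
#'
#' @param dataset A [wing_dataset()] with contour records.
#' @param n_points Resampling density (pseudo-landmarks per contour).
#' @param n_harmonics Harmonics retained.
#' @return List with `coefficients` (n x 4*n_harmonics matrix; columns
#'   a1,b1,c1,d1,a2,...), `perimeters` (mm), `species`, `ids`,
#'   `harmonics` (list of normalized `efa_harmonics`).
#' @export
efa_dataset <- function(dataset, n_points = 300, n_harmonics = 20) {
  cl <- contour_list(dataset)
  perims <- vapply(cl$contours, contour_perimeter, numeric(1))
  ref <- NULL
  harms <- vector("list", length(cl$contours))
  for (i in seq_along(cl$contours)) {
    rs <- resample_contour(cl$contours[[i]], n_points)
    hn <- efa_normalize(efa(rs, n_harmonics), align_to = ref)
    if (is.null(ref)) ref <- hn$coefficients
    harms[[i]] <- hn
  }
  cm <- t(vapply(harms, function(hh) as.vector(t(hh$coefficients)),
                 numeric(4L * n_harmonics)))
  colnames(cm) <- paste0(rep(c("a", "b", "c", "d"), n_harmonics),
                         rep(seq_len(n_harmonics), each = 4L))
  rownames(cm) <- cl$ids
  list(coefficients = cm, perimeters = perims, species = cl$species,
       ids = cl$ids, harmonics = harms)
}
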