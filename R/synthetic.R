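#' Template wing landmark configuration
#'
#' A hand-placed 21-point configuration approximating the landmark protocol
#' of a tabanid wing: points along the leading edge, wing tip, trailing
#' edge, and interior vein junctions. The exact coordinates are arbitrary
#' (any non-degenerate wing-like configuration serves); the generator adds
#' species- and specimen-level shape variation around it.
#'
#' @return A 21 x 2 numeric matrix, wing length about 1 unit.
#' @export
template_wing_landmarks <- function() {
  matrix(c(
    0.00,  0.00,   # wing base
    0.15,  0.06,   # leading edge
    0.35,  0.10,
    0.55,  0.12,
    0.75,  0.11,
    0.90,  0.07,
    1.00,  0.00,   # wing tip
    0.92, -0.06,   # trailing edge
    0.80, -0.12,
    0.65, -0.16,
    0.48, -0.17,
    0.30, -0.14,
    0.12, -0.08,
    0.25,  0.02,   # interior vein junctions
    0.40,  0.04,
    0.55,  0.03,
    0.70,  0.02,
    0.60, -0.06,
    0.45, -0.08,
    0.32, -0.05,
    0.20, -0.03
  ), ncol = 2L, byrow = TRUE)
}

#' Template wing-cell contour
#'
#' A smooth, slightly asymmetric rounded-quadrilateral closed curve standing
#' in for the first submarginal cell. Built as a sheared superellipse so it
#' is convex-ish, simple, and has no exact symmetry (exact symmetries make
#' outline normalization degenerate in uninteresting ways).
#'
#' @param n_points Number of boundary points.
#' @return An n_points x 2 matrix, counter-clockwise, size about 1 unit.
#' @export
template_cell_contour <- function(n_points = 200) {
  t <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  p <- 2.5                                 # superellipse exponent
  x <- sign(cos(t)) * abs(cos(t))^(2 / p)
  y <- 0.55 * sign(sin(t)) * abs(sin(t))^(2 / p)
  x <- x + 0.18 * y                        # shear: break symmetry
  y <- y + 0.05 * x^2                      # mild bend
  cbind(x, y)
}

#' Specification for the synthetic wing-data generator
#'
#' Defines the statistical structure of a simulated multi-species wing
#' dataset. Defaults mirror the published 15-species Tabanus study tables:
#' per-species sample sizes, mean centroid sizes (7.34–13.47 mm), mean cell
#' perimeters (9.27–16.92 mm), and a size coefficient of variation of 0.05
#' (the published SD/mean ratios are about 0.04–0.07). Shape-noise scales
#' are expressed in unit-centroid-size shape units; the defaults
#' (between-species 0.006 > within-species 0.005) place expected pairwise
#' Mahalanobis distances in the published 4–19 range. Digitization noise
#' is in mm (default 0.01, about 0.001 shape units on a 9 mm wing, well
#' below the within-species scale).
#'
#' @param n_species Number of species.
#' @param n_per_species Integer vector of specimens per species (recycled).
#' @param template_landmarks Base landmark configuration.
#' @param between_shape_sd Per-coordinate SD of species mean-shape offsets.
#' @param within_shape_sd Per-coordinate SD of specimen shape noise.
#' @param digitization_sd Per-coordinate SD of replicate digitization noise,
#'   in mm (used by [generate_replicates()]).
#' @param size_means Per-species mean size (mm): centroid size for landmark
#'   data, scaled to cell perimeter targets for contour data.
#' @param perimeter_means Per-species mean cell perimeter (mm).
#' @param size_cv Coefficient of variation of the log-normal size noise.
#' @param allometry_coef Optional size–shape coupling: shape drift (in shape
#'   units) per unit of standardized log size, along a fixed direction.
#'   Zero by default (size and shape independent).
#' @param between_coef_sd,within_coef_sd SDs of the Gaussian perturbations
#'   of normalized elliptic Fourier coefficients at the species and
#'   specimen level.
#' @param contour_points Boundary points per simulated contour.
#' @param contour_harmonics Harmonics used to build simulated contours.
#' @param seed Integer seed; every generate call is reproducible given it.
#' @return Object of class `synthetic_wing_spec` (a list of the above).
#' @export
synthetic_wing_spec <- function(n_species = 15,
                                n_per_species = tabanus_reference()$n_landmark,
                                template_landmarks = template_wing_landmarks(),
                                between_shape_sd = 0.006,
                                within_shape_sd = 0.005,
                                digitization_sd = 0.01,
                                size_means = tabanus_reference()$cs_mean,
                                perimeter_means = tabanus_reference()$perim_mean,
                                size_cv = 0.05,
                                allometry_coef = 0,
                                between_coef_sd = 0.006,
                                within_coef_sd = 0.005,
                                contour_points = 300,
                                contour_harmonics = 20,
                                seed = 1L) {
  n_per_species <- rep_len(as.integer(n_per_species), n_species)
  size_means <- rep_len(as.numeric(size_means), n_species)
  perimeter_means <- rep_len(as.numeric(perimeter_means), n_species)
  template_landmarks <- as_coord_matrix(template_landmarks, "landmarks",
                                        "<template>")
  if (centroid_size(template_landmarks) <= 0)
    stop("degenerate template configuration")
  if (any(size_means <= 0) || any(perimeter_means <= 0))
    stop("all sizes must be positive")
  if (!(between_shape_sd > within_shape_sd))
    warning("between_shape_sd <= within_shape_sd: species will be hard ",
            "to separate by shape (not the published regime)")
  structure(list(n_species = as.integer(n_species),
                 n_per_species = n_per_species,
                 template_landmarks = template_landmarks,
                 between_shape_sd = between_shape_sd,
                 within_shape_sd = within_shape_sd,
                 digitization_sd = digitization_sd,
                 size_means = size_means,
                 perimeter_means = perimeter_means,
                 size_cv = size_cv,
                 allometry_coef = allometry_coef,
                 between_coef_sd = between_coef_sd,
                 within_coef_sd = within_coef_sd,
                 contour_points = as.integer(contour_points),
                 contour_harmonics = as.integer(contour_harmonics),
                 seed = as.integer(seed)),
            class = "synthetic_wing_spec")
}

species_names <- function(k) sprintf("sp%02d", seq_len(k))

lognormal_sizes <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rotate2 <- function(m, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  m %*% R
}

#' Generate a synthetic multi-species landmark dataset
#'
#' Species mean shapes are the template (centred, unit centroid size) plus
#' Gaussian per-coordinate offsets; specimens add within-species Gaussian
#' shape noise, are scaled to a log-normal size around the species mean
#' size, and are randomly rotated and translated (so Procrustes alignment
#' has real work to do). With `allometry_coef > 0`, a shape drift
#' proportional to the specimen's standardized log size is added along a
#' fixed direction, inducing a known allometric signal.
#'
#' @param spec A [synthetic_wing_spec()].
#' @return A [wing_dataset()] with landmark records, labels `sp01`, `sp02`,
#'   ... and ids `<species>-<index>`.
#' @export
generate_landmark_dataset <- function(spec = synthetic_wing_spec()) {
  stopifnot(inherits(spec, "synthetic_wing_spec"))
  set.seed(spec$seed)
  tmpl <- spec$template_landmarks
  tmpl <- sweep(tmpl, 2L, colMeans(tmpl))
  tmpl <- tmpl / centroid_size(tmpl)
  p <- nrow(tmpl)
  sp_names <- species_names(spec$n_species)

  allo_dir <- matrix(rnorm(2L * p), p, 2L)
  allo_dir <- allo_dir / sqrt(sum(allo_dir^2))

  records <- list()
  for (j in seq_len(spec$n_species)) {
    mean_shape <- tmpl + matrix(rnorm(2L * p, sd = spec$between_shape_sd),
                                p, 2L)
    sizes <- lognormal_sizes(spec$n_per_species[j], spec$size_means[j],
                             spec$size_cv)
    for (i in seq_len(spec$n_per_species[j])) {
      shp <- mean_shape + matrix(rnorm(2L * p, sd = spec$within_shape_sd),
                                 p, 2L)
      if (spec$allometry_coef != 0) {
        z <- (log(sizes[i]) - log(spec$size_means[j])) /
          sqrt(log(1 + spec$size_cv^2))
        shp <- shp + spec$allometry_coef * z * allo_dir
      }
      shp <- sweep(shp, 2L, colMeans(shp))
      shp <- shp / centroid_size(shp) * sizes[i]
      shp <- rotate2(shp, runif(1, 0, 2 * pi))
      shp <- sweep(shp, 2L, rnorm(2L, sd = 5), `+`)
      records[[length(records) + 1L]] <-
        specimen_record(paste0(sp_names[j], "-", i), sp_names[j],
                        landmarks = shp)
    }
  }
  wing_dataset(records)
}

#' Generate a synthetic multi-species contour dataset
#'
#' The template cell contour is decomposed into normalized elliptic Fourier
#' coefficients; species mean coefficient sets add Gaussian offsets to the
#' free coefficients (everything except the fixed `a1 = 1`, `b1 = c1 = 0`),
#' specimens add within-species coefficient noise, and each contour is
#' reconstructed, scaled to a log-normal perimeter around the species mean
#' perimeter, randomly rotated and translated. Self-intersecting draws are
#' rejected and redrawn (at most 100 retries per specimen).
#'
#' @param spec A [synthetic_wing_spec()].
#' @return A [wing_dataset()] with contour records.
#' @export
generate_contour_dataset <- function(spec = synthetic_wing_spec()) {
  stopifnot(inherits(spec, "synthetic_wing_spec"))
  set.seed(spec$seed + 1L)
  base <- efa_normalize(efa(resample_contour(template_cell_contour(),
                                             spec$contour_points),
                            spec$contour_harmonics))
  free <- matrix(TRUE, spec$contour_harmonics, 4L)
  free[1L, c(1L, 2L, 3L)] <- FALSE          # a1, b1, c1 fixed by normalization
  sp_names <- species_names(spec$n_species)

  records <- list()
  for (j in seq_len(spec$n_species)) {
    mean_coef <- base$coefficients
    mean_coef[free] <- mean_coef[free] +
      rnorm(sum(free), sd = spec$between_coef_sd)
    perims <- lognormal_sizes(spec$n_per_species[j], spec$perimeter_means[j],
                              spec$size_cv)
    for (i in seq_len(spec$n_per_species[j])) {
      ct <- NULL
      for (try in seq_len(100L)) {
        cf <- mean_coef
        cf[free] <- cf[free] + rnorm(sum(free), sd = spec$within_coef_sd)
        h <- structure(list(coefficients = cf, dc = c(A0 = 0, C0 = 0),
                            n_harmonics = spec$contour_harmonics,
                            normalized = TRUE, size_scalar = 1,
                            perimeter = NA_real_),
                       class = "efa_harmonics")
        cand <- efa_reconstruct(h, spec$contour_points)
        probe <- unique(round(seq(1L, nrow(cand), length.out = 100L)))
        if (is_simple_polygon(cand[probe, , drop = FALSE])) {
          ct <- cand; break
        }
      }
      if (is.null(ct))
        stop("persistent self-intersection for species ", sp_names[j],
             "; reduce coefficient perturbations")
      ct <- ct * (perims[i] / contour_perimeter(ct))
      ct <- rotate2(ct, runif(1, 0, 2 * pi))
      ct <- sweep(ct, 2L, rnorm(2L, sd = 5), `+`)
      records[[length(records) + 1L]] <-
        specimen_record(paste0(sp_names[j], "-", i), sp_names[j],
                        contour = ct)
    }
  }
  wing_dataset(records)
}

# O(n^2) segment-intersection test on a closed polygon (vectorized);
# adjacent segments share an endpoint and are excluded
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1L), ]
  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  d1 <- cross2(b[i, ] - a[i, ], a[j, ] - a[i, ])
  d2 <- cross2(b[i, ] - a[i, ], b[j, ] - a[i, ])
  d3 <- cross2(b[j, ] - a[j, ], a[i, ] - a[j, ])
  d4 <- cross2(b[j, ] - a[j, ], b[i, ] - a[j, ])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(u, v) u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]

#' Duplicate a dataset with digitization-replicate noise
#'
#' Emulates digitizing every specimen `m` times by the same operator:
#' each record is duplicated `m` times with independent Gaussian coordinate
#' noise (in mm) and `replicate_index` set, ready for
#' [procrustes_anova_repeatability()].
#'
#' @param dataset A [wing_dataset()] with landmark records.
#' @param digitization_sd Per-coordinate noise SD in mm.
#' @param m Replicates per specimen (default 2).
#' @param seed Integer seed.
#' @return A [wing_dataset()] with `m` times as many records.
#' @export
generate_replicates <- function(dataset, digitization_sd, m = 2L,
                                seed = 1L) {
  set.seed(seed)
  stopifnot(m >= 2L, digitization_sd >= 0)
  records <- list()
  for (r in dataset$records) {
    if (is.null(r$landmarks)) next
    p <- nrow(r$landmarks)
    for (rep_i in seq_len(m)) {
      noisy <- r$landmarks +
        matrix(rnorm(2L * p, sd = digitization_sd), p, 2L)
      records[[length(records) + 1L]] <-
        specimen_record(r$specimen_id, r$species, landmarks = noisy,
                        replicate_index = rep_i)
    }
  }
  wing_dataset(records)
}
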