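#' Run a full wing-morphometrics analysis
#'
#' Orchestrates one pipeline end to end, in the standard order of
#' operations. Landmark pipeline: generalized Procrustes alignment,
#' centroid size, shape PCA (default 24 PCs), discriminant analysis,
#' pairwise Mahalanobis distances, permutation tests (size means and shape
#' distances) with Bonferroni correction, leave-one-out classification by
#' size (Gaussian maximum likelihood with frequency priors) and by shape
#' (minimum Mahalanobis distance), and chance-adjusted accuracies. Outline
#' pipeline: arc-length resampling, elliptic Fourier decomposition with
#' first-harmonic normalization, cell perimeter as the size variable, shape
#' PCA (default 23 PCs), then the same statistical stack.
#'
#' @param dataset A [wing_dataset()] with landmark and/or contour records.
#' @param pipeline `"landmark"` or `"outline"`.
#' @param n_pcs Shape PCs to retain; defaults 24 (landmark) or 23 (outline).
#' @param permutation_B Permutation replicates (default 1000); set to 0 to
#'   skip the permutation tests (they dominate run time).
#' @param seed Integer seed for the permutation tests.
#' @param n_points,n_harmonics Outline resampling density and harmonic
#'   count (outline pipeline only).
#' @param out_dir Optional directory: when given, report tables are written
#'   via [write_report_tables()].
#' @return List of class `wing_analysis` with elements `pipeline`, `sizes`,
#'   `labels`, `ids`, `space` (shape_space), `model`
#'   (discriminant_model), `mahalanobis`, `size_permutation`,
#'   `shape_permutation`, `size_report`, `shape_report`, `allometry`, plus
#'   `gpa_fit` (landmark) or `efa_set` (outline), and `seed`.
#' @export
analyze_wing_data <- function(dataset,
                              pipeline = c("landmark", "outline"),
                              n_pcs = NULL,
                              permutation_B = 1000,
                              seed = 1L,
                              n_points = 300,
                              n_harmonics = 20,
                              out_dir = NULL) {
  pipeline <- match.arg(pipeline)
  if (is.null(n_pcs)) n_pcs <- if (pipeline == "landmark") 24L else 23L

  if (pipeline == "landmark") {
    fit <- gpa(dataset)
    sizes <- fit$centroid_sizes
    labels <- fit$species
    ids <- fit$ids
    vars <- shape_variables(fit)
    extra <- list(gpa_fit = fit)
  } else {
    es <- efa_dataset(dataset, n_points = n_points,
                      n_harmonics = n_harmonics)
    sizes <- es$perimeters
    labels <- es$species
    ids <- es$ids
    vars <- es$coefficients
    extra <- list(efa_set = es)
  }

  space <- shape_pca(vars, labels, n_retain = n_pcs)
  model <- discriminant_analysis(space)
  D <- mahalanobis_matrix(space)
  allo <- allometry_r2(model$factor_map[, 1L], sizes)

  size_perm <- shape_perm <- NULL
  if (permutation_B > 0) {
    size_perm <- permutation_test(sizes, labels, "mean_difference",
                                  B = permutation_B, seed = seed)
    shape_perm <- permutation_test(space$scores, labels, "mahalanobis",
                                   B = permutation_B, seed = seed + 1L)
  }
  size_report <- loo_classify_size(sizes, labels)
  shape_report <- loo_classify_shape(space)

  res <- c(list(pipeline = pipeline, sizes = sizes, labels = labels,
                ids = ids, space = space, model = model, mahalanobis = D,
                size_permutation = size_perm, shape_permutation = shape_perm,
                size_report = size_report, shape_report = shape_report,
                allometry = allo, seed = as.integer(seed)),
           extra)
  class(res) <- "wing_analysis"
  if (!is.null(out_dir))
    write_report_tables(res, out_dir, prefix = pipeline)
  res
}

#' @export
print.wing_analysis <- function(x, ...) {
  cat("wing_analysis (", x$pipeline, " pipeline): ",
      length(x$labels), " specimens, ", length(unique(x$labels)),
      " species\n", sep = "")
  fr <- round(100 * x$model$df_variance_fractions[1:min(2,
    length(x$model$df_variance_fractions))], 1)
  cat("  DF1 = ", fr[1L], "%",
      if (length(fr) > 1L) paste0(", DF2 = ", fr[2L], "%"),
      "; allometry r^2 = ", round(x$allometry$r_squared, 3), "\n", sep = "")
  cat("  size LOO:  ", sprintf("%.2f", x$size_report$total_accuracy_percent),
      "% (adjusted ", x$size_report$adjusted_accuracy_percent, "%)\n",
      sep = "")
  cat("  shape LOO: ", sprintf("%.2f", x$shape_report$total_accuracy_percent),
      "% (adjusted ", x$shape_report$adjusted_accuracy_percent, "%)\n",
      sep = "")
  invisible(x)
}

#' Simulate a wing dataset and write it to files
#'
#' Generates landmark and contour datasets from a [synthetic_wing_spec()]
#' and writes them as TPS and CSV plus a JSON metadata echo of the spec
#' (including the seed), so a simulation is fully reproducible from its
#' output directory.
#'
#' @param spec A [synthetic_wing_spec()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the `landmark` and `contour` datasets and
#'   the written `files`.
#' @export
simulate_wing_data <- function(spec = synthetic_wing_spec(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  lm_ds <- generate_landmark_dataset(spec)
  ct_ds <- generate_contour_dataset(spec)
  files <- c(
    landmarks_tps = file.path(out_dir, "landmarks.tps"),
    landmarks_csv = file.path(out_dir, "landmarks.csv"),
    contours_csv = file.path(out_dir, "contours.csv"),
    metadata = file.path(out_dir, "metadata.json"))
  write_tps(lm_ds, files[["landmarks_tps"]])
  write_landmark_csv(lm_ds, files[["landmarks_csv"]])
  write_contour_csv(ct_ds, files[["contours_csv"]])
  meta <- unclass(spec)
  meta$template_landmarks <- NULL
  jsonlite::write_json(meta, files[["metadata"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(landmark = lm_ds, contour = ct_ds, files = files))
}

#' Standalone chance adjustment of a published accuracy
#'
#' Utility for verifying printed classification tables: applies the
#' proportional-chance correction to a raw accuracy given the per-group
#' sample sizes.
#'
#' @param accuracy Raw accuracy, as a fraction in `[0, 1]` or a percent in
#'   `(1, 100]` (auto-detected).
#' @param group_sizes Per-group sample sizes.
#' @return Integer percent.
#' @export
chance_adjust <- function(accuracy, group_sizes) {
  if (accuracy > 1) accuracy <- accuracy / 100
  adjusted_accuracy(accuracy, group_sizes)
}
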