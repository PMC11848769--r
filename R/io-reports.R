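#' Per-species size summary table
#'
#' The standard size table: sample size, mean, min, max, variance and SD of
#' a size variable (centroid size or cell perimeter) per species.
#'
#' @param sizes Numeric per-specimen sizes (mm).
#' @param labels Species labels.
#' @param digits Rounding for the table (default 2, matching the usual
#'   presentation); use `NULL` for full precision.
#' @return Data frame with columns species, n, mean, min, max, variance, sd.
#' @export
size_summary_table <- function(sizes, labels, digits = 2) {
  stopifnot(length(sizes) == length(labels))
  sp <- sort(unique(as.character(labels)))
  out <- do.call(rbind, lapply(sp, function(g) {
    x <- sizes[labels == g]
    data.frame(species = g, n = length(x), mean = mean(x),
               min = min(x), max = max(x),
               variance = if (length(x) > 1L) var(x) else 0,
               sd = if (length(x) > 1L) sd(x) else 0)
  }))
  if (!is.null(digits))
    out[, 3:7] <- round(out[, 3:7], digits)
  out
}

#' Serialize a Mahalanobis matrix as a lower triangle
#'
#' @param D Symmetric distance matrix with species dimnames.
#' @param digits Rounding (default 2).
#' @return Data frame: species rows, lower-triangle columns; upper triangle
#'   and diagonal left empty.
#' @export
mahalanobis_lower_triangle <- function(D, digits = 2) {
  k <- nrow(D)
  M <- matrix("", k, k - 1L,
              dimnames = list(rownames(D), colnames(D)[-k]))
  for (i in 2:k) for (j in seq_len(i - 1L))
    M[i, j] <- formatC(D[i, j], digits = digits, format = "f")
  data.frame(species = rownames(D), M, check.names = FALSE,
             row.names = NULL)
}

#' Write analysis report tables
#'
#' Writes the standard report set for one pipeline run to `out_dir`: a
#' per-species size summary, the pairwise Mahalanobis distance matrix
#' (lower triangle), and the validated-classification tables for size and
#' shape (per-species assigned counts and accuracies plus total and
#' chance-adjusted rows). Each CSV has a JSON twin with the same stem.
#'
#' @param results A result list from [analyze_wing_data()] (needs elements
#'   `sizes`, `labels`, `mahalanobis`, `size_report`, `shape_report`; any
#'   may be NULL and is then skipped).
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix (e.g. `"landmark"` or `"outline"`).
#' @return Invisibly, the character vector of files written.
#' @export
write_report_tables <- function(results, out_dir, prefix = "analysis") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  written <- character(0)
  emit <- function(df, stem) {
    csv <- file.path(out_dir, paste0(prefix, "_", stem, ".csv"))
    js <- file.path(out_dir, paste0(prefix, "_", stem, ".json"))
    write.csv(df, csv, row.names = FALSE)
    jsonlite::write_json(df, js, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
    written <<- c(written, csv, js)
  }

  if (!is.null(results$sizes))
    emit(size_summary_table(results$sizes, results$labels), "size_summary")
  if (!is.null(results$mahalanobis))
    emit(mahalanobis_lower_triangle(results$mahalanobis), "mahalanobis")
  for (what in c("size", "shape")) {
    rep <- results[[paste0(what, "_report")]]
    if (is.null(rep)) next
    per <- rep$per_species
    tail <- data.frame(
      species = c("Total", "Adjusted total"),
      n = c(sum(per$n), NA),
      assigned_correct = c(sum(per$assigned_correct), NA),
      accuracy_percent = c(rep$total_accuracy_percent,
                           rep$adjusted_accuracy_percent))
    emit(rbind(per, tail), paste0("classification_", what))
  }
  invisible(written)
}
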