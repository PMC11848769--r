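#' Specimen record
#'
#' One digitized specimen: an ordered landmark configuration and/or a closed
#' wing-cell contour, with its species label. Coordinates are in millimetres,
#' y-up. Sources digitized in image coordinates (y-down) must be flipped at
#' read time (`flip_y` in the readers): shape statistics are
#' reflection-sensitive, so mixing conventions silently corrupts analyses.
#'
#' @param specimen_id Character scalar, unique within a dataset.
#' @param species Non-empty character scalar, the species label.
#' @param landmarks Optional numeric matrix (p x 2) of landmark coordinates.
#' @param contour Optional numeric matrix (m x 2), ordered boundary points of
#'   a closed contour (the closing segment from last to first point is
#'   implicit; do not repeat the first point).
#' @param replicate_index Optional integer digitization-replicate number.
#' @return An object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, species, landmarks = NULL,
                            contour = NULL, replicate_index = NA_integer_) {
  specimen_id <- as.character(specimen_id)
  species <- as.character(species)
  if (length(species) != 1L || is.na(species) || !nzchar(species))
    stop("species label must be a non-empty string (specimen ", specimen_id, ")")
  if (!is.null(landmarks)) {
    landmarks <- as_coord_matrix(landmarks, "landmarks", specimen_id)
    if (nrow(landmarks) < 1L)
      stop("landmarks must contain at least one point (specimen ", specimen_id, ")")
  }
  if (!is.null(contour)) {
    contour <- as_coord_matrix(contour, "contour", specimen_id)
    if (nrow(contour) < 3L)
      stop("contour needs >= 3 points (specimen ", specimen_id, ")")
    dup <- which(rowSums((contour - contour[c(2:nrow(contour), 1L), ])^2) == 0)
    if (length(dup))
      contour <- contour[-dup, , drop = FALSE]
    if (nrow(contour) < 3L)
      stop("contour degenerate after removing repeated points (specimen ",
           specimen_id, ")")
  }
  structure(list(specimen_id = specimen_id, species = species,
                 landmarks = landmarks, contour = contour,
                 replicate_index = as.integer(replicate_index)),
            class = "specimen_record")
}

as_coord_matrix <- function(x, what, id) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2L)
    stop(what, " must be a two-column (x, y) matrix (specimen ", id, ")")
  if (!all(is.finite(x)))
    stop("non-finite ", what, " coordinates (specimen ", id, ")")
  dimnames(x) <- NULL
  x
}

#' Wing dataset
#'
#' A collection of [specimen_record()]s sharing a landmark protocol. All
#' records that carry landmarks must have the same landmark count; contours
#' may differ in raw point count (they are resampled downstream).
#'
#' @param records List of `specimen_record` objects.
#' @param unit Coordinate unit; fixed to `"mm"`.
#' @return An object of class `wing_dataset` with elements `records`,
#'   `landmark_count` (NA if no record has landmarks) and `unit`.
#' @export
wing_dataset <- function(records, unit = "mm") {
  stopifnot(is.list(records))
  ok <- vapply(records, inherits, logical(1), "specimen_record")
  if (length(records) && !all(ok)) stop("all records must be specimen_record objects")
  counts <- unique(vapply(records, function(r)
    if (is.null(r$landmarks)) NA_integer_ else nrow(r$landmarks), integer(1)))
  counts <- counts[!is.na(counts)]
  if (length(counts) > 1L)
    stop("mixed landmark counts within one dataset: ",
         paste(sort(counts), collapse = ", "))
  structure(list(records = records,
                 landmark_count = if (length(counts)) counts else NA_integer_,
                 unit = unit),
            class = "wing_dataset")
}

#' @export
print.wing_dataset <- function(x, ...) {
  n <- length(x$records)
  sp <- species_labels(x)
  has_lm <- sum(vapply(x$records, function(r) !is.null(r$landmarks), logical(1)))
  has_ct <- sum(vapply(x$records, function(r) !is.null(r$contour), logical(1)))
  cat("wing_dataset: ", n, " specimens, ", length(unique(sp)), " species\n",
      "  landmarks: ", has_lm, " records (",
      if (is.na(x$landmark_count)) "-" else x$landmark_count, " per wing), ",
      "contours: ", has_ct, " records, unit: ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @export
length.wing_dataset <- function(x) length(x$records)

#' Species labels of a dataset
#' @param dataset A [wing_dataset()].
#' @return Character vector, one label per record.
#' @export
species_labels <- function(dataset) {
  vapply(dataset$records, function(r) r$species, character(1))
}

#' Specimen identifiers of a dataset
#' @inheritParams species_labels
#' @return Character vector of specimen ids.
#' @export
specimen_ids <- function(dataset) {
  vapply(dataset$records, function(r) r$specimen_id, character(1))
}

#' Landmark array of a dataset
#'
#' Stacks the landmark configurations into a `p x 2 x n` array in record
#' order, dropping records without landmarks.
#'
#' @inheritParams species_labels
#' @return List with `coords` (array), `species`, `ids`, `replicate_index`.
#' @export
landmark_array <- function(dataset) {
  keep <- vapply(dataset$records, function(r) !is.null(r$landmarks), logical(1))
  recs <- dataset$records[keep]
  if (!length(recs)) stop("dataset contains no landmark records")
  p <- nrow(recs[[1]]$landmarks)
  coords <- array(NA_real_, dim = c(p, 2L, length(recs)))
  for (i in seq_along(recs)) coords[, , i] <- recs[[i]]$landmarks
  list(coords = coords,
       species = vapply(recs, function(r) r$species, character(1)),
       ids = vapply(recs, function(r) r$specimen_id, character(1)),
       replicate_index = vapply(recs, function(r) r$replicate_index, integer(1)))
}

#' Contour list of a dataset
#'
#' @inheritParams species_labels
#' @return List with `contours` (list of m x 2 matrices), `species`, `ids`.
#' @export
contour_list <- function(dataset) {
  keep <- vapply(dataset$records, function(r) !is.null(r$contour), logical(1))
  recs <- dataset$records[keep]
  if (!length(recs)) stop("dataset contains no contour records")
  list(contours = lapply(recs, function(r) r$contour),
       species = vapply(recs, function(r) r$species, character(1)),
       ids = vapply(recs, function(r) r$specimen_id, character(1)))
}

require_two_species <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("at least 2 distinct species are required for between-group analysis")
  invisible(labels)
}
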