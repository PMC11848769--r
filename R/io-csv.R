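#' Read landmark data from CSV
#'
#' Expects a header `specimen_id, species, x1, y1, ..., xp, yp` (column names
#' are not case-sensitive; the coordinate columns only need to come in x/y
#' pairs after the two metadata columns). An optional `replicate` column
#' after `species` is honoured.
#'
#' @param path Path to a CSV file.
#' @param flip_y Negate y at read time for image-origin (y-down) sources.
#' @return A [wing_dataset()].
#' @export
read_landmark_csv <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("empty landmark CSV: ", path, "; returning empty dataset")
    return(wing_dataset(list()))
  }
  nm <- tolower(names(df))
  if (length(nm) < 4L || nm[1] != "specimen_id" || nm[2] != "species")
    stop("expected header: specimen_id, species[, replicate], x1, y1, ...")
  has_rep <- length(nm) >= 3L && nm[3] == "replicate"
  first_coord <- if (has_rep) 4L else 3L
  coord_cols <- seq(first_coord, length(nm))
  if (length(coord_cols) %% 2L != 0L)
    stop("odd number of coordinate columns (", length(coord_cols), ")")
  p <- length(coord_cols) %/% 2L
  cm <- as.matrix(df[, coord_cols, drop = FALSE])
  if (!is.numeric(cm)) {
    bad <- which(!apply(df[, coord_cols, drop = FALSE], 1L,
                        function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric coordinate in row(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  if (any(!is.finite(cm))) {
    bad <- which(apply(cm, 1L, function(r) any(!is.finite(r))))
    stop("missing/non-finite coordinate in row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    lm <- matrix(cm[i, ], ncol = 2L, byrow = TRUE)
    if (flip_y) lm[, 2L] <- -lm[, 2L]
    specimen_record(df[[1L]][i], df[[2L]][i], landmarks = lm,
                    replicate_index = if (has_rep) df[[3L]][i] else NA_integer_)
  })
  ds <- wing_dataset(records)
  stopifnot(ds$landmark_count == p)
  ds
}

#' Write landmark data to CSV
#'
#' Inverse of [read_landmark_csv()]; records without landmarks are skipped.
#'
#' @param dataset A [wing_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_landmark_csv <- function(dataset, path) {
  la <- landmark_array(dataset)
  p <- dim(la$coords)[1L]
  flat <- t(apply(la$coords, 3L, function(m) as.vector(t(m))))
  colnames(flat) <- as.vector(rbind(paste0("x", 1:p), paste0("y", 1:p)))
  df <- data.frame(specimen_id = la$ids, species = la$species,
                   replicate = la$replicate_index, flat,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read contour data from long-format CSV
#'
#' Expects header `specimen_id, species, x, y`; rows for one specimen must be
#' contiguous and in boundary order.
#'
#' @inheritParams read_landmark_csv
#' @return A [wing_dataset()] of contour-only records.
#' @export
read_contour_csv <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "x", "y")
  if (!all(need %in% tolower(names(df))))
    stop("expected header: specimen_id, species, x, y")
  names(df) <- tolower(names(df))
  ids <- unique(df$specimen_id)
  records <- lapply(ids, function(id) {
    sub <- df[df$specimen_id == id, ]
    ct <- cbind(sub$x, if (flip_y) -sub$y else sub$y)
    specimen_record(id, sub$species[1L], contour = ct)
  })
  wing_dataset(records)
}

#' @rdname read_contour_csv
#' @param dataset A [wing_dataset()] with contour records.
#' @export
write_contour_csv <- function(dataset, path) {
  cl <- contour_list(dataset)
  df <- do.call(rbind, lapply(seq_along(cl$contours), function(i)
    data.frame(specimen_id = cl$ids[i], species = cl$species[i],
               x = cl$contours[[i]][, 1L], y = cl$contours[[i]][, 2L])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
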