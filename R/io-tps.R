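#' Read a TPS landmark/outline file
#'
#' Parses the TPS dialect common to digitizing tools: each record starts with
#' an `LM=<p>` line followed by `p` whitespace-separated coordinate pairs,
#' optionally followed by `OUTLINES=<k>` with one `POINTS=<m>` block of `m`
#' coordinate pairs per outline (the first outline becomes the record's
#' contour), and optional `IMAGE=`, `ID=` and `SCALE=` lines. Keys are
#' case-insensitive. When `SCALE=` is present and `scale_policy = "apply"`,
#' coordinates are multiplied by the scale factor so that the returned
#' dataset is in millimetres.
#'
#' @param path Path to a TPS file.
#' @param scale_policy `"apply"` (default) multiplies coordinates by any
#'   `SCALE=` factor; `"ignore"` returns raw digitizer units.
#' @param species_from How to obtain the species label: a function applied to
#'   the record id (default: the part of the id before the last underscore,
#'   or the whole id when it has none), or a character vector recycled over
#'   records. When the label is derived from the id, a matching
#'   `<species>_` prefix is stripped from the stored specimen id — the
#'   convention [write_tps()] uses — so write/read round-trips are exact.
#'   Pass an explicit character vector to keep ids untouched.
#' @param flip_y Set `TRUE` for sources digitized in image coordinates
#'   (y-down); y is negated so stored shapes are y-up.
#' @return A [wing_dataset()].
#' @export
read_tps <- function(path, scale_policy = c("apply", "ignore"),
                     species_from = default_species_from, flip_y = FALSE) {
  scale_policy <- match.arg(scale_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^[Ll][Mm]=", lines)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))

  records <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    rec_name <- paste0("record ", k)
    p <- tps_int(block[1L], rec_name)
    body <- block[-1L]
    keyed <- grepl("^[A-Za-z]+=", body)
    coords_lm <- tps_coords(body[!keyed][seq_len(min(p, sum(!keyed)))], rec_name)
    if (p > 0 && (is.null(coords_lm) || nrow(coords_lm) != p))
      stop("LM=", p, " but ", if (is.null(coords_lm)) 0 else nrow(coords_lm),
           " coordinate pairs found (", rec_name, ")")
    rest <- body[cumsum(!keyed) > p | keyed]

    contour <- NULL
    i <- 1L
    id <- NULL; image <- NULL; scale <- NA_real_
    while (i <= length(rest)) {
      ln <- rest[i]
      if (grepl("^[Oo][Uu][Tt][Ll][Ii][Nn][Ee][Ss]=", ln)) {
        i <- i + 1L
        while (i <= length(rest) && grepl("^[Pp][Oo][Ii][Nn][Tt][Ss]=", rest[i])) {
          m <- tps_int(rest[i], rec_name)
          pts <- tps_coords(rest[i + seq_len(m)], rec_name)
          if (is.null(pts) || nrow(pts) != m)
            stop("POINTS=", m, " but fewer coordinate pairs follow (", rec_name, ")")
          if (is.null(contour)) contour <- pts
          i <- i + m + 1L
        }
      } else if (grepl("^[Ii][Dd]=", ln)) {
        id <- sub("^[Ii][Dd]=", "", ln); i <- i + 1L
      } else if (grepl("^[Ii][Mm][Aa][Gg][Ee]=", ln)) {
        image <- sub("^[Ii][Mm][Aa][Gg][Ee]=", "", ln); i <- i + 1L
      } else if (grepl("^[Ss][Cc][Aa][Ll][Ee]=", ln)) {
        scale <- as.numeric(sub("^[Ss][Cc][Aa][Ll][Ee]=", "", ln)); i <- i + 1L
      } else {
        stop("unrecognized line in ", rec_name, ": '", ln, "'")
      }
    }

    sid <- if (!is.null(id) && nzchar(id)) id
      else if (!is.null(image) && nzchar(image)) sub("\\.[A-Za-z0-9]+$", "", image)
      else as.character(k)
    if (scale_policy == "apply" && !is.na(scale)) {
      if (!is.null(coords_lm) && nrow(coords_lm)) coords_lm <- coords_lm * scale
      if (!is.null(contour)) contour <- contour * scale
    }
    if (flip_y) {
      if (!is.null(coords_lm) && nrow(coords_lm)) coords_lm[, 2L] <- -coords_lm[, 2L]
      if (!is.null(contour)) contour[, 2L] <- -contour[, 2L]
    }
    records[[k]] <- list(id = sid,
                         landmarks = if (p > 0) coords_lm else NULL,
                         contour = contour)
  }

  ids <- vapply(records, `[[`, character(1), "id")
  derived <- is.function(species_from)
  sp <- if (derived) unname(vapply(ids, species_from, character(1)))
        else rep_len(as.character(species_from), length(ids))
  # ids written as <species>_<specimen_id> shed the species prefix again
  if (derived) {
    pref <- paste0(sp, "_")
    strip <- startsWith(ids, pref)
    ids[strip] <- substring(ids[strip], nchar(pref[strip]) + 1L)
  }
  wing_dataset(lapply(seq_along(records), function(k)
    specimen_record(ids[k], sp[k],
                    landmarks = records[[k]]$landmarks,
                    contour = records[[k]]$contour)))
}

default_species_from <- function(id) {
  if (grepl("_", id)) sub("_[^_]*$", "", id) else id
}

tps_int <- function(line, rec) {
  v <- suppressWarnings(as.integer(sub("^[A-Za-z]+=", "", line)))
  if (is.na(v) || v < 0) stop("bad count line '", line, "' (", rec, ")")
  v
}

tps_coords <- function(lines, rec) {
  if (!length(lines)) return(NULL)
  parts <- strsplit(lines, "[ \t,]+")
  if (any(vapply(parts, length, integer(1)) != 2L))
    stop("malformed coordinate line (", rec, ")")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2L, byrow = TRUE)
  if (any(!is.finite(m))) stop("non-numeric coordinate (", rec, ")")
  m
}

#' Write a dataset to TPS format
#'
#' Inverse of [read_tps()]: one `LM=` block per record (0 when the record has
#' no landmarks), followed by `OUTLINES=1`/`POINTS=` for the contour when
#' present, and an `ID=` line. Species labels are encoded into ids as
#' `<species>_<specimen_id>` so that [read_tps()] with the default
#' `species_from` recovers them.
#'
#' @param dataset A [wing_dataset()].
#' @param path Output file path.
#' @param digits Significant digits written (default 17: lossless for
#'   doubles, so a write/read cycle is exact).
#' @return Invisibly, `path`.
#' @export
write_tps <- function(dataset, path, digits = 17) {
  fmt <- function(m) paste(formatC(m[, 1], digits = digits, format = "g"),
                           formatC(m[, 2], digits = digits, format = "g"))
  out <- character(0)
  for (r in dataset$records) {
    p <- if (is.null(r$landmarks)) 0L else nrow(r$landmarks)
    out <- c(out, paste0("LM=", p))
    if (p > 0L) out <- c(out, fmt(r$landmarks))
    if (!is.null(r$contour))
      out <- c(out, "OUTLINES=1", paste0("POINTS=", nrow(r$contour)),
               fmt(r$contour))
    out <- c(out, paste0("ID=", r$species, "_", r$specimen_id))
  }
  writeLines(out, path)
  invisible(path)
}
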