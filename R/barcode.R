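#' Read nucleotide barcode sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that validates the
#' records (non-empty sequences over the IUPAC nucleotide alphabet).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet-class] object.
#' @export
read_barcodes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path)
  if (any(Biostrings::width(seqs) == 0)) stop("empty sequence record in ", path)
  seqs
}

#' Average nucleotide composition of a sequence set
#'
#' Base composition over the unambiguous A/C/G/T positions of each
#' sequence. With `average = "per_sequence"` (default) fractions are
#' computed per sequence and then averaged with equal weight per sequence
#' — the convention for reporting the "average nucleotide composition" of a
#' barcode set; `"pooled"` counts all positions together. Case and record
#' order are irrelevant.
#'
#' @param seqs A `DNAStringSet`, or a character vector of sequences, or a
#'   FASTA file path.
#' @param average `"per_sequence"` or `"pooled"`.
#' @return Named numeric vector of percentages `A`, `T`, `C`, `G`, `AT`,
#'   `GC` (full precision; round to 1 decimal for presentation).
#' @export
base_composition <- function(seqs, average = c("per_sequence", "pooled")) {
  average <- match.arg(average)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_barcodes(seqs)
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  stopifnot(length(seqs) >= 1L)
  counts <- Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"),
                                                drop = FALSE]
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " sequence(s) with no unambiguous bases excluded")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
    if (!length(tot)) stop("no sequences with unambiguous bases")
  }
  frac <- if (average == "per_sequence") colMeans(counts / tot)
          else colSums(counts) / sum(tot)
  out <- 100 * c(A = unname(frac["A"]), T = unname(frac["T"]),
                 C = unname(frac["C"]), G = unname(frac["G"]))
  c(out, AT = unname(out["A"] + out["T"]), GC = unname(out["C"] + out["G"]))
}
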