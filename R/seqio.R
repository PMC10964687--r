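#' Sequence dataset container
#'
#' A light container for a set of DNA sequences (ChIP-seq peak regions):
#' identifiers, sequences over `{A,C,G,T,N}`, and per-sequence widths.
#'
#' @param ids character vector of identifiers.
#' @param seqs character vector of sequences (same length as `ids`).
#' @return An object of class `seq_dataset` with fields `id`, `seq`, `n`
#'   and `widths`.
#' @export
seq_dataset <- function(ids, seqs) {
  stopifnot(is.character(ids), is.character(seqs), length(ids) == length(seqs))
  structure(
    list(id = unname(ids), seq = unname(toupper(seqs)), n = length(seqs),
         widths = unname(nchar(seqs))),
    class = "seq_dataset"
  )
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("seq_dataset: %d sequences, widths %d-%d\n",
              x$n, if (x$n) min(x$widths) else 0L, if (x$n) max(x$widths) else 0L))
  invisible(x)
}

#' @export
length.seq_dataset <- function(x) x$n

#' Read a FASTA file of peak sequences
#'
#' Sequences are upper-cased on input; multi-line records are supported and
#' record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return A [seq_dataset()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  # cheap format pre-scan so malformed input errors name the offending line
  first <- readLines(path, n = 50L, warn = FALSE)
  nonempty <- which(nzchar(trimws(first)))
  if (!length(nonempty)) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(first[nonempty[1]]), ">")) {
    stop(sprintf("malformed FASTA header at line %d of %s", nonempty[1], path))
  }
  xs <- Biostrings::readBStringSet(path)
  if (!length(xs)) stop("no sequences in FASTA file: ", path)
  seq_dataset(names(xs), as.character(xs))
}

#' Write a dataset to FASTA
#'
#' @param dataset a [seq_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "seq_dataset"))
  xs <- Biostrings::BStringSet(setNames(dataset$seq, dataset$id))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Normalize sequence characters and, optionally, widths
#'
#' Characters outside `{A,C,G,T}` are replaced by `N`. With
#' `width_policy = "center_trim"` every sequence is trimmed symmetrically to
#' the minimum width in the dataset (peaks are summit-centered, so trimming
#' both flanks retains the informative middle); for odd excess the extra
#' symbol is removed from the right.
#'
#' @param dataset a [seq_dataset()].
#' @param width_policy `"none"` or `"center_trim"`.
#' @return A normalized [seq_dataset()].
#' @export
normalize_dataset <- function(dataset, width_policy = c("none", "center_trim")) {
  stopifnot(inherits(dataset, "seq_dataset"))
  width_policy <- match.arg(width_policy)
  if (dataset$n == 0) stop("empty dataset")
  seqs <- gsub("[^ACGT]", "N", toupper(dataset$seq))
  if (width_policy == "center_trim") {
    wmin <- min(nchar(seqs))
    if (wmin < 1) stop("sequence shorter than 1 after trimming")
    seqs <- vapply(seqs, function(s) {
      excess <- nchar(s) - wmin
      left <- excess %/% 2
      substr(s, left + 1, left + wmin)
    }, character(1), USE.NAMES = FALSE)
  }
  seq_dataset(dataset$id, seqs)
}
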