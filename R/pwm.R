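#' Position weight matrix
#'
#' The positive model: a k x 4 row-stochastic matrix of per-position base
#' probabilities, columns in A, C, G, T order.
#'
#' @param matrix numeric k x 4 matrix; rows must sum to 1 and entries be
#'   positive.
#' @return An object of class `pwm`.
#' @export
pwm <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, all(matrix > 0),
            all(abs(rowSums(matrix) - 1) < 1e-6))
  colnames(matrix) <- .ALPHABET
  structure(matrix / rowSums(matrix), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, consensus %s\n", nrow(x), consensus(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Seed a PWM from a k-mer
#'
#' Row `j` puts `match_weight` on the j-th base of the k-mer and spreads
#' the remainder evenly over the other three bases.
#'
#' @param kmer a k-mer over `{A,C,G,T}`.
#' @param match_weight probability of the consensus base, in (0.25, 1);
#'   default 0.7 leaves room for mutated instances while dominating the
#'   uniform background.
#' @return A [pwm()].
#' @export
seed_pwm <- function(kmer, match_weight = 0.7) {
  stopifnot(match_weight > 0.25, match_weight < 1)
  bases <- strsplit(kmer, "", fixed = TRUE)[[1]]
  idx <- match(bases, .ALPHABET)
  if (anyNA(idx)) stop("kmer contains a symbol outside {A,C,G,T}: ", kmer)
  k <- length(idx)
  m <- matrix((1 - match_weight) / 3, nrow = k, ncol = 4)
  m[cbind(seq_len(k), idx)] <- match_weight
  pwm(m)
}

#' Consensus string of a PWM (per-row argmax)
#'
#' @param x a [pwm()].
#' @return character scalar.
#' @export
consensus <- function(x) {
  paste0(.ALPHABET[max.col(unclass(x), ties.method = "first")], collapse = "")
}

#' Reverse complement of a PWM
#'
#' Rows reversed, columns swapped A<->T and C<->G.
#'
#' @param x a [pwm()].
#' @return A [pwm()].
#' @export
reverse_complement_pwm <- function(x) {
  m <- unclass(x)[rev(seq_len(nrow(x))), c(4, 3, 2, 1), drop = FALSE]
  pwm(m)
}

#' Read motifs in JASPAR PFM format
#'
#' Expects blocks of a `>ID NAME` header followed by four rows
#' `A [ counts ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` (brackets
#' optional). Counts are smoothed with a pseudocount (default 0.8, split
#' evenly per cell) and normalized per column.
#'
#' @param path path to a JASPAR PFM file.
#' @param pseudocount total pseudocount per matrix column.
#' @return named list of [pwm()] objects.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR header lines in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    start <- heads[h]
    end <- if (h < length(heads)) heads[h + 1] - 1L else length(lines)
    block <- lines[(start + 1L):end]
    if (length(block) < 4) stop("JASPAR block with fewer than 4 rows at line ", start)
    id <- sub("^>\\s*", "", lines[start])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^[ACGT]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    base_order <- substr(block[1:4], 1, 1)
    if (!setequal(base_order, .ALPHABET)) base_order <- .ALPHABET
    widths <- lengths(rows)
    if (length(unique(widths)) != 1) {
      stop("JASPAR rows of unequal length for motif ", id)
    }
    counts <- do.call(rbind, rows)[match(.ALPHABET, base_order), , drop = FALSE]
    counts <- counts + pseudocount / 4
    probs <- t(counts) / colSums(counts) # k x 4
    out[[id]] <- pwm(probs)
  }
  out
}

#' Write motifs in JASPAR PFM format
#'
#' Probabilities are scaled to counts (`nsites`, default 100) so the file
#' round-trips through [read_jaspar_pfm()] up to the pseudocount.
#'
#' @param pwms named list of [pwm()] objects.
#' @param path output path.
#' @param nsites count scale.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pwms, path, nsites = 100) {
  if (inherits(pwms, "pwm")) pwms <- list(motif1 = pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    m <- unclass(pwms[[id]]) * nsites
    writeLines(sprintf(">%s %s", id, id), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", .ALPHABET[b],
                         paste(sprintf("%.6f", m[, b]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write motifs in MEME minimal motif format
#'
#' @param pwms named list of [pwm()] objects.
#' @param path output path.
#' @param bg_freqs background letter frequencies (A, C, G, T).
#' @param nsites number of contributing sites recorded per motif.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path, bg_freqs = rep(0.25, 4), nsites = 20) {
  if (inherits(pwms, "pwm")) pwms <- list(motif1 = pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", ""), con)
  writeLines(sprintf("Background letter frequencies\nA %.5f C %.5f G %.5f T %.5f",
                     bg_freqs[1], bg_freqs[2], bg_freqs[3], bg_freqs[4]), con)
  for (id in names(pwms)) {
    m <- unclass(pwms[[id]])
    writeLines(c("", sprintf("MOTIF %s", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(m), nsites)), con)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
  }
  invisible(path)
}
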