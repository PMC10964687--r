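#' Six similarity/distance metrics between two probability columns
#'
#' For 4-vectors `a`, `b` summing to 1: Euclidean distance
#' `sqrt(sum((a-b)^2))`, Manhattan distance `sum(|a-b|)`, Bhattacharyya
#' coefficient `sum(sqrt(a*b))`, Hellinger distance `sqrt(1 - bha)`,
#' Sandelin-Wasserman similarity `2 - sum((a-b)^2)`, and the Pearson
#' correlation of the two vectors. Two equal constant columns have
#' `pcc = 1` (zero-variance convention); constant but unequal, `pcc = 0`.
#'
#' @param a,b probability 4-vectors (sum to 1 within 1e-6).
#' @return named numeric vector `euc`, `man`, `hell`, `pcc`, `bha`, `sw`.
#' @export
compare_columns <- function(a, b) {
  stopifnot(length(a) == 4, length(b) == 4)
  if (abs(sum(a) - 1) > 1e-6 || abs(sum(b) - 1) > 1e-6) {
    stop("columns must be normalized probability vectors")
  }
  d2 <- sum((a - b)^2)
  bha <- min(sum(sqrt(a * b)), 1)
  pcc <- if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    if (max(abs(a - b)) < 1e-12) 1 else 0
  } else {
    cor(a, b)
  }
  c(euc = sqrt(d2), man = sum(abs(a - b)), hell = sqrt(1 - bha),
    pcc = pcc, bha = bha, sw = 2 - d2)
}

#' Compare two equal-width PWMs column by column
#'
#' Each metric is the unweighted mean of its per-column values. An
#' identical pair scores `(euc 0, man 0, hell 0, pcc 1, bha 1, sw 2)`.
#'
#' @param a,b [pwm()] objects of equal width.
#' @return named numeric vector of the six averaged metrics (class
#'   `metrics_report`).
#' @export
compare_pwms <- function(a, b) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  if (nrow(a) != nrow(b)) {
    stop("PWM widths differ (", nrow(a), " vs ", nrow(b),
         "); align with align_to_reference() first")
  }
  cols <- vapply(seq_len(nrow(a)), function(j)
    compare_columns(unclass(a)[j, ], unclass(b)[j, ]), numeric(6))
  structure(rowMeans(cols), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Align a discovered PWM to a reference and score the best alignment
#'
#' Scans every ungapped offset with at least `min_overlap` overlapping
#' columns, for the query as-is and reverse-complemented, and keeps the
#' alignment maximizing the mean Bhattacharyya coefficient over the
#' overlap. Needed because discovered motifs and database references
#' rarely share a width.
#'
#' @param query,ref [pwm()] objects.
#' @param min_overlap minimum overlapping columns (>= 4).
#' @return list with `alignment` (fields `offset` — position of the first
#'   query column relative to the first reference column, `strand`,
#'   `overlap`) and `metrics` (a `metrics_report` over the overlap).
#' @export
align_to_reference <- function(query, ref, min_overlap = 4L) {
  stopifnot(inherits(query, "pwm"), inherits(ref, "pwm"), min_overlap >= 4)
  kq <- nrow(query)
  kr <- nrow(ref)
  if (min(kq, kr) < min_overlap) stop("no offset achieves min_overlap")
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else reverse_complement_pwm(query)
    for (off in (-(kq - min_overlap)):(kr - min_overlap)) {
      qi <- seq_len(kq) + off       # query columns in reference coordinates
      keep <- qi >= 1 & qi <= kr
      if (sum(keep) < min_overlap) next
      sub_q <- pwm(unclass(q)[keep, , drop = FALSE])
      sub_r <- pwm(unclass(ref)[qi[keep], , drop = FALSE])
      rep <- compare_pwms(sub_q, sub_r)
      if (is.null(best) || rep[["bha"]] > best$metrics[["bha"]]) {
        best <- list(alignment = list(offset = off, strand = strand,
                                      overlap = sum(keep)),
                     metrics = rep)
      }
    }
  }
  if (is.null(best)) stop("no offset achieves min_overlap")
  best
}

#' Write a metrics report table as TSV
#'
#' @param reports named list of `metrics_report` vectors (one per
#'   query/reference pair).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) as.data.frame(as.list(unclass(r)))))
  df <- cbind(pair = names(reports), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
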