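#' Build the sparse motif trie (SMT)
#'
#' Inserts every k-window of every sequence into a trie stored as a growable
#' node table `M` with 6 columns per node: child pointers for A, C, G, T,
#' the terminal count, and the 2-bit numeric code of the spelled k-mer
#' (exact for `k <= 26`, `NA` beyond). The root is node 1; inserting an
#' already-present k-mer only increments the terminal count and appends the
#' window address. Windows containing `N` are skipped; sequences shorter
#' than `k` contribute nothing.
#'
#' @param dataset a [seq_dataset()].
#' @param k k-mer width (a warning is issued outside the practical motif
#'   range 5..35).
#' @return An object of class `smt`: fields `M` (nu x 6 node table), `nu`,
#'   `k`, `n_windows`, `terminals` (terminal node ids) and `addresses`
#'   (per-terminal integer matrix of (sequence index 1-based, offset
#'   0-based)).
#' @export
create_smt <- function(dataset, k) {
  stopifnot(inherits(dataset, "seq_dataset"))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k < 5 || k > 35) {
    warning("k = ", k, " is outside the practical motif width range [5, 35]")
  }
  res <- smt_build(dataset$seq, k)
  res$address_index <- setNames(seq_along(res$terminals), res$terminals)
  class(res) <- "smt"
  res
}

#' @export
print.smt <- function(x, ...) {
  cat(sprintf("smt: k=%d, nu=%d nodes, %d distinct k-mers, %g windows, occupancy %.3f\n",
              x$k, x$nu, length(x$terminals), x$n_windows, occupancy(x)))
  invisible(x)
}

#' Exact k-mer lookup
#'
#' Walks the child pointers for `query`; an absent pointer anywhere on the
#' path means the k-mer was never inserted.
#'
#' @param smt an [create_smt()] trie.
#' @param query a k-mer over `{A,C,G,T}` of width `smt$k`.
#' @return list with `count` (0 if absent) and `addresses` (integer matrix
#'   of (sequence index, offset), 0 rows if absent).
#' @export
ksearch <- function(smt, query) {
  stopifnot(inherits(smt, "smt"))
  if (nchar(query) != smt$k) stop("query length must equal smt k")
  node <- smt_walk(smt$M, query)
  if (node == 0) {
    return(list(count = 0L, addresses = matrix(integer(0), 0, 2)))
  }
  list(count = as.integer(smt$M[node, 5]),
       addresses = smt$addresses[[smt$address_index[[as.character(node)]]]])
}

#' Bounded-mismatch trie search
#'
#' Depth-first recursion over the trie children: a branch is pruned as soon
#' as the accumulated mismatch count exceeds `d_max`; reaching depth k is a
#' match. With `collect = FALSE` only the existence decision is returned;
#' with `collect = TRUE` all stored k-mers within Hamming distance `d_max`
#' of the query are returned with their distances, counts and addresses.
#'
#' @param smt an [create_smt()] trie.
#' @param query a k-mer of width `smt$k`.
#' @param d_max maximum allowed mismatches (0..k).
#' @param collect return the full match set instead of a boolean?
#' @return logical scalar, or a data.frame with columns `kmer`, `count`,
#'   `distance` and a list-column `addresses`.
#' @export
kdive <- function(smt, query, d_max, collect = FALSE) {
  stopifnot(inherits(smt, "smt"))
  if (nchar(query) != smt$k) stop("query length must equal smt k")
  if (d_max < 0) stop("d_max must be >= 0")
  res <- smt_kdive(smt$M, smt$k, query, as.integer(d_max), collect)
  if (!collect) return(res$found)
  n <- length(res$node)
  counts <- if (n) as.integer(smt$M[res$node, 5]) else integer(0)
  addr <- lapply(res$node, function(nd)
    smt$addresses[[smt$address_index[[as.character(nd)]]]])
  out <- data.frame(kmer = res$kmer, count = counts,
                    distance = res$distance, stringsAsFactors = FALSE)
  out$addresses <- addr
  out
}

#' SMT child-cell occupancy
#'
#' Fraction of non-empty cells among the four child-pointer columns over
#' all allocated node rows: `nnz / (4 * nu)`. For trees built from typical
#' DNA this stays below the analytic average level of one half (each node
#' has between 0 and 4 children, 2 on average in the balanced argument).
#'
#' @param smt an [create_smt()] trie.
#' @return a fraction in `[0, 1]`.
#' @export
occupancy <- function(smt) {
  stopifnot(inherits(smt, "smt"))
  sum(smt$M[, 1:4] != 0) / (4 * smt$nu)
}

#' List all stored k-mers with counts
#'
#' @param smt an [create_smt()] trie.
#' @return data.frame with columns `kmer`, `count`, `node`.
#' @export
smt_table <- function(smt) {
  stopifnot(inherits(smt, "smt"))
  res <- smt_kmers(smt$M, smt$k)
  data.frame(kmer = res$kmer, count = as.integer(res$count),
             node = res$node, stringsAsFactors = FALSE)
}

# Decode the numeric 2-bit code of a terminal back to its k-mer (k <= 26).
decode_kmer <- function(code, k) {
  out <- character(k)
  for (j in k:1) {
    out[j] <- .ALPHABET[code %% 4 + 1]
    code <- code %/% 4
  }
  paste0(out, collapse = "")
}

#' Enriched k-mer extraction
#'
#' For every stored k-mer `w`, the expected count under the background is
#' the number of scanned windows times `P(w | beta)`; the p-value is the
#' one-sided binomial tail of the observed count, and q-values come from
#' Benjamini-Hochberg over all stored k-mers. Records are sorted by
#' ascending q-value, then descending observed count, then k-mer.
#'
#' @param smt an [create_smt()] trie.
#' @param bg a [fit_background()] model.
#' @param alpha q-value threshold in (0, 1).
#' @param top maximum number of records returned.
#' @return data.frame with columns `kmer`, `observed`, `expected`,
#'   `p_value`, `q_value`.
#' @export
extract_enriched <- function(smt, bg, alpha = 0.001, top = Inf) {
  stopifnot(inherits(smt, "smt"), inherits(bg, "markov_bg"),
            alpha > 0, alpha < 1)
  tab <- smt_table(smt)
  if (!nrow(tab)) {
    return(data.frame(kmer = character(0), observed = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  m <- smt$n_windows
  pw <- exp(bg_kmer_logprob(tab$kmer, bg))
  expected <- m * pw
  p <- pbinom(tab$count - 1, size = m, prob = pmin(pw, 1), lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(kmer = tab$kmer, observed = tab$count, expected = expected,
                    p_value = p, q_value = q, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, -out$observed, out$kmer), , drop = FALSE]
  out <- out[out$q_value <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = top)
}

#' Greedy neighborhood grouping of enriched k-mers
#'
#' Repeatedly takes the most significant remaining k-mer, aggregates the
#' counts of all stored k-mers within Hamming distance `d` of it (via
#' [kdive()] with `collect = TRUE`), removes the whole neighborhood from
#' consideration, and repeats until `n_seeds` seeds are produced or the
#' list is exhausted. Neighborhoods of returned seeds are pairwise disjoint.
#'
#' @param smt an [create_smt()] trie.
#' @param enriched output of [extract_enriched()].
#' @param d neighborhood Hamming radius.
#' @param n_seeds maximum number of seeds.
#' @return the selected rows of `enriched` with `observed` replaced by the
#'   aggregated neighborhood count, plus a list-column `neighborhood`.
#' @export
group_seeds <- function(smt, enriched, d = 2L, n_seeds = 10L) {
  stopifnot(inherits(smt, "smt"), d >= 0)
  if (!nrow(enriched)) return(enriched)
  remaining <- enriched
  picked <- list()
  while (nrow(remaining) > 0 && length(picked) < n_seeds) {
    seedrow <- remaining[1L, , drop = FALSE]
    if (d == 0) {
      nb <- seedrow$kmer
    } else {
      matches <- kdive(smt, seedrow$kmer, d_max = d, collect = TRUE)
      nb <- matches$kmer
      seedrow$observed <- sum(matches$count)
    }
    seedrow$neighborhood <- list(nb)
    picked[[length(picked) + 1L]] <- seedrow
    remaining <- remaining[!(remaining$kmer %in% nb), , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo cost of the bounded-mismatch search
#'
#' The per-fragment comparison count of the trie search stops at the d-th
#' mismatch, each comparison being a mismatch with probability `p`
#' independently: the count is negative-binomial with mean `d / p`. This
#' simulates `reps` fragments and returns the mean number of comparisons.
#'
#' @param d number of allowed mutations (stop at the d-th mismatch), >= 1.
#' @param p per-comparison mismatch probability in (0, 1].
#' @param reps number of simulated fragments.
#' @param seed integer seed.
#' @return list with `mean`, `se` (standard error of the mean) and `reps`.
#' @export
simulate_kdive_cost <- function(d, p, reps = 1e6, seed = 42L) {
  stopifnot(d >= 1, p > 0, p <= 1, reps >= 1)
  set.seed(seed)
  # comparisons = d mismatches + matches drawn before the d-th mismatch
  x <- d + rnbinom(reps, size = d, prob = p)
  list(mean = mean(x), se = stats::sd(x) / sqrt(reps), reps = reps)
}

#' Write an enriched k-mer table as TSV
#'
#' @param enriched output of [extract_enriched()] or [group_seeds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enriched_tsv <- function(enriched, path) {
  cols <- intersect(c("kmer", "observed", "expected", "p_value", "q_value"),
                    names(enriched))
  write.table(enriched[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
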