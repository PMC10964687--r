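#' Fit an order-r Markov background model
#'
#' The negative (background) model used everywhere downstream: smoothed
#' relative frequencies of (context, symbol) transitions pooled over all
#' sequences. Tables are kept for every context length `0..order`, so the
#' first `order` positions of a sequence are scored and sampled with the
#' longest context available. Windows containing `N` are skipped.
#'
#' @param dataset a [seq_dataset()].
#' @param order nonnegative Markov order `r` (at most 8).
#' @param pseudocount value added to every (context, symbol) cell before
#'   normalization; `0.01` by default.
#' @return An object of class `markov_bg` with fields `order`, `initial`
#'   (probability vector over the `4^r` contexts), `trans` (list of
#'   transition matrices, one per context length `0..r`) and `pseudocount`.
#' @export
fit_background <- function(dataset, order = 2L, pseudocount = 0.01) {
  stopifnot(inherits(dataset, "seq_dataset"), order >= 0, order <= 8,
            pseudocount >= 0)
  seqs <- dataset$seq
  if (!any(nchar(seqs) >= order + 1)) {
    stop("no sequence long enough to contain a full order-", order, " context")
  }
  trans <- vector("list", order + 1L)
  for (L in 0:order) {
    ctxs <- all_contexts(L)
    counts <- matrix(pseudocount, nrow = length(ctxs), ncol = 4,
                     dimnames = list(ctxs, .ALPHABET))
    raw <- matrix(0, nrow = length(ctxs), ncol = 4, dimnames = list(ctxs, .ALPHABET))
    for (s in seqs) {
      t <- nchar(s)
      if (t < L + 1) next
      win <- substring(s, 1:(t - L), (L + 1):t)
      win <- win[!grepl("N", win, fixed = TRUE)]
      if (!length(win)) next
      ctx <- substr(win, 1, L)
      sym <- substr(win, L + 1, L + 1)
      tab <- table(factor(ctx, levels = ctxs), factor(sym, levels = .ALPHABET))
      raw <- raw + unclass(tab)
    }
    counts <- counts + raw
    rs <- rowSums(counts)
    zero <- rs == 0
    counts[zero, ] <- 1 # unseen context with no smoothing: uniform
    trans[[L + 1L]] <- counts / rowSums(counts)
  }
  ctxs <- all_contexts(order)
  init_counts <- rep(pseudocount, length(ctxs))
  names(init_counts) <- ctxs
  for (s in seqs) {
    t <- nchar(s)
    if (t < order || order == 0) next
    win <- substring(s, 1:(t - order + 1), order:t)
    win <- win[!grepl("N", win, fixed = TRUE)]
    if (length(win)) {
      tab <- table(factor(win, levels = ctxs))
      init_counts <- init_counts + as.numeric(tab)
    }
  }
  if (order == 0) init_counts <- setNames(1, "")
  if (sum(init_counts) == 0) init_counts[] <- 1
  structure(
    list(order = as.integer(order), initial = init_counts / sum(init_counts),
         trans = trans, pseudocount = pseudocount),
    class = "markov_bg"
  )
}

all_contexts <- function(L) {
  if (L == 0) return("")
  do.call(paste0, rev(expand.grid(rep(list(.ALPHABET), L),
                                  stringsAsFactors = FALSE)))
}

#' @export
print.markov_bg <- function(x, ...) {
  cat(sprintf("markov_bg: order %d, %d contexts\n", x$order, nrow(x$trans[[x$order + 1L]])))
  invisible(x)
}

#' Log-probability of k-mers under a background model
#'
#' Each position is conditioned on the longest available preceding context
#' (up to the model order). Vectorized over k-mers.
#'
#' @param kmers character vector of equal-width k-mers over `{A,C,G,T}`.
#' @param bg a [fit_background()] model.
#' @return numeric vector of log-probabilities.
#' @export
bg_kmer_logprob <- function(kmers, bg) {
  stopifnot(inherits(bg, "markov_bg"))
  if (!length(kmers)) return(numeric(0))
  k <- nchar(kmers[1])
  stopifnot(all(nchar(kmers) == k))
  r <- bg$order
  lp <- numeric(length(kmers))
  for (j in seq_len(k)) {
    L <- min(j - 1L, r)
    tab <- bg$trans[[L + 1L]]
    ctx <- substr(kmers, j - L, j - 1L)
    sym <- substr(kmers, j, j)
    lp <- lp + log(tab[cbind(match(ctx, rownames(tab)), match(sym, .ALPHABET))])
  }
  lp
}

# Per-position log background probabilities of one sequence.
# Returns list(lp, valid_sym): N positions get lp = 0 and valid_sym = FALSE
# (windows covering them are invalidated by the caller); a context containing
# N falls back to the order-0 marginal.
position_log_probs <- function(sequence, bg) {
  t <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bidx <- match(chars, .ALPHABET)
  valid_sym <- !is.na(bidx)
  r <- bg$order
  j <- seq_len(t)
  L <- pmin(j - 1L, r)
  ctx <- substring(sequence, j - L, j - 1L)
  lp <- numeric(t)
  for (Lv in unique(L)) {
    sel <- which(L == Lv & valid_sym)
    if (!length(sel)) next
    tab <- bg$trans[[Lv + 1L]]
    ridx <- match(ctx[sel], rownames(tab))
    bad <- is.na(ridx)
    if (any(bad)) {
      lp[sel[bad]] <- log(bg$trans[[1L]][1L, bidx[sel[bad]]])
      ridx <- ridx[!bad]
      sel <- sel[!bad]
    }
    if (length(sel)) lp[sel] <- log(tab[cbind(ridx, bidx[sel])])
  }
  list(lp = lp, valid_sym = valid_sym)
}

#' Markov shuffle of a dataset
#'
#' Fits an order-`order` chain on the dataset (unsmoothed, so only observed
#' transitions can be emitted) and samples a new dataset with identical
#' sequence count and widths.
#'
#' @param dataset a [seq_dataset()].
#' @param order Markov order.
#' @param seed integer seed; the operation is reproducible under a fixed seed.
#' @return A [seq_dataset()] of background sequences.
#' @export
markov_shuffle <- function(dataset, order = 2L, seed = 42L) {
  stopifnot(inherits(dataset, "seq_dataset"))
  bg <- fit_background(dataset, order = order, pseudocount = 0)
  set.seed(seed)
  seqs <- vapply(dataset$widths, function(t) sample_markov_seq(t, bg),
                 character(1))
  seq_dataset(paste0("shuf_", seq_along(seqs)), seqs)
}

# Sample one sequence of length t from a markov_bg model, conditioning each
# position on the longest available preceding context.
sample_markov_seq <- function(t, bg) {
  r <- bg$order
  if (t == 0) return("")
  if (r == 0) {
    p <- bg$trans[[1L]][1L, ]
    return(paste0(sample(.ALPHABET, t, replace = TRUE, prob = p), collapse = ""))
  }
  out <- character(t)
  for (j in seq_len(t)) {
    L <- min(j - 1L, r)
    ctx <- if (L > 0) paste0(out[(j - L):(j - 1L)], collapse = "") else ""
    tab <- bg$trans[[L + 1L]]
    p <- tab[match(ctx, rownames(tab)), ]
    if (anyNA(p)) p <- bg$trans[[1L]][1L, ]
    out[j] <- sample(.ALPHABET, 1L, prob = p)
  }
  paste0(out, collapse = "")
}

#' Eulerian k-let preserving shuffle
#'
#' Permutes a sequence so that the multiset of `klet`-length substrings is
#' exactly preserved (Eulerian-path shuffle on the (klet-1)-mer graph,
#' Altschul-Erickson style); the first and last `(klet-1)`-mers are kept.
#' Inputs containing `N` are segmented at the `N` runs and each segment of
#' length `>= klet` is shuffled independently.
#'
#' @param sequence a DNA string.
#' @param klet k-let size, at least 2 (2 = dinucleotide shuffle).
#' @param seed integer seed.
#' @return The shuffled string.
#' @export
euler_shuffle <- function(sequence, klet = 2L, seed = 42L) {
  stopifnot(is.character(sequence), length(sequence) == 1, klet >= 2)
  if (nchar(sequence) < klet) stop("sequence shorter than klet")
  set.seed(seed)
  if (grepl("N", sequence, fixed = TRUE)) {
    parts <- strsplit(sequence, "(?<=N)(?=[^N])|(?<=[^N])(?=N)", perl = TRUE)[[1]]
    parts <- vapply(parts, function(p) {
      if (startsWith(p, "N") || nchar(p) < klet) p else euler_shuffle_core(p, klet)
    }, character(1), USE.NAMES = FALSE)
    return(paste0(parts, collapse = ""))
  }
  euler_shuffle_core(sequence, klet)
}

# Altschul-Erickson shuffle: pick a random last-out-edge per vertex forming
# an arborescence into the final vertex, permute the remaining out-edges,
# then walk the Eulerian path.
euler_shuffle_core <- function(sequence, klet) {
  t <- nchar(sequence)
  L <- klet - 1L
  nv <- t - L + 1L # number of vertex visits
  verts <- substring(sequence, 1:nv, L:(L + nv - 1L))
  if (nv < 2) return(sequence)
  from <- verts[-nv]
  to <- verts[-1L]
  vnames <- unique(verts)
  v_end <- verts[nv]
  out_edges <- split(to, factor(from, levels = vnames))
  need_last <- setdiff(vnames[vapply(out_edges, length, 1L) > 0], v_end)
  # successor lookup for arborescence check
  repeat {
    last_edge <- vapply(need_last, function(v) {
      es <- out_edges[[v]]
      es[[sample.int(length(es), 1L)]]
    }, character(1))
    if (is_arborescence(need_last, last_edge, v_end)) break
  }
  # order out-edges: random permutation, chosen last edge at the end
  ordered <- lapply(vnames, function(v) {
    es <- out_edges[[v]]
    if (!length(es)) return(es)
    if (v %in% need_last) {
      le <- last_edge[[v]]
      i <- match(le, es)
      es <- c(sample(es[-i]), le)
    } else {
      es <- sample(es)
    }
    es
  })
  names(ordered) <- vnames
  nxt <- vapply(ordered, function(e) 1L, 1L)
  path <- character(nv)
  path[1] <- verts[1]
  cur <- verts[1]
  for (i in 2:nv) {
    e <- ordered[[cur]][nxt[[cur]]]
    nxt[[cur]] <- nxt[[cur]] + 1L
    path[i] <- e
    cur <- e
  }
  paste0(path[1], paste0(substr(path[-1], L, L), collapse = ""), collapse = "")
}

# Do the chosen last-edges form a tree directed toward v_end?
is_arborescence <- function(vs, last_edge, v_end) {
  for (v in vs) {
    seen <- character(0)
    cur <- v
    while (cur != v_end) {
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      if (!cur %in% names(last_edge)) return(FALSE)
      cur <- last_edge[[cur]]
    }
  }
  TRUE
}

#' Write a background model as a plain-text table
#'
#' Format: a header line `ORDER r`, then one line per context (tab-separated:
#' context, then the four probabilities in A,C,G,T order) for every context
#' length `0..r`, the empty context written as `.`; finally an `INITIAL`
#' section with one line per order-r context and its initial probability.
#'
#' @param bg a [fit_background()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "markov_bg"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ORDER %d", bg$order), con)
  for (L in 0:bg$order) {
    tab <- bg$trans[[L + 1L]]
    ctx <- rownames(tab)
    ctx[ctx == ""] <- "."
    writeLines(sprintf("%s\t%.10g\t%.10g\t%.10g\t%.10g",
                       ctx, tab[, 1], tab[, 2], tab[, 3], tab[, 4]), con)
  }
  writeLines("INITIAL", con)
  ctx <- names(bg$initial)
  ctx[ctx == ""] <- "."
  writeLines(sprintf("%s\t%.10g", ctx, bg$initial), con)
  invisible(path)
}

#' Read a background model written by [write_background()]
#'
#' @param path input path.
#' @return A `markov_bg` model.
#' @export
read_background <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ORDER [0-9]+$", lines[1])) stop("malformed background file header")
  order <- as.integer(sub("^ORDER ", "", lines[1]))
  ini_at <- match("INITIAL", lines)
  ctx_lines <- lines[2:(ini_at - 1L)]
  fields <- strsplit(ctx_lines, "\t", fixed = TRUE)
  ctxs <- vapply(fields, `[[`, character(1), 1L)
  ctxs[ctxs == "."] <- ""
  probs <- t(vapply(fields, function(f) as.numeric(f[2:5]), numeric(4)))
  trans <- vector("list", order + 1L)
  for (L in 0:order) {
    sel <- nchar(ctxs) == L
    tab <- probs[sel, , drop = FALSE]
    dimnames(tab) <- list(ctxs[sel], .ALPHABET)
    trans[[L + 1L]] <- tab
  }
  ini_lines <- lines[(ini_at + 1L):length(lines)]
  fields <- strsplit(ini_lines, "\t", fixed = TRUE)
  ini <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  names(ini) <- vapply(fields, `[[`, character(1), 1L)
  names(ini)[names(ini) == "."] <- ""
  structure(list(order = order, initial = ini, trans = trans, pseudocount = NA_real_),
            class = "markov_bg")
}
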