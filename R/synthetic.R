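#' Planted-motif dataset specification
#'
#' @param n number of sequences.
#' @param t sequence width.
#' @param k motif width.
#' @param d maximum mutations per implanted instance; each instance mutates
#'   exactly `j` positions with `j` drawn uniformly from `0..d`, so the
#'   Hamming bound is a hard invariant of the truth.
#' @param model occurrence model: every sequence gets one instance
#'   (`"oops"`), a Bernoulli(`gamma`) coin decides presence (`"zoops"`), or
#'   a Poisson(`gamma`) count truncated to what fits without overlap
#'   (`"anr"`).
#' @param gamma occurrence probability (zoops) or expected per-sequence
#'   instance count (anr).
#' @param background `"uniform"` or a [fit_background()] model to sample
#'   background sequence from.
#' @param consensus a width-`k` string over `{A,C,G,T}` or `"random"`.
#' @param seed integer seed.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n, t, k, d = 0L, model = c("zoops", "oops", "anr"),
                       gamma = 0.9, background = "uniform",
                       consensus = "random", seed = 42L) {
  model <- match.arg(model)
  stopifnot(k <= t, d >= 0, d <= k, gamma > 0,
            model != "zoops" || gamma <= 1)
  structure(list(n = as.integer(n), t = as.integer(t), k = as.integer(k),
                 d = as.integer(d), model = model, gamma = gamma,
                 background = background, consensus = consensus,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a planted-motif dataset with ground truth
#'
#' Background sequence is sampled from the spec's background model, then
#' motif instances (the consensus mutated at exactly `j <= d` positions)
#' are implanted at uniform random non-overlapping offsets according to the
#' occurrence model. The analytic per-column base distributions implied by
#' the mutation process are returned alongside the instance list.
#'
#' @param spec a [plant_spec()].
#' @return list with `dataset` (a [seq_dataset()]) and `truth` (class
#'   `plant_truth`: `consensus`, `instances` data.frame with columns
#'   `seq_index`, `offset` (0-based), `implanted`, `n_mutations`, and
#'   `true_column_distributions`, a k x 4 matrix).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  k <- spec$k
  cons <- spec$consensus
  if (identical(cons, "random")) {
    cons <- paste0(sample(.ALPHABET, k, replace = TRUE), collapse = "")
  }
  stopifnot(nchar(cons) == k, !grepl("[^ACGT]", cons))
  seqs <- if (identical(spec$background, "uniform")) {
    vapply(seq_len(spec$n), function(i)
      paste0(sample(.ALPHABET, spec$t, replace = TRUE), collapse = ""),
      character(1))
  } else {
    stopifnot(inherits(spec$background, "markov_bg"))
    vapply(seq_len(spec$n), function(i) sample_markov_seq(spec$t, spec$background),
           character(1))
  }
  n_inst <- switch(spec$model,
    oops = rep(1L, spec$n),
    zoops = stats::rbinom(spec$n, 1L, spec$gamma),
    anr = pmin(stats::rpois(spec$n, spec$gamma), (spec$t %/% k)))
  inst <- list()
  for (i in seq_len(spec$n)) {
    if (n_inst[i] == 0) next
    offs <- sample_nonoverlapping_offsets(spec$t, k, n_inst[i])
    for (u in offs) {
      j <- sample(0:spec$d, 1L)
      implanted <- mutate_kmer(cons, j)
      substr(seqs[i], u + 1L, u + k) <- implanted
      inst[[length(inst) + 1L]] <- data.frame(
        seq_index = i, offset = u, implanted = implanted, n_mutations = j,
        stringsAsFactors = FALSE)
    }
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(seq_index = integer(0), offset = integer(0),
               implanted = character(0), n_mutations = integer(0))
  # each column mutated with probability E[j]/k, to a uniform other base
  mu <- mean(0:spec$d) / k
  cons_idx <- match(strsplit(cons, "", fixed = TRUE)[[1]], .ALPHABET)
  truth_cols <- matrix(mu / 3, nrow = k, ncol = 4, dimnames = list(NULL, .ALPHABET))
  truth_cols[cbind(seq_len(k), cons_idx)] <- 1 - mu
  truth <- structure(list(consensus = cons, instances = instances,
                          true_column_distributions = truth_cols),
                     class = "plant_truth")
  list(dataset = seq_dataset(sprintf("seq_%d", seq_len(spec$n)), seqs),
       truth = truth)
}

# Uniform random 0-based offsets for n_inst non-overlapping width-k windows.
sample_nonoverlapping_offsets <- function(t, k, n_inst) {
  for (attempt in 1:1000) {
    offs <- sort(sample.int(t - k + 1L, n_inst, replace = FALSE) - 1L)
    if (n_inst == 1L || all(diff(offs) >= k)) return(offs)
  }
  stop("could not place ", n_inst, " non-overlapping instances (t=", t, ", k=", k, ")")
}

# Mutate exactly j positions of a k-mer, each to a different base.
mutate_kmer <- function(kmer, j) {
  if (j == 0) return(kmer)
  bases <- strsplit(kmer, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(bases), j)
  for (p in pos) {
    bases[p] <- sample(setdiff(.ALPHABET, bases[p]), 1L)
  }
  paste0(bases, collapse = "")
}

#' Fraction of planted instances recovered by a motif report
#'
#' An instance counts as recovered when the report's top posterior offset
#' for its sequence lies within `slack` positions of the implanted offset.
#'
#' @param truth `truth` element of [generate_planted()].
#' @param report a `motif_report` from [run_pipeline()] (or an `em_result`,
#'   which carries the same offset fields).
#' @param slack allowed absolute offset error.
#' @return fraction in `[0, 1]`.
#' @export
count_instances_recovered <- function(truth, report, slack = 0L) {
  stopifnot(inherits(truth, "plant_truth"))
  inst <- truth$instances
  if (!nrow(inst)) stop("truth contains no instances")
  pos <- match(inst$seq_index, report$seq_index)
  ok <- !is.na(pos) &
    abs(report$top_offsets[pos] - inst$offset) <= slack
  mean(ok)
}
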