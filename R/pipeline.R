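#' Pipeline configuration
#'
#' Defaults mirror the tool's standard run configuration: neighborhood
#' radius `d = 2`, zoops occurrence model, at most 1000 EM iterations with
#' a 0.001 log-likelihood increment stop, one reported motif.
#'
#' @param input path to the peak FASTA file.
#' @param k k-mer / motif width (required; no automatic estimation).
#' @param control optional path to a control FASTA; when given it is used
#'   directly as background data instead of shuffling.
#' @param n_motifs number of motifs to report (> 1 uses occurrence masking
#'   between rounds; experimental).
#' @param d Hamming radius for seed grouping.
#' @param model occurrence model for EM.
#' @param max_iter,tol EM convergence controls (see [model_config()]).
#' @param alpha enrichment q-value threshold.
#' @param bg_order Markov order of the background model.
#' @param shuffle control-set generator when no control file is given:
#'   `"markov"` or `"euler"`.
#' @param n_seeds number of grouped seeds refined by EM.
#' @param seed integer seed for all stochastic steps.
#' @param outdir optional output directory for [write_outputs()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, k, control = NULL, n_motifs = 1L, d = 2L,
                            model = "zoops", max_iter = 1000L, tol = 0.001,
                            alpha = 0.001, bg_order = 2L,
                            shuffle = c("markov", "euler"), n_seeds = 10L,
                            seed = 42L, outdir = NULL) {
  shuffle <- match.arg(shuffle)
  stopifnot(k >= 1, n_motifs >= 1, d >= 0, n_seeds >= 1)
  structure(list(input = input, k = as.integer(k), control = control,
                 n_motifs = as.integer(n_motifs), d = as.integer(d),
                 model = model, max_iter = as.integer(max_iter), tol = tol,
                 alpha = alpha, bg_order = as.integer(bg_order),
                 shuffle = shuffle, n_seeds = as.integer(n_seeds),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' preprocess -> background -> trie counting -> enrichment -> seed grouping
#' -> EM refinement -> ranked reports. Each reported motif is the EM
#' refinement (under `config$model`) of an enriched-k-mer seed; reports are
#' ranked by final log-likelihood. For `n_motifs > 1`, windows assigned to
#' each reported motif (posterior > 0.5) are masked to `N` before the next
#' round of counting.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-loaded [seq_dataset()]; when supplied,
#'   `config$input` is not read.
#' @return list of `motif_report` objects (fields `rank`, `pwm`,
#'   `consensus`, `seed_kmer`, `aggregated_count`, `q_value`, `loglik`,
#'   `iterations`, `gamma`, `top_offsets`, `top_posterior`, `seq_index`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- if (is.null(dataset)) read_fasta(config$input) else dataset
  ds <- normalize_dataset(ds, "none")
  control <- if (!is.null(config$control)) {
    normalize_dataset(read_fasta(config$control), "none")
  } else NULL
  reports <- list()
  cur <- ds
  for (rank in seq_len(config$n_motifs)) {
    rep <- discover_one_motif(cur, config, control)
    if (is.null(rep)) break
    rep$rank <- rank
    reports[[rank]] <- rep
    if (rank < config$n_motifs) cur <- mask_occurrences(cur, rep, config$k)
  }
  if (!length(reports)) stop("no motif found")
  ord <- order(-vapply(reports, `[[`, numeric(1), "loglik"))
  reports <- reports[ord]
  for (i in seq_along(reports)) reports[[i]]$rank <- i
  reports
}

# One counting + optimization round on the current (possibly masked) data.
discover_one_motif <- function(ds, config, control) {
  bg_data <- if (!is.null(control)) {
    control
  } else if (config$shuffle == "markov") {
    markov_shuffle(ds, order = config$bg_order, seed = config$seed)
  } else {
    seqs <- vapply(seq_len(ds$n), function(i)
      euler_shuffle(ds$seq[i], klet = config$bg_order + 1L,
                    seed = config$seed + i), character(1))
    seq_dataset(ds$id, seqs)
  }
  bg <- fit_background(bg_data, order = config$bg_order)
  smt <- create_smt(ds, config$k)
  if (!length(smt$terminals)) return(NULL)
  enriched <- extract_enriched(smt, bg, alpha = config$alpha)
  if (!nrow(enriched)) {
    warning("no k-mer enriched at alpha = ", config$alpha,
            "; falling back to the most frequent k-mer")
    tab <- smt_table(smt)
    tab <- tab[order(-tab$count, tab$kmer), ]
    enriched <- data.frame(kmer = tab$kmer[1], observed = tab$count[1],
                           expected = NA_real_, p_value = NA_real_,
                           q_value = NA_real_, stringsAsFactors = FALSE)
  }
  seeds <- group_seeds(smt, enriched, d = config$d, n_seeds = config$n_seeds)
  cfg <- model_config(model = config$model, max_iter = config$max_iter,
                      tol = config$tol)
  fits <- lapply(seq_len(nrow(seeds)), function(i) {
    run_em(ds, seed_pwm(seeds$kmer[i]), bg, cfg)
  })
  best <- which.max(vapply(fits, function(f) f$trace[length(f$trace)], 0))
  fit <- fits[[best]]
  structure(list(rank = NA_integer_, pwm = fit$pwm,
                 consensus = consensus(fit$pwm),
                 seed_kmer = seeds$kmer[best],
                 aggregated_count = seeds$observed[best],
                 q_value = seeds$q_value[best],
                 loglik = fit$trace[length(fit$trace)],
                 iterations = fit$iterations, converged = fit$converged,
                 gamma = fit$gamma, trace = fit$trace,
                 top_offsets = fit$top_offsets,
                 top_posterior = fit$top_posterior,
                 seq_index = fit$seq_index),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("motif_report %d: %s (seed %s, count %s, loglik %.2f, %d iter)\n",
              x$rank, x$consensus, x$seed_kmer,
              format(x$aggregated_count), x$loglik, x$iterations))
  invisible(x)
}

# Mask confidently assigned motif windows (posterior > 0.5) to N.
mask_occurrences <- function(ds, report, k) {
  seqs <- ds$seq
  hit <- report$top_posterior > 0.5
  for (j in which(hit)) {
    i <- report$seq_index[j]
    u <- report$top_offsets[j] # 0-based
    substr(seqs[i], u + 1L, u + k) <- paste(rep("N", k), collapse = "")
  }
  seq_dataset(ds$id, seqs)
}

#' Write pipeline outputs
#'
#' Writes `motifs.meme` (MEME minimal), `motifs.jaspar` (PFM), `seeds.tsv`
#' (seed k-mer table), and `run.log` (consensus, likelihood and iteration
#' summary per motif).
#'
#' @param reports result of [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(reports, dir) {
  stopifnot(length(reports) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pwms <- setNames(lapply(reports, `[[`, "pwm"),
                   vapply(reports, function(r) sprintf("motif_%d_%s", r$rank, r$consensus),
                          character(1)))
  write_meme_motifs(pwms, file.path(dir, "motifs.meme"))
  write_jaspar_pfm(pwms, file.path(dir, "motifs.jaspar"))
  seeds <- data.frame(
    rank = vapply(reports, `[[`, integer(1), "rank"),
    seed_kmer = vapply(reports, `[[`, character(1), "seed_kmer"),
    consensus = vapply(reports, `[[`, character(1), "consensus"),
    aggregated_count = vapply(reports, function(r) as.numeric(r$aggregated_count), 0),
    q_value = vapply(reports, function(r) as.numeric(r$q_value), 0),
    loglik = vapply(reports, `[[`, numeric(1), "loglik"),
    iterations = vapply(reports, `[[`, integer(1), "iterations"))
  write.table(seeds, file.path(dir, "seeds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_lines <- c(sprintf("motiftrie run: %d motif(s)", length(reports)),
                 vapply(reports, function(r)
                   sprintf("motif %d: %s seed=%s loglik=%.4f iterations=%d converged=%s gamma=%.4f",
                           r$rank, r$consensus, r$seed_kmer, r$loglik,
                           r$iterations, r$converged, r$gamma), character(1)))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `exec/motiftrie` script. Exit codes: 0 success,
#' 2 input error, 3 no motif found.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the optparse package is required for the command line interface")
  }
  parser <- optparse::OptionParser(
    usage = "motiftrie -i peaks.fa -k INT [options] -o OUTDIR",
    option_list = list(
      optparse::make_option(c("-i", "--input"), type = "character"),
      optparse::make_option(c("-b", "--control"), type = "character", default = NULL),
      optparse::make_option(c("-k", "--kmer"), type = "integer"),
      optparse::make_option(c("-n", "--nmotifs"), type = "integer", default = 1L),
      optparse::make_option(c("-d", "--dmax"), type = "integer", default = 2L),
      optparse::make_option(c("-c", "--model"), type = "character", default = "zoops"),
      optparse::make_option(c("-r", "--maxiter"), type = "integer", default = 1000L),
      optparse::make_option(c("-f", "--tol"), type = "double", default = 0.001),
      optparse::make_option("--alpha", type = "double", default = 0.001),
      optparse::make_option("--bg-order", type = "integer", default = 2L, dest = "bg_order"),
      optparse::make_option("--shuffle", type = "character", default = "markov"),
      optparse::make_option("--seeds", type = "integer", default = 10L),
      optparse::make_option("--seed", type = "integer", default = 42L),
      optparse::make_option(c("-o", "--outdir"), type = "character")
    ))
  opt <- optparse::parse_args(parser, args = args)
  if (is.null(opt$input) || is.null(opt$kmer) || is.null(opt$outdir)) {
    message("missing required option (-i, -k, -o); see --help")
    return(invisible(2L))
  }
  config <- try(pipeline_config(
    input = opt$input, k = opt$kmer, control = opt$control,
    n_motifs = opt$nmotifs, d = opt$dmax, model = opt$model,
    max_iter = opt$maxiter, tol = opt$tol, alpha = opt$alpha,
    bg_order = opt$bg_order, shuffle = opt$shuffle, n_seeds = opt$seeds,
    seed = opt$seed, outdir = opt$outdir), silent = TRUE)
  if (inherits(config, "try-error")) {
    message(config)
    return(invisible(2L))
  }
  reports <- try(run_pipeline(config))
  if (inherits(reports, "try-error")) {
    status <- if (grepl("no motif found", attr(reports, "condition")$message)) 3L else 2L
    return(invisible(status))
  }
  write_outputs(reports, opt$outdir)
  for (r in reports) print(r)
  invisible(0L)
}
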