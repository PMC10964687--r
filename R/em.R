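#' EM run configuration
#'
#' @param model occurrence model: `"zoops"` (zero or one site per sequence,
#'   the usual choice for ChIP-seq peaks), `"oops"` (exactly one) or
#'   `"anr"` (any number, independent per-window Bernoulli occurrences).
#' @param gamma prior probability that a sequence contains the motif
#'   (zoops) or the per-window occurrence rate (anr); re-estimated at every
#'   M-step.
#' @param max_iter iteration cap.
#' @param tol stop when the log-likelihood increment between successive
#'   iterations falls below this value.
#' @param pseudocount added to every PWM cell in the M-step.
#' @return list of class `model_config`.
#' @export
model_config <- function(model = c("zoops", "oops", "anr"), gamma = 0.5,
                         max_iter = 1000L, tol = 0.001, pseudocount = 0.01) {
  model <- match.arg(model)
  stopifnot(gamma > 0, gamma <= 1, max_iter >= 1, tol > 0, pseudocount > 0)
  structure(list(model = model, gamma = gamma, max_iter = as.integer(max_iter),
                 tol = tol, pseudocount = pseudocount),
            class = "model_config")
}

#' Whole-sequence background score with sliding window sums
#'
#' Computes every position's log background probability once, the sequence
#' total, and the k-window sums by a sliding (cumulative) sum — the
#' precomputation that lets each per-offset marginal be obtained by one
#' subtraction and one addition instead of a fresh product.
#'
#' @param sequence a DNA string.
#' @param bg a [fit_background()] model.
#' @param k window width.
#' @return list with `total` (sum of all position log-probabilities),
#'   `window_sums` (length `t - k + 1`), and `valid` (logical; `FALSE` for
#'   windows containing `N`, which are excluded downstream).
#' @export
log_background_score <- function(sequence, bg, k) {
  t <- nchar(sequence)
  if (t < k) stop("sequence shorter than k")
  pl <- position_log_probs(sequence, bg)
  m <- t - k + 1L
  cs <- c(0, cumsum(pl$lp))
  nbad <- c(0, cumsum(!pl$valid_sym))
  u <- seq_len(m)
  list(total = sum(pl$lp),
       window_sums = cs[u + k] - cs[u],
       valid = (nbad[u + k] - nbad[u]) == 0)
}

#' Per-offset log marginals via the precomputed background
#'
#' `log P(s | p_u) = total - window_sums[u] + sum_j log alpha[j, s[u+j]]`:
#' the whole-sequence background product divided by the window's background
#' and multiplied by the window's PWM probability, all in log space.
#' Offsets whose window contains `N` are returned as `NA`.
#'
#' @param sequence a DNA string.
#' @param pwm a [pwm()] (the positive model).
#' @param bg a [fit_background()] model (the negative model).
#' @return numeric vector over offsets `u = 1..t-k+1`.
#' @export
log_marginal_offsets <- function(sequence, pwm, bg) {
  stopifnot(inherits(pwm, "pwm"))
  k <- nrow(pwm)
  bs <- log_background_score(sequence, bg, k)
  W <- window_codes(sequence, k)
  s <- pwm_window_scores(W, log(unclass(pwm)))
  out <- bs$total - bs$window_sums + s
  out[!bs$valid] <- NA_real_
  out
}

# m x k matrix of base codes (1..4, NA for N) for all k-windows.
window_codes <- function(sequence, k) {
  t <- nchar(sequence)
  bidx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], .ALPHABET)
  m <- t - k + 1L
  matrix(bidx[outer(seq_len(m) - 1L, seq_len(k), "+")], nrow = m, ncol = k)
}

# Sum of log PWM entries over each window row; NA rows propagate NA.
pwm_window_scores <- function(W, lpw) {
  s <- numeric(nrow(W))
  for (j in seq_len(ncol(W))) s <- s + unname(lpw[j, W[, j]])
  s
}

# One-time per-dataset precomputation shared by all EM iterations.
em_precompute <- function(dataset, k, bg) {
  keep <- which(dataset$widths >= k)
  if (length(keep) < dataset$n) {
    warning(dataset$n - length(keep), " sequence(s) shorter than k skipped")
  }
  seqs <- dataset$seq[keep]
  per <- lapply(seqs, function(s) {
    bs <- log_background_score(s, bg, k)
    W <- window_codes(s, k)
    if (!any(bs$valid)) return(NULL)
    list(W = W, win_bg = bs$window_sums, valid = bs$valid, total = bs$total)
  })
  drop <- vapply(per, is.null, TRUE)
  if (any(drop)) {
    warning(sum(drop), " sequence(s) without any N-free window skipped")
    per <- per[!drop]
    keep <- keep[!drop]
  }
  if (!length(per)) stop("no usable sequence of width >= k")
  ms <- vapply(per, function(p) length(p$win_bg), 1L)
  ends <- cumsum(ms)
  starts <- ends - ms + 1L
  list(
    seq_index = keep,
    Wall = do.call(rbind, lapply(per, `[[`, "W")),
    win_bg = unlist(lapply(per, `[[`, "win_bg")),
    valid = unlist(lapply(per, `[[`, "valid")),
    total = vapply(per, `[[`, numeric(1), "total"),
    split = Map(seq, starts, ends),
    mv = vapply(per, function(p) sum(p$valid), 1L),
    k = k
  )
}

log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Core E-step on precomputed data. Returns per-window posterior weights
# (0 at invalid windows), per-sequence absence/presence (zoops), the
# observed-data log-likelihood, and the ANR per-window rate mass.
e_step_core <- function(pre, lpw, gamma, model) {
  S <- pwm_window_scores(pre$Wall, lpw)
  w_all <- numeric(length(S))
  n <- length(pre$split)
  absence <- numeric(n)
  loglik <- 0
  for (i in seq_len(n)) {
    idx <- pre$split[[i]]
    v <- pre$valid[idx]
    iv <- idx[v]
    z <- pre$total[i] - pre$win_bg[iv] + S[iv]
    if (model == "oops") {
      li <- log_sum_exp(z) - log(pre$mv[i])
      w_all[iv] <- exp(z - log_sum_exp(z))
      loglik <- loglik + li
    } else if (model == "zoops") {
      comp <- c(log(gamma) - log(pre$mv[i]) + z, log1p(-gamma) + pre$total[i])
      li <- log_sum_exp(comp)
      w_all[iv] <- exp(comp[seq_along(z)] - li)
      absence[i] <- exp(comp[length(comp)] - li)
      loglik <- loglik + li
    } else { # anr: independent Bernoulli per window
      a <- log(gamma) + S[iv]
      b <- log1p(-gamma) + pre$win_bg[iv]
      mx <- pmax(a, b)
      lw <- mx + log(exp(a - mx) + exp(b - mx))
      w_all[iv] <- exp(a - lw)
      loglik <- loglik + sum(lw)
    }
  }
  list(w = w_all, absence = absence, loglik = loglik)
}

# Core M-step: smoothed posterior-weighted base counts per motif column,
# and the updated occurrence parameter.
m_step_core <- function(pre, est, model, pseudocount) {
  k <- pre$k
  counts <- matrix(pseudocount, nrow = k, ncol = 4)
  for (j in seq_len(k)) {
    col <- pre$Wall[, j]
    for (b in 1:4) counts[j, b] <- counts[j, b] + sum(est$w[which(col == b)])
  }
  gamma <- switch(model,
    zoops = mean(1 - est$absence),
    anr = sum(est$w) / sum(pre$mv),
    oops = NA_real_)
  list(pwm = pwm(counts / rowSums(counts)),
       gamma = min(max(gamma, 1e-6), 1 - 1e-6))
}

#' E-step of the motif EM
#'
#' Computes per-offset occurrence posteriors for the current positive model
#' under the configured occurrence model, and the observed-data
#' log-likelihood. Under oops/zoops the positional prior is uniform over
#' the valid offsets of each sequence.
#'
#' @param dataset a [seq_dataset()].
#' @param pwm a [pwm()].
#' @param bg a [fit_background()] model.
#' @param config a [model_config()].
#' @return object of class `em_state`: `posteriors` (per sequence, a vector
#'   over offsets plus an `absence` element for zoops; per-window occurrence
#'   probabilities for anr) and `loglik`.
#' @export
e_step <- function(dataset, pwm, bg, config) {
  stopifnot(inherits(pwm, "pwm"), inherits(config, "model_config"))
  pre <- em_precompute(dataset, nrow(pwm), bg)
  est <- e_step_core(pre, log(unclass(pwm)), config$gamma, config$model)
  posteriors <- lapply(seq_along(pre$split), function(i) {
    w <- est$w[pre$split[[i]]]
    if (config$model == "zoops") list(offsets = w, absence = est$absence[i])
    else w
  })
  structure(list(posteriors = posteriors, loglik = est$loglik,
                 seq_index = pre$seq_index),
            class = "em_state")
}

#' M-step of the motif EM
#'
#' Re-estimates the PWM as pseudocount-smoothed, posterior-weighted base
#' frequencies over all windows, and the occurrence parameter gamma from
#' the per-sequence presence mass (zoops) or mean window posterior (anr).
#'
#' @param dataset a [seq_dataset()].
#' @param state an [e_step()] result.
#' @param config a [model_config()].
#' @return list with elements `pwm` and `gamma`.
#' @export
m_step <- function(dataset, state, config) {
  stopifnot(inherits(state, "em_state"), inherits(config, "model_config"))
  w1 <- state$posteriors[[1]]
  k <- if (config$model == "zoops") {
    dataset$widths[state$seq_index[1]] - length(w1$offsets) + 1L
  } else {
    dataset$widths[state$seq_index[1]] - length(w1) + 1L
  }
  sub <- seq_dataset(dataset$id[state$seq_index], dataset$seq[state$seq_index])
  pre <- em_precompute(sub, k, uniform_bg())
  w_all <- unlist(lapply(state$posteriors, function(p)
    if (config$model == "zoops") p$offsets else p))
  absence <- if (config$model == "zoops")
    vapply(state$posteriors, `[[`, numeric(1), "absence") else numeric(0)
  m_step_core(pre, list(w = w_all, absence = absence), config$model,
              config$pseudocount)
}

# Uniform order-0 background (used where only window layout is needed).
uniform_bg <- function() {
  structure(list(order = 0L, initial = setNames(1, ""),
                 trans = list(matrix(0.25, 1, 4, dimnames = list("", .ALPHABET))),
                 pseudocount = 0),
            class = "markov_bg")
}

#' Run the fast EM to convergence
#'
#' Alternates E and M steps starting from a seed PWM. The per-iteration
#' score is the observed-data log-likelihood evaluated before the update;
#' iteration stops once its increment falls below `config$tol` or after
#' `config$max_iter` parameter updates.
#'
#' @param dataset a [seq_dataset()].
#' @param seed_pwm starting [pwm()] (see [seed_pwm()]).
#' @param bg a [fit_background()] model.
#' @param config a [model_config()].
#' @return object of class `em_result`: `pwm`, `gamma`, `trace` (log-
#'   likelihood per iteration), `iterations` (number of parameter updates),
#'   `converged`, and `top_offsets`/`top_posterior` (per retained sequence,
#'   the best-scoring 0-based offset and its posterior under the final
#'   model) plus `seq_index`.
#' @export
run_em <- function(dataset, seed_pwm, bg, config = model_config()) {
  stopifnot(inherits(seed_pwm, "pwm"), inherits(config, "model_config"))
  pre <- em_precompute(dataset, nrow(seed_pwm), bg)
  cur <- seed_pwm
  gamma <- config$gamma
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  est <- NULL
  for (it in seq_len(config$max_iter + 1L)) {
    est <- e_step_core(pre, log(unclass(cur)), gamma, config$model)
    trace <- c(trace, est$loglik)
    if (it > 1 && est$loglik - trace[it - 1L] < config$tol) {
      converged <- TRUE
      break
    }
    if (it > config$max_iter) break
    upd <- m_step_core(pre, est, config$model, config$pseudocount)
    cur <- upd$pwm
    if (config$model != "oops") gamma <- upd$gamma
    iterations <- it
  }
  # best offset per sequence under the final parameters
  top_off <- integer(length(pre$split))
  top_post <- numeric(length(pre$split))
  for (i in seq_along(pre$split)) {
    idx <- pre$split[[i]]
    w <- est$w[idx]
    j <- which.max(w)
    top_off[i] <- j - 1L
    top_post[i] <- w[j]
  }
  structure(list(pwm = cur, gamma = gamma, trace = trace,
                 iterations = iterations, converged = converged,
                 top_offsets = top_off, top_posterior = top_post,
                 seq_index = pre$seq_index),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("em_result: consensus %s, %d iterations (%s), loglik %.3f, gamma %.3f\n",
              consensus(x$pwm), x$iterations,
              if (x$converged) "converged" else "iteration cap",
              x$trace[length(x$trace)], x$gamma))
  invisible(x)
}
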