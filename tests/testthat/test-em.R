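test_that("seed_pwm concentrates match weight on the seed bases", {
  p <- seed_pwm("AC", 0.7)
  expect_equal(unclass(p)[1, ], c(A = 0.7, C = 0.1, G = 0.1, T = 0.1))
  expect_equal(unclass(p)[2, ], c(A = 0.1, C = 0.7, G = 0.1, T = 0.1))
  expect_true(all(abs(rowSums(unclass(p)) - 1) < 1e-12))
  expect_equal(consensus(seed_pwm("GATTAC")), "GATTAC")
  expect_error(seed_pwm("ACGN"), "outside")
})

test_that("whole-sequence background score and window sums are consistent", {
  bg <- motiftrie:::uniform_bg()
  s <- random_seqs(1, 24, seed = 2)
  bs <- log_background_score(s, bg, k = 6)
  expect_equal(bs$total, 24 * log(0.25))
  # disjoint tiling windows add up to the total when k divides t
  tiles <- bs$window_sums[seq(1, 19, by = 6)]
  expect_equal(sum(tiles), bs$total)

  ds <- random_dataset(50, 30, seed = 31)
  bg2 <- fit_background(ds, order = 2)
  for (i in 1:50) {
    s <- ds$seq[i]
    bs <- log_background_score(s, bg2, k = 7)
    lp <- naive_position_logp(s, bg2)
    expect_equal(bs$total, sum(lp), tolerance = 1e-12)
    direct <- vapply(1:(30 - 7 + 1), function(u) sum(lp[u:(u + 6)]), numeric(1))
    expect_equal(bs$window_sums, direct, tolerance = 1e-9)
  }
})

test_that("windows containing N are flagged invalid", {
  bg <- motiftrie:::uniform_bg()
  bs <- log_background_score("ACGTNACGTACG", bg, k = 4)
  expect_equal(which(!bs$valid), 2:5)
  lm <- log_marginal_offsets("ACGTNACGTACG", seed_pwm("ACGT"), bg)
  expect_true(all(is.na(lm[2:5])))
  expect_true(all(!is.na(lm[-(2:5)])))
})

test_that("fast log marginals equal the naive three-product formula", {
  ds <- random_dataset(50, 26, seed = 77)
  bg <- fit_background(ds, order = 1)
  set.seed(7)
  for (i in 1:50) {
    s <- ds$seq[i]
    p <- random_pwm(6, seed = 7000 + i)
    fast <- log_marginal_offsets(s, p, bg)
    naive <- naive_log_marginal(s, unclass(p), bg)
    expect_equal(fast, naive, tolerance = 1e-9)
  }
})

test_that("log marginal degenerates correctly at the boundaries", {
  bg <- motiftrie:::uniform_bg()
  s <- "ACGTACGT"
  # pwm equal to the background: every offset scores the sequence total
  flat <- pwm(matrix(0.25, 5, 4))
  lm <- log_marginal_offsets(s, flat, bg)
  expect_equal(lm, rep(8 * log(0.25), 4))
  # k = t: single offset, pure PWM score
  p <- random_pwm(8, seed = 3)
  lm1 <- log_marginal_offsets(s, p, bg)
  bidx <- match(strsplit(s, "")[[1]], ALPH)
  expect_equal(lm1, sum(log(unclass(p)[cbind(1:8, bidx)])))
})

test_that("e_step posteriors normalize and reduce to uniform when alpha = beta", {
  bg <- motiftrie:::uniform_bg()
  ds <- random_dataset(6, 20, seed = 12)
  flat <- pwm(matrix(0.25, 6, 4))
  st_oops <- e_step(ds, flat, bg, model_config("oops"))
  for (w in st_oops$posteriors) {
    expect_equal(w, rep(1 / 15, 15))
  }
  cfg <- model_config("zoops", gamma = 0.4)
  st_z <- e_step(ds, random_pwm(6, seed = 5), bg, cfg)
  for (p in st_z$posteriors) {
    expect_equal(sum(p$offsets) + p$absence, 1, tolerance = 1e-9)
  }
})

test_that("zoops absence posterior matches a hand-computed Bayes ratio", {
  # toy: t = 4, k = 3 (two offsets), gamma = 0.5, uniform background
  s <- "ACGT"
  bg <- motiftrie:::uniform_bg()
  p <- seed_pwm("ACG", 0.7)
  st <- e_step(seq_dataset("s", s), p, bg, model_config("zoops", gamma = 0.5))
  # hand computation, independent arithmetic:
  # P(s|p_1) = (.7*.7*.7) * .25 ; P(s|p_2) = .25 * (.1*.1*.1)
  # absence term: (1-gamma) * .25^4 ; offsets: gamma/2 * P(s|p_u)
  num1 <- 0.5 / 2 * (0.7^3 * 0.25)
  num2 <- 0.5 / 2 * (0.1^3 * 0.25)
  num0 <- 0.5 * 0.25^4
  z <- num1 + num2 + num0
  expect_equal(st$posteriors[[1]]$offsets, c(num1 / z, num2 / z), tolerance = 1e-9)
  expect_equal(st$posteriors[[1]]$absence, num0 / z, tolerance = 1e-9)
  expect_equal(st$loglik, log(z), tolerance = 1e-9)
})

test_that("m_step recovers smoothed window frequencies from hard posteriors", {
  # five sequences, posteriors concentrated at known offsets
  seqs <- c("AAACGTAA", "CCACGTCC", "GGACGTGG", "TTACGTTT", "ACACGTCA")
  ds <- seq_dataset(sprintf("s%d", 1:5), seqs)
  bg <- motiftrie:::uniform_bg()
  cfg <- model_config("oops", pseudocount = 0.01)
  k <- 4
  m <- nchar(seqs[1]) - k + 1
  posts <- lapply(1:5, function(i) { w <- numeric(m); w[3] <- 1; w })
  st <- structure(list(posteriors = posts, loglik = 0, seq_index = 1:5),
                  class = "em_state")
  upd <- m_step(ds, st, cfg)
  # all five windows at offset 3 spell ACGT
  expected <- matrix(0.01 / (5 + 0.04), 4, 4)
  expected[cbind(1:4, 1:4)] <- 5.01 / 5.04
  expect_equal(unclass(upd$pwm), expected, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(unclass(upd$pwm) > 0))
  expect_true(all(abs(rowSums(unclass(upd$pwm)) - 1) < 1e-9))
})

test_that("EM log-likelihood is nondecreasing and convergence honors tol/max_iter", {
  pl <- generate_planted(plant_spec(n = 25, t = 40, k = 6, d = 1,
                                    model = "zoops", gamma = 0.8, seed = 60))
  bg <- fit_background(markov_shuffle(pl$dataset, order = 1, seed = 60), order = 1)
  for (model in c("oops", "zoops")) {
    for (rep in 1:10) {
      start <- random_pwm(6, seed = 900 + rep)
      res <- run_em(pl$dataset, start, bg,
                    model_config(model, max_iter = 40, tol = 1e-4))
      expect_true(all(diff(res$trace) >= -1e-8))
      expect_lte(res$iterations, 40)
      if (res$converged) {
        inc <- diff(res$trace)
        expect_lt(inc[length(inc)], 1e-4)
      }
    }
  }
  # tol = Inf: exactly one parameter update
  res1 <- run_em(pl$dataset, seed_pwm(pl$truth$consensus), bg,
                 model_config("zoops", tol = Inf))
  expect_equal(res1$iterations, 1L)
  expect_true(res1$converged)
  # hard iteration cap
  res2 <- run_em(pl$dataset, random_pwm(6, seed = 1), bg,
                 model_config("zoops", max_iter = 3, tol = 1e-12))
  expect_lte(res2$iterations, 3L)
})

test_that("anr posteriors are per-window probabilities and gamma stays in range", {
  pl <- generate_planted(plant_spec(n = 15, t = 30, k = 5, d = 0,
                                    model = "anr", gamma = 1.2, seed = 19))
  bg <- motiftrie:::uniform_bg()
  st <- e_step(pl$dataset, seed_pwm(pl$truth$consensus), bg, model_config("anr"))
  for (w in st$posteriors) {
    expect_true(all(w >= 0 & w <= 1))
  }
  res <- run_em(pl$dataset, seed_pwm(pl$truth$consensus), bg,
                model_config("anr", max_iter = 20))
  expect_gt(res$gamma, 0)
  expect_lt(res$gamma, 1)
})

test_that("zoops EM recovers a planted motif's consensus", {
  pl <- generate_planted(plant_spec(n = 120, t = 60, k = 8, d = 1,
                                    model = "zoops", gamma = 0.9, seed = 77))
  bg <- fit_background(markov_shuffle(pl$dataset, order = 0, seed = 77), order = 0)
  res <- run_em(pl$dataset, seed_pwm(pl$truth$consensus), bg,
                model_config("zoops"))
  expect_equal(consensus(res$pwm), pl$truth$consensus)
  expect_gt(res$gamma, 0.7)
})
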