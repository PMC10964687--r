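toy_tree <- function() {
  suppressWarnings(create_smt(seq_dataset("s", "ACGTACGAT"), k = 4))
}

test_that("the worked single-sequence tree inserts six overlapping k-mers", {
  smt <- toy_tree()
  expect_equal(smt$n_windows, 6)
  expect_equal(sum(smt$M[smt$terminals, 5]), 6)
  expect_equal(length(smt$terminals), 6L) # all six 4-mers distinct here
  expect_equal(smt$M[1, 1], 2) # root's first child is node 2
})

test_that("re-inserting an existing k-mer increments its count, creating no nodes", {
  smt1 <- suppressWarnings(create_smt(seq_dataset("s", "ACGT"), k = 4))
  smt2 <- suppressWarnings(create_smt(seq_dataset(c("s", "t"), c("ACGT", "ACGT")), k = 4))
  expect_equal(smt2$nu, smt1$nu)
  expect_equal(ksearch(smt2, "ACGT")$count, 2L)
  expect_equal(ksearch(smt2, "ACGT")$addresses,
               matrix(c(1L, 2L, 0L, 0L), 2, 2))
})

test_that("empty or too-short input yields a root-only tree", {
  smt <- suppressWarnings(create_smt(seq_dataset("s", "ACG"), k = 4))
  expect_equal(smt$nu, 1)
  expect_equal(length(smt$terminals), 0L)
  expect_error(create_smt(seq_dataset("s", "ACGT"), k = 0), "k must be")
  expect_warning(create_smt(seq_dataset("s", "ACGTACGAT"), k = 4), "range")
})

test_that("terminal counts equal dictionary counts on random data", {
  ds <- random_dataset(50, 30, seed = 101)
  smt <- create_smt(ds, k = 6)
  oracle <- dict_count_oracle(ds$seq, 6)
  tab <- smt_table(smt)
  expect_equal(nrow(tab), length(oracle))
  expect_equal(setNames(tab$count, tab$kmer)[names(oracle)], oracle)
  # conservation: totals match the number of inserted windows
  expect_equal(sum(tab$count), smt$n_windows)
  expect_equal(smt$n_windows, sum(pmax(ds$widths - 6 + 1, 0)))
})

test_that("N-containing windows are skipped in construction", {
  ds <- seq_dataset("s", "ACGTNACGTA")
  smt <- create_smt(ds, k = 5)
  oracle <- dict_count_oracle(ds$seq, 5)
  tab <- smt_table(smt)
  expect_equal(sort(tab$kmer), sort(names(oracle)))
  expect_equal(smt$n_windows, length(oracle))
})

test_that("terminal numeric codes decode to the spelled k-mer path", {
  ds <- random_dataset(10, 25, seed = 55)
  smt <- create_smt(ds, k = 7)
  tab <- smt_table(smt)
  codes <- smt$M[tab$node, 6]
  decoded <- vapply(codes, motiftrie:::decode_kmer, character(1), k = 7)
  expect_equal(decoded, tab$kmer)
})

test_that("ksearch walks to the stored count and addresses", {
  smt <- toy_tree()
  hit <- ksearch(smt, "ACGT")
  expect_equal(hit$count, 1L)
  expect_equal(hit$addresses, matrix(c(1L, 0L), 1, 2))
  expect_equal(ksearch(smt, "TTTT")$count, 0L)
  expect_error(ksearch(smt, "ACGTA"), "length")

  ds <- random_dataset(20, 20, seed = 77)
  tree <- create_smt(ds, k = 5)
  oracle <- dict_count_oracle(ds$seq, 5)
  for (w in names(oracle)) {
    expect_equal(ksearch(tree, w)$count, unname(oracle[[w]]))
  }
})

test_that("kdive at d_max = 0 reproduces the exact-search decision", {
  ds <- random_dataset(15, 18, seed = 42)
  tree <- create_smt(ds, k = 6)
  set.seed(1)
  for (i in 1:50) {
    q <- paste0(sample(ALPH, 6, replace = TRUE), collapse = "")
    expect_equal(kdive(tree, q, d_max = 0), ksearch(tree, q)$count > 0)
  }
})

test_that("a stored 10-mer is found with a mismatch budget of two", {
  ds <- random_dataset(10, 40, seed = 9)
  tree <- create_smt(ds, k = 10)
  s <- smt_table(tree)$kmer[1]
  expect_true(kdive(tree, s, d_max = 2))
  expect_error(kdive(tree, s, d_max = -1), "d_max")
})

test_that("kdive(collect) equals the brute-force Hamming ball on random trees", {
  set.seed(500)
  for (i in 1:100) {
    k <- sample(4:8, 1)
    d <- sample(0:2, 1)
    ds <- random_dataset(sample(3:10, 1), sample((k + 2):25, 1), seed = 1000 + i)
    tree <- suppressWarnings(create_smt(ds, k = k))
    stored <- smt_table(tree)
    q <- paste0(sample(ALPH, k, replace = TRUE), collapse = "")
    got <- kdive(tree, q, d_max = d, collect = TRUE)
    expect_equal(sort(got$kmer), hamming_ball_oracle(stored$kmer, q, d))
    # distances and counts agree with direct recomputation
    expect_equal(got$distance, vapply(got$kmer, hamming, 1L, b = q),
                 ignore_attr = TRUE)
    expect_equal(got$count,
                 stored$count[match(got$kmer, stored$kmer)])
  }
})

test_that("kdive match sets grow with the mismatch budget and exhaust at d = k", {
  ds <- random_dataset(8, 20, seed = 321)
  tree <- suppressWarnings(create_smt(ds, k = 6))
  q <- "ACGTAC"
  prev <- character(0)
  for (d in 0:3) {
    cur <- kdive(tree, q, d_max = d, collect = TRUE)$kmer
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  full <- kdive(tree, q, d_max = 6, collect = TRUE)
  expect_equal(sort(full$kmer), sort(smt_table(tree)$kmer))
})

test_that("occupancy counts occupied child cells over allocated rows", {
  one <- suppressWarnings(create_smt(seq_dataset("s", "ACGT"), k = 4))
  expect_equal(one$nu, 5)
  expect_equal(occupancy(one), 4 / 20)

  all1 <- suppressWarnings(create_smt(seq_dataset("s", "ACGT"), k = 1))
  expect_equal(all1$nu, 5)
  expect_equal(occupancy(all1), 4 / 20)

  big <- create_smt(random_dataset(50, 100, seed = 2), k = 8)
  expect_lt(occupancy(big), 0.5)
  expect_gt(occupancy(big), 0)
})

test_that("expected counts under a uniform background follow m * 4^-k", {
  ds <- random_dataset(10, 20, seed = 4)
  smt <- create_smt(ds, k = 5)
  bg <- motiftrie:::uniform_bg()
  enr <- extract_enriched(smt, bg, alpha = 0.999)
  expect_true(all(abs(enr$expected - 160 * 4^-5) < 1e-9))
})

test_that("a strongly planted consensus is the most significant k-mer", {
  pl <- generate_planted(plant_spec(n = 60, t = 30, k = 6, d = 0,
                                    model = "oops", seed = 8))
  smt <- create_smt(pl$dataset, k = 6)
  bg <- fit_background(markov_shuffle(pl$dataset, order = 0, seed = 8), order = 0)
  enr <- extract_enriched(smt, bg, alpha = 0.05)
  expect_equal(enr$kmer[1], pl$truth$consensus)
  # BH q-values are nondecreasing in p-value order
  byp <- enr[order(enr$p_value), ]
  expect_true(all(diff(byp$q_value) >= -1e-12))
  expect_true(all(enr$q_value >= enr$p_value))
})

test_that("group_seeds aggregates disjoint Hamming neighborhoods greedily", {
  # two k-mers at distance 1 planted on a sparse background
  ds <- seq_dataset(sprintf("s%d", 1:5),
                    c("AACCAG", "AACCAG", "AACCTG", "GGTTGA", "AACCAG"))
  smt <- suppressWarnings(create_smt(ds, k = 6))
  bg <- motiftrie:::uniform_bg()
  enr <- extract_enriched(smt, bg, alpha = 0.99)
  g1 <- group_seeds(smt, enr, d = 1, n_seeds = 10)
  expect_equal(g1$kmer[1], "AACCAG")
  expect_equal(g1$observed[1], 4) # 3 exact + 1 single-mismatch neighbor
  expect_false("AACCTG" %in% g1$kmer)
  nb <- g1$neighborhood
  for (i in seq_along(nb)) for (j in seq_len(i - 1)) {
    expect_length(intersect(nb[[i]], nb[[j]]), 0)
  }
  # d = 0 keeps records unchanged
  g0 <- group_seeds(smt, enr, d = 0, n_seeds = 2)
  expect_equal(g0$kmer, enr$kmer[1:2])
  expect_equal(g0$observed, enr$observed[1:2])
})

test_that("the simulated search cost matches the closed-form mean d/p", {
  for (d in 1:5) for (p in c(0.25, 0.5, 0.75)) {
    sim <- simulate_kdive_cost(d, p, reps = 20000, seed = d * 100 + p * 4)
    expect_lt(abs(sim$mean - d / p), 3 * sim$se)
  }
  exact <- simulate_kdive_cost(3, 1, reps = 1000, seed = 1)
  expect_equal(exact$mean, 3)
  expect_equal(exact$se, 0)
})
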