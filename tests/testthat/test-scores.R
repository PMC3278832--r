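test_that("cluster beta reproduces published count ratios", {
  pop <- toy_population(pos = c(0, 5, 144), neg = c(15, 6, 19))
  betas <- vapply(pop$clusters$clusters, cluster_beta, numeric(1))
  expect_equal(unname(betas[1]), -1)           # 15 interactions, all negative
  expect_equal(unname(betas[2]), -1 / 11)      # 5 positive vs 6 negative
  expect_equal(unname(betas[3]), 125 / 163)    # 144 positive vs 19 negative
})

test_that("mci is the interaction-weighted mean of |beta|", {
  # one pure cluster of any size
  expect_equal(mci(toy_population(pos = 7, neg = 0)$clusters), 1)
  # {n = 4, beta = 1} and {n = 6, beta = 0} -> 0.4
  expect_equal(mci(toy_population(pos = c(4, 3), neg = c(0, 3))$clusters), 0.4)
  # all balanced
  expect_equal(mci(toy_population(pos = c(2, 3), neg = c(2, 3))$clusters), 0)
  empty <- toy_population(pos = 3, neg = 0)$clusters
  empty$clusters <- list()
  expect_error(population_score(empty), "empty")
})

test_that("mci equals brute-force recomputation on random toy populations", {
  set.seed(101)
  for (r in 1:25) {
    k <- sample(1:10, 1)
    pos <- integer(k); neg <- integer(k)
    for (i in seq_len(k)) {
      n <- sample(1:12, 1)
      pos[i] <- sample(0:n, 1)
      neg[i] <- n - pos[i]
    }
    if (all(pos + neg == 0)) next
    keep <- pos + neg >= 1
    pos <- pos[keep]; neg <- neg[keep]
    got <- mci(toy_population(pos, neg)$clusters)
    oracle <- sum(abs(pos - neg)) / sum(pos + neg)
    expect_equal(got, oracle)
  }
})

test_that("mci is invariant to cluster order, sign flip, and beta-preserving splits", {
  pop <- toy_population(pos = c(6, 2, 5), neg = c(2, 6, 5),
                        eps = list(c(runif(6, 0.05, 0.3), -runif(2, 0.05, 0.3)),
                                   c(runif(2, 0.05, 0.3), -runif(6, 0.05, 0.3)),
                                   c(runif(5, 0.05, 0.3), -runif(5, 0.05, 0.3))))
  base <- mci(pop$clusters)
  reordered <- pop$clusters
  reordered$clusters <- rev(reordered$clusters)
  expect_equal(mci(reordered), base)
  # global sign flip of all epsilon
  flipped <- toy_population(pos = c(2, 6, 5), neg = c(6, 2, 5))
  expect_equal(mci(flipped$clusters),
               mci(toy_population(pos = c(6, 2, 5), neg = c(2, 6, 5))$clusters))
  # splitting a cluster into two with the same beta leaves mci unchanged
  whole <- toy_population(pos = 6, neg = 2)
  split2 <- toy_population(pos = c(3, 3), neg = c(1, 1))
  expect_equal(mci(whole$clusters), mci(split2$clusters))
})

test_that("smci handles cancellation, purity, and the equal-magnitude identity", {
  pop <- toy_population(pos = 1, neg = 1, eps = list(c(0.2, -0.2)))
  expect_equal(smci(pop$clusters), 0)
  expect_equal(smci(toy_population(pos = c(4, 3), neg = c(0, 0))$clusters), 1)
  # equal |epsilon| within clusters: smci == mci, over random sign patterns
  set.seed(77)
  for (r in 1:20) {
    k <- sample(1:4, 1)
    pos <- integer(k); neg <- integer(k)
    for (i in seq_len(k)) {
      n <- sample(1:6, 1)
      pos[i] <- sample(0:n, 1); neg[i] <- n - pos[i]
    }
    mag <- runif(1, 0.05, 0.4)
    eps <- lapply(seq_len(k), function(i) {
      c(rep(mag, pos[i]), rep(-mag, neg[i]))
    })
    pop <- toy_population(pos, neg, eps = eps)
    expect_equal(smci(pop$clusters), mci(pop$clusters))
  }
})

test_that("mp score honors its anchor contract and monotonicity", {
  bg <- structure(list(n_positive = 30, n_negative = 70,
                       f_positive = 0.3, alpha = -0.4),
                  class = "background_composition")
  cl <- function(np, nn) {
    toy_population(np, nn)$clusters$clusters[[1]]
  }
  expect_equal(mp_score(cl(8, 0), bg)$mp, 1)    # all positive
  expect_equal(mp_score(cl(0, 8), bg)$mp, -1)   # all negative
  expect_equal(mp_score(cl(3, 7), bg)$mp, 0)    # f equals background ratio
  # monotone nondecreasing in the positive fraction for fixed background
  mps <- vapply(0:10, function(np) mp_score(cl(np, 10 - np), bg)$mp, numeric(1))
  expect_true(all(diff(mps) >= 0))
  expect_true(all(mps >= -1 & mps <= 1))
  # degenerate background only admissible for pure clusters
  bg0 <- structure(list(n_positive = 0, n_negative = 10,
                        f_positive = 0, alpha = -1),
                   class = "background_composition")
  expect_error(mp_score(cl(3, 7), bg0), "degenerate")
  expect_equal(mp_score(cl(0, 5), bg0)$mp, -1)
})

test_that("monochromatic classification is strict at |MP| = 0.5", {
  fake <- function(mp) {
    structure(list(cluster_id = "c", mp = mp, monochromatic = abs(mp) > 0.5,
                   direction = if (mp > 0.5) "positive"
                               else if (mp < -0.5) "negative" else "none"),
              class = "mp_result")
  }
  counts <- classify_mp(list(fake(0.51), fake(0.5), fake(-0.7)))
  expect_equal(unname(counts["positive_monochromatic"]), 1L)
  expect_equal(unname(counts["negative_monochromatic"]), 1L)
  expect_equal(unname(counts["non_monochromatic"]), 1L)
  # through the real scorer: beta at the threshold is not monochromatic
  bg <- structure(list(n_positive = 50, n_negative = 50,
                       f_positive = 0.5, alpha = 0),
                  class = "background_composition")
  at <- mp_score(toy_population(3, 1)$clusters$clusters[[1]], bg)  # mp = 0.5
  expect_equal(at$mp, 0.5)
  expect_false(at$monochromatic)
})

test_that("highly monochromatic clusters strictly exceed the population MCI", {
  pop <- population_score(toy_population(pos = c(5, 3, 0), neg = c(5, 3, 6))$clusters)
  hm <- highly_monochromatic(pop)
  expect_equal(hm$cluster_id, "CPLX003")  # |beta| = 1 > mci
  expect_equal(hm$sign, "negative")
  expect_equal(attr(hm, "n_negative"), 1L)

  # |beta| equal to the mci exactly is excluded
  pop_eq <- population_score(toy_population(pos = c(4, 4), neg = c(2, 2))$clusters)
  expect_equal(pop_eq$mci, 1 / 3)
  expect_equal(nrow(highly_monochromatic(pop_eq)), 0)

  # all clusters pure: mci = 1 cannot be exceeded
  pure <- population_score(toy_population(pos = c(4, 0), neg = c(0, 3))$clusters)
  expect_equal(pure$mci, 1)
  expect_equal(nrow(highly_monochromatic(pure)), 0)
})
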