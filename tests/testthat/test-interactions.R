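test_that("epsilon_score implements the multiplicative deviation", {
  expect_equal(epsilon_score(0.5, 1.0, 0.5), 0)
  expect_equal(epsilon_score(0.2, 0.8, 0.5), -0.2)
  expect_equal(epsilon_score(1.0, 0.9, 0.9), 0.19)
  expect_equal(epsilon_score(c(0.5, 0.2), c(1, 0.8), c(0.5, 0.5)),
               c(0, -0.2))
  expect_error(epsilon_score(-0.1, 1, 1), "wild type")
})

test_that("read_interactions maps columns and drops unusable rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query\tarray\tscore\tpval",
               "yal001c\tYBR001C\t0.12\t0.01",
               "YAL002W\tYBR002C\t-0.30\t0.002",
               "YAL003W\tYBR003C\t0.05\t0.20",
               "YAL004W\tYBR004C\t\t0.01",       # missing score
               "YAL005C\tYAL005C\t0.10\t0.01",   # self-pair
               "YAL006W\tYBR006C\t0\t0.01"),     # zero score: sign undefined
             path)
  cmap <- list(gene_a = "query", gene_b = "array",
               epsilon = "score", p_value = "pval")
  expect_message(x <- read_interactions(path, cmap), "dropped 1 row")
  expect_s3_class(x, "interaction_set")
  expect_equal(nrow(x), 3)
  expect_equal(attr(x, "cutoff_level"), "raw")
  # identifiers are case-normalized
  expect_equal(x$gene_a[1], "YAL001C")
  expect_equal(x$sign, c("positive", "negative", "positive"))
  expect_error(read_interactions(path, list(gene_a = "nonesuch")),
               "gene_a")
})

test_that("read_interactions accepts a YAML column map", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q\ta\te\tp", "G1\tG2\t0.2\t0.01"), path)
  ymap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gene_a: q", "gene_b: a", "epsilon: e", "p_value: p"), ymap)
  x <- read_interactions(path, ymap)
  expect_equal(nrow(x), 1)
  expect_equal(x$epsilon, 0.2)
})

test_that("cutoff filters match the published thresholds", {
  x <- make_iset(gene_a = c("A", "B", "C", "D"),
                 gene_b = c("B", "C", "D", "E"),
                 epsilon = c(0.10, -0.13, 0.17, 0.20),
                 p_value = c(0.01, 0.04, 0.06, 0.01))
  kept <- function(level) {
    y <- apply_cutoff(x, level)
    paste0(y$gene_a, y$gene_b)
  }
  # (0.10, 0.01): lenient and intermediate, not stringent
  expect_true("AB" %in% kept("lenient"))
  expect_true("AB" %in% kept("intermediate"))
  expect_false("AB" %in% kept("stringent"))
  # (-0.13, 0.04): all three
  expect_true(all(c("BC") %in% kept("lenient")))
  expect_true("BC" %in% kept("intermediate"))
  expect_true("BC" %in% kept("stringent"))
  # (0.17, 0.06): p fails everywhere
  expect_false("CD" %in% kept("lenient"))
  expect_false("CD" %in% kept("stringent"))
  # (0.20, 0.01) passes stringent
  expect_true("DE" %in% kept("stringent"))
  expect_equal(attr(apply_cutoff(x, "lenient"), "cutoff_level"), "lenient")
  expect_error(apply_cutoff(apply_cutoff(x, "lenient"), "lenient"), "raw")
})

test_that("stringent calls are a subset of intermediate and lenient calls", {
  d <- generate_interaction_data(simulation_params(seed = 11, p_sig = 0.7))
  x <- d$interactions
  key <- function(y) paste(y$gene_a, y$gene_b)
  len <- key(apply_cutoff(x, "lenient"))
  int <- key(apply_cutoff(x, "intermediate"))
  str <- key(apply_cutoff(x, "stringent"))
  expect_true(all(str %in% int))
  expect_true(all(int %in% len))
})

test_that("collapse_duplicates merges concordant and removes discordant pairs", {
  x <- interaction_set(
    data.frame(gene_a = c("A", "B", "C", "D", "E"),
               gene_b = c("B", "A", "D", "C", "F"),
               epsilon = c(0.2, 0.4, 0.2, -0.2, 0.3),
               p_value = c(0.01, 0.005, 0.01, 0.01, 0.02)),
    pair_policy = "ordered")
  expect_message(y <- collapse_duplicates(x), "1 pair")
  expect_equal(attr(y, "pair_policy"), "unordered-collapsed")
  expect_equal(nrow(y), 2)  # (A,B) merged, (C,D) discordant removed, (E,F) kept
  ab <- y[y$gene_a == "A" & y$gene_b == "B", ]
  expect_equal(ab$epsilon, 0.3)
  expect_equal(ab$p_value, 0.005)
  expect_false(any(y$gene_a == "C"))
  expect_lte(nrow(y), nrow(x))
})

test_that("collapse_duplicates leaves a duplicate-free set unchanged", {
  x <- interaction_set(
    data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
               epsilon = c(0.2, -0.1), p_value = c(0.01, 0.02)),
    pair_policy = "ordered")
  y <- collapse_duplicates(x)
  expect_equal(as.data.frame(y)[c("gene_a", "gene_b", "epsilon", "p_value")],
               as.data.frame(x)[c("gene_a", "gene_b", "epsilon", "p_value")])
})

test_that("background composition counts, f_positive and alpha agree", {
  x <- make_iset(gene_a = sprintf("A%03d", 1:100),
                 gene_b = sprintf("B%03d", 1:100),
                 epsilon = c(rep(0.1, 10), rep(-0.1, 90)))
  bg <- background_composition(x)
  expect_equal(bg$f_positive, 0.1)
  expect_equal(bg$alpha, -0.8)
  expect_equal(bg$n_positive + bg$n_negative, nrow(x))
  expect_equal(bg$alpha, 2 * bg$f_positive - 1)

  balanced <- make_iset(c("A", "B"), c("C", "D"), c(0.2, -0.2))
  expect_equal(background_composition(balanced)$alpha, 0)
  allpos <- make_iset(c("A", "B"), c("C", "D"), c(0.2, 0.1))
  expect_equal(background_composition(allpos)$alpha, 1)
  expect_equal(background_composition(allpos)$f_positive, 1)
  empty <- make_iset(character(0), character(0), numeric(0), numeric(0))
  expect_error(background_composition(empty), "empty")
})

test_that("interaction_set rejects self-pairs and zero scores", {
  expect_error(make_iset("A", "a", 0.2), "self")
  expect_error(make_iset("A", "B", 0), "sign")
  expect_error(make_iset("A", "B", 0.2, p_value = 1.5), "p_value")
})
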