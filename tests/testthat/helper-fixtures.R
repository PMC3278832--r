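# Fixture builders used across the suite. Everything is constructed in code;
# no data files.

# Quick interaction set from parallel vectors.
make_iset <- function(gene_a, gene_b, epsilon, p_value = 0.01,
                      cutoff = "raw", policy = "unordered-collapsed") {
  interaction_set(data.frame(gene_a = gene_a, gene_b = gene_b,
                             epsilon = epsilon,
                             p_value = rep_len(p_value, length(epsilon)),
                             stringsAsFactors = FALSE),
                  cutoff_level = cutoff, pair_policy = policy)
}

# A population of within-complex clusters with prescribed sign counts.
# Cluster k is a star around a hub gene, so all pairs are distinct and both
# genes of every interaction sit in complex k. `eps` optionally gives the
# epsilon vector per cluster (signs must match the counts: positives first).
toy_population <- function(pos, neg, eps = NULL, p_value = 0.01) {
  stopifnot(length(pos) == length(neg))
  rows <- list()
  sets <- list()
  for (k in seq_along(pos)) {
    n <- pos[k] + neg[k]
    hub <- sprintf("H%03d", k)
    leaves <- sprintf("L%03d_%02d", k, seq_len(n))
    e <- if (is.null(eps)) c(rep(0.2, pos[k]), rep(-0.2, neg[k]))
         else eps[[k]]
    rows[[k]] <- data.frame(gene_a = hub, gene_b = leaves, epsilon = e,
                            p_value = p_value, stringsAsFactors = FALSE)
    sets[[sprintf("CPLX%03d", k)]] <- c(hub, leaves)
  }
  iset <- interaction_set(do.call(rbind, rows),
                          pair_policy = "unordered-collapsed")
  catalog <- gene_set_catalog(sets, kind = "complexes")
  list(interactions = iset, catalog = catalog,
       clusters = build_within_clusters(iset, catalog, min_interactions = 1))
}

# Exhaustive upper-tail probability of Bin(n, 1/2) by enumerating all 2^n
# equally likely sign outcomes (independent oracle for the binomial test).
enum_binom_tail <- function(n, x) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  mean(rowSums(outcomes) >= x)
}

# Expected |beta| of a cluster with n interactions and per-interaction
# majority-match probability p, by direct enumeration over Bin(n, p).
enum_expected_abs_beta <- function(n, p) {
  x <- 0:n
  sum(stats::dbinom(x, n, p) * abs(2 * x - n) / n)
}
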