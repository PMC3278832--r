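#' Exact binomial upper tail for monochromatic-complex counts
#'
#' Under the null hypothesis that each complex is equally likely to be
#' monochromatic or not, the number of monochromatic complexes among `n`
#' follows Bin(n, 0.5). The significance of observing `x` or more is the
#' exact upper tail `sum_{k=x}^{n} C(n,k) 0.5^n`.
#'
#' @param n Number of complexes in the population (>= 1).
#' @param x Number identified as monochromatic, `0 <= x <= n`.
#' @return An object of class `binom_test_result`: list with `n`, `x`,
#'   `p_value`.
#' @examples
#' binom_upper_tail(46, 46)$p_value  # 0.5^46
#' @export
binom_upper_tail <- function(n, x) {
  if (n < 1 || x < 0 || x > n) stop("need n >= 1 and 0 <= x <= n")
  p <- stats::pbinom(x - 1, size = n, prob = 0.5, lower.tail = FALSE)
  structure(list(n = as.integer(n), x = as.integer(x), p_value = p),
            class = "binom_test_result")
}

#' @export
print.binom_test_result <- function(x, ...) {
  cat(sprintf("Exact binomial test: %d / %d monochromatic, P(X >= %d) = %.4g\n",
              x$x, x$n, x$x, x$p_value))
  invisible(x)
}

#' Standardized score of an observed statistic against a null
#'
#' @param observed Observed statistic value.
#' @param mean Mean of the null distribution.
#' @param std Standard deviation of the null distribution (> 0).
#' @return `(observed - mean) / std`.
#' @export
z_score <- function(observed, mean, std) {
  if (!is.finite(std) || std <= 0) {
    stop("z-score undefined for null standard deviation <= 0")
  }
  (observed - mean) / std
}

#' Empirical upper-tail p-value against permutation replicates
#'
#' The proportion of null values at least as large as the observed statistic.
#' When no replicate reaches the observed value the display string reports
#' the resolution bound `< 1/b`. The `"add-one"` estimator
#' `(r + 1) / (b + 1)` is available as an alternative that never returns 0.
#'
#' @param observed Observed statistic.
#' @param values Numeric vector of null replicate values (or a
#'   `null_distribution`).
#' @param estimator `"proportion"` (default; ties count against significance)
#'   or `"add-one"`.
#' @return List with `p` (numeric) and `display` (string).
#' @export
empirical_p <- function(observed, values, estimator = c("proportion", "add-one")) {
  estimator <- match.arg(estimator)
  if (inherits(values, "null_distribution")) values <- values$values
  b <- length(values)
  if (b < 1) stop("need at least one null replicate")
  r <- sum(values >= observed)
  p <- if (estimator == "proportion") r / b else (r + 1) / (b + 1)
  display <- if (estimator == "proportion" && r == 0) {
    paste0("< ", format(1 / b, digits = 3))
  } else {
    format(p, digits = 3)
  }
  list(p = p, display = display)
}

statistic_from_splits <- function(sgn, eps, grp, total, statistic) {
  if (statistic == "mci") {
    sum(abs(rowsum(sgn, grp))) / total
  } else {
    net <- abs(rowsum(eps, grp))
    gross <- rowsum(abs(eps), grp)
    n_k <- rowsum(rep(1, length(grp)), grp)
    sum(n_k * net / gross) / total
  }
}

#' Permutation null distribution for MCI or sMCI
#'
#' Generates the null distribution of the population statistic by replacing
#' the interactions in each cluster with interactions drawn at random from
#' the screened pool, keeping the number of interactions in each cluster
#' fixed. By default one joint draw without replacement fills all clusters in
#' a replicate (a true permutation of interaction labels); independent
#' per-cluster draws and with-replacement sampling are available as
#' variants. Summaries (mean, sd, Z-score, empirical p) compare the observed
#' statistic with the replicates.
#'
#' @param clusters A non-empty `cluster_set` (defines the observed statistic
#'   and the fixed cluster-size multiset).
#' @param pool An [interaction_set()] of all screened interactions to resample
#'   from; must hold at least as many interactions as the clusters jointly
#'   contain unless `replace = TRUE`.
#' @param b Number of permutation replicates (default 1000).
#' @param seed Integer seed; recorded in the result so a run is reproducible.
#' @param statistic `"mci"` or `"smci"`.
#' @param replace Sample the pool with replacement.
#' @param per_cluster Draw each cluster independently instead of one joint
#'   draw per replicate.
#'
#' @return An object of class `null_distribution`: list with `values`, `b`,
#'   `seed`, `statistic`, `observed`, `mean`, `std`, `z` (`NA` and flagged
#'   via `degenerate = TRUE` when the null variance is zero), `empirical_p`,
#'   `p_display`.
#' @export
permutation_null <- function(clusters, pool, b = 1000, seed = 20111130,
                             statistic = c("mci", "smci"),
                             replace = FALSE, per_cluster = FALSE) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(pool, "interaction_set"))
  statistic <- match.arg(statistic)
  if (length(clusters) == 0) stop("empty cluster set")
  if (b < 1) stop("need b >= 1")
  sizes <- cluster_sizes(clusters)
  total <- sum(sizes)
  npool <- nrow(pool)
  if (!replace && npool < total) {
    stop(sprintf(
      "pool (%d) smaller than total cluster content (%d); use replace = TRUE",
      npool, total))
  }
  sgn <- ifelse(pool$sign == "positive", 1, -1)
  eps <- pool$epsilon
  grp <- rep.int(seq_along(sizes), sizes)
  pop <- population_score(clusters)
  observed <- if (statistic == "mci") pop$mci else pop$smci

  set.seed(as.integer(seed))
  values <- vapply(seq_len(b), function(r) {
    idx <- if (per_cluster) {
      unlist(lapply(sizes, function(n) sample.int(npool, n, replace = replace)))
    } else {
      sample.int(npool, total, replace = replace)
    }
    statistic_from_splits(sgn[idx], eps[idx], grp, total, statistic)
  }, numeric(1))

  mu <- mean(values)
  s <- stats::sd(values)
  degenerate <- !is.finite(s) || s == 0
  ep <- empirical_p(observed, values)
  structure(list(values = values, b = as.integer(b), seed = as.integer(seed),
                 statistic = statistic, observed = observed,
                 mean = mu, std = s,
                 z = if (degenerate) NA_real_ else z_score(observed, mu, s),
                 degenerate = degenerate,
                 empirical_p = ep$p, p_display = ep$display),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null of %s (B = %d, seed = %d)\n",
              toupper(x$statistic), x$b, x$seed))
  cat(sprintf("  observed = %.4f\n  null mean = %.4f, sd = %.4f\n",
              x$observed, x$mean, x$std))
  if (x$degenerate) {
    cat("  z = undefined (zero null variance)\n")
  } else {
    cat(sprintf("  z = %.4f\n", x$z))
  }
  cat(sprintf("  empirical p %s\n",
              if (x$empirical_p == 0) x$p_display else paste("=", x$p_display)))
  invisible(x)
}

#' Histogram of a permutation null with the observed statistic marked
#'
#' @param x A `null_distribution`.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.null_distribution <- function(x, ...) {
  graphics::hist(x$values, breaks = 30,
                 xlim = range(c(x$values, x$observed)),
                 main = sprintf("Null %s (B = %d)", toupper(x$statistic), x$b),
                 xlab = toupper(x$statistic), ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}

#' Serialize a permutation test as a structured text report plus TSV
#'
#' Writes `<stem>.txt` with the summary (statistic, observed, B, seed, mean,
#' sd, z, empirical p) and `<stem>_replicates.tsv` with one replicate value
#' per line.
#'
#' @param x A `null_distribution`.
#' @param stem Output path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_null_distribution <- function(x, stem) {
  stopifnot(inherits(x, "null_distribution"))
  txt <- file.path(paste0(stem, ".txt"))
  tsv <- file.path(paste0(stem, "_replicates.tsv"))
  writeLines(c(
    sprintf("statistic\t%s", x$statistic),
    sprintf("observed\t%.10g", x$observed),
    sprintf("b\t%d", x$b),
    sprintf("seed\t%d", x$seed),
    sprintf("null_mean\t%.10g", x$mean),
    sprintf("null_sd\t%.10g", x$std),
    sprintf("z\t%s", if (x$degenerate) "undefined" else sprintf("%.10g", x$z)),
    sprintf("empirical_p\t%s", x$p_display)), txt)
  utils::write.table(data.frame(value = x$values), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(txt, tsv))
}
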