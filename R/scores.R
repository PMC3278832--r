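#' Signed purity of a cluster
#'
#' `beta = (n_positive - n_negative) / n_total` in `[-1, 1]`. `|beta| = 1`
#' means a pure (fully monochromatic) cluster; `beta = 0` means equal counts
#' of positive and negative interactions.
#'
#' @param cluster A cluster from a `cluster_set`, or any list with
#'   `n_positive`, `n_negative`, `n_total`.
#' @return Signed purity in `[-1, 1]`.
#' @export
cluster_beta <- function(cluster) {
  if (cluster$n_total < 1) stop("beta of an empty cluster is undefined")
  (cluster$n_positive - cluster$n_negative) / cluster$n_total
}

#' Signed strength purity of a cluster
#'
#' The strength analogue of [cluster_beta()]: the net interaction strength
#' over the total strength, `sum(epsilon) / sum(|epsilon|)`, in `[-1, 1]`.
#' It equals `beta` whenever all interactions in the cluster have the same
#' `|epsilon|`.
#'
#' @inheritParams cluster_beta
#' @return Signed strength purity in `[-1, 1]`.
#' @export
cluster_beta_strength <- function(cluster) {
  eps <- cluster$interactions$epsilon
  denom <- sum(abs(eps))
  if (denom < .Machine$double.eps) {
    stop("all interaction strengths are below machine tolerance")
  }
  sum(eps) / denom
}

#' Population-level monochromaticity scores
#'
#' Computes per-cluster purities and the two population indices. The
#' monochromatic index (MCI) is the mean of `|beta_i|` weighted by each
#' cluster's interaction count, reflecting that clusters with more
#' interactions are more reliable; it ranges from 0 (every cluster balanced)
#' to 1 (every cluster pure). The strength-based index (sMCI) applies the
#' same weighting to `|sum(epsilon)| / sum(|epsilon|)` per cluster, so
#' monochromaticity is judged by net interaction strength rather than counts.
#'
#' @param clusters A non-empty `cluster_set`.
#' @return An object of class `population_score`: list with `mci`, `smci`,
#'   `n_clusters`, `total_interactions` and a `per_cluster` data frame
#'   (cluster_id, kind, complexes, n_total, n_positive, n_negative, beta,
#'   beta_strength).
#' @export
population_score <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (length(clusters) == 0) {
    stop("population score of an empty cluster set is undefined")
  }
  tab <- as.data.frame(clusters)
  tab$beta <- vapply(clusters$clusters, cluster_beta, numeric(1))
  tab$beta_strength <- vapply(clusters$clusters, cluster_beta_strength,
                              numeric(1))
  w <- tab$n_total
  structure(list(mci = sum(w * abs(tab$beta)) / sum(w),
                 smci = sum(w * abs(tab$beta_strength)) / sum(w),
                 n_clusters = nrow(tab),
                 total_interactions = sum(w),
                 per_cluster = tab),
            class = "population_score")
}

#' Monochromatic index of a cluster population
#'
#' @param clusters A `cluster_set` or a precomputed [population_score()].
#' @return The MCI in `[0, 1]`.
#' @export
mci <- function(clusters) {
  if (inherits(clusters, "population_score")) return(clusters$mci)
  population_score(clusters)$mci
}

#' Strength-based monochromatic index of a cluster population
#'
#' @inheritParams mci
#' @return The sMCI in `[0, 1]`.
#' @export
smci <- function(clusters) {
  if (inherits(clusters, "population_score")) return(clusters$smci)
  population_score(clusters)$smci
}

#' Background-adjusted monochromatic purity (MP) score of one cluster
#'
#' A per-complex purity score that compares the cluster's positive fraction
#' `f` with the background positive fraction `f0`: `+1` when all interactions
#' are positive, `-1` when all are negative, and `0` when the cluster has the
#' same positive/negative ratio as the background. Between those anchors the
#' score interpolates piecewise linearly,
#' `(f - f0) / (1 - f0)` for `f >= f0` and `-(f0 - f) / f0` otherwise, which
#' makes the jump across the background ratio steeper the more imbalanced the
#' background is. A cluster is called monochromatic when `|MP| > 0.5`
#' (strictly). The exact historical form of this score is not recoverable
#' from its original description; this reconstruction honours all its stated
#' anchor points and is isolated here so an alternative form can be swapped
#' in.
#'
#' @param cluster A cluster (see [cluster_beta()]).
#' @param background A [background_composition()]. A degenerate background
#'   (`f_positive` of 0 or 1) is only admissible for a pure cluster.
#' @return An object of class `mp_result`: list with `cluster_id`, `mp`,
#'   `monochromatic`, `direction` (`"positive"`, `"negative"` or `"none"`).
#' @export
mp_score <- function(cluster, background) {
  stopifnot(inherits(background, "background_composition"))
  if (cluster$n_total < 1) stop("MP score of an empty cluster is undefined")
  f <- cluster$n_positive / cluster$n_total
  f0 <- background$f_positive
  if (f0 %in% c(0, 1) && !(f %in% c(0, 1))) {
    stop("MP score undefined: degenerate background with a non-pure cluster")
  }
  mp <- if (f == 1) 1
        else if (f == 0) -1
        else if (f >= f0) (f - f0) / (1 - f0)
        else -(f0 - f) / f0
  structure(list(cluster_id = cluster$id, mp = mp,
                 monochromatic = abs(mp) > 0.5,
                 direction = if (mp > 0.5) "positive"
                             else if (mp < -0.5) "negative" else "none"),
            class = "mp_result")
}

#' Classify MP-score results
#'
#' @param results List of [mp_score()] results.
#' @return Named integer vector: counts of positively monochromatic,
#'   negatively monochromatic and non-monochromatic clusters
#'   (`|MP| > 0.5` strictly).
#' @export
classify_mp <- function(results) {
  dirs <- vapply(results, function(r) r$direction, character(1))
  c(positive_monochromatic = sum(dirs == "positive"),
    negative_monochromatic = sum(dirs == "negative"),
    non_monochromatic = sum(dirs == "none"))
}

#' Highly monochromatic clusters of a population
#'
#' Clusters whose `|beta|` strictly exceeds the population MCI, labeled by
#' the sign of `beta`. When every cluster is pure the MCI is 1 and no cluster
#' can exceed it, so the result is empty.
#'
#' @param pop A [population_score()].
#' @return Data frame (subset of `pop$per_cluster`) with an added `sign`
#'   column, plus attributes `n_positive` / `n_negative` holding the counts
#'   by dominant sign.
#' @export
highly_monochromatic <- function(pop) {
  stopifnot(inherits(pop, "population_score"))
  tab <- pop$per_cluster[abs(pop$per_cluster$beta) > pop$mci, , drop = FALSE]
  tab$sign <- ifelse(tab$beta > 0, "positive", "negative")
  rownames(tab) <- NULL
  structure(tab,
            n_positive = sum(tab$sign == "positive"),
            n_negative = sum(tab$sign == "negative"))
}

#' @export
print.population_score <- function(x, ...) {
  cat(sprintf(
    "Population of %d cluster(s), %d interactions\n  MCI  = %.4f\n  sMCI = %.4f\n",
    x$n_clusters, x$total_interactions, x$mci, x$smci))
  invisible(x)
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("MP(%s) = %+.4f [%s]\n", x$cluster_id, x$mp,
              if (x$monochromatic) paste0("monochromatic ", x$direction)
              else "not monochromatic"))
  invisible(x)
}
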