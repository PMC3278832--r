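#' @title Interaction clusters within and between protein complexes
#' @description
#' A *cluster* is a labeled set of genetic interactions: either all
#' interactions whose two genes belong to one protein complex (a
#' within-complex cluster), or all interactions linking one specific pair of
#' distinct complexes (a between-complex cluster). A `cluster_set` is the
#' population of such clusters over which the monochromatic index is
#' computed; only clusters with at least `min_interactions` interactions are
#' retained.
#' @name clusters
NULL

new_cluster <- function(id, kind, complexes, interactions) {
  np <- sum(interactions$sign == "positive")
  nn <- sum(interactions$sign == "negative")
  structure(list(id = id, kind = kind, complexes = complexes,
                 interactions = interactions,
                 n_total = np + nn, n_positive = np, n_negative = nn),
            class = "gi_cluster")
}

new_cluster_set <- function(clusters, min_interactions, kind) {
  structure(list(clusters = clusters, min_interactions = min_interactions,
                 kind = kind),
            class = "cluster_set")
}

#' @export
length.cluster_set <- function(x) length(x$clusters)

cluster_sizes <- function(cs) {
  vapply(cs$clusters, function(cl) cl$n_total, integer(1))
}

#' Build within-complex interaction clusters
#'
#' For every complex in the catalog, collects the interactions whose two
#' genes are both members. Because consensus complex catalogs overlap, one
#' interaction may appear in several clusters. Clusters with fewer than
#' `min_interactions` interactions are discarded.
#'
#' @param x An [interaction_set()].
#' @param catalog A [gene_set_catalog()] with `kind = "complexes"`.
#' @param min_interactions Minimum cluster size retained (default 2).
#'
#' @return A `cluster_set` of within-complex clusters.
#' @export
build_within_clusters <- function(x, catalog, min_interactions = 2) {
  stopifnot(inherits(x, "interaction_set"),
            inherits(catalog, "gene_set_catalog"))
  if (attr(catalog, "kind") != "complexes") {
    stop("catalog must have kind = 'complexes'")
  }
  clusters <- list()
  for (nm in names(catalog)) {
    members <- catalog[[nm]]
    keep <- x$gene_a %in% members & x$gene_b %in% members
    if (sum(keep) >= min_interactions) {
      clusters[[nm]] <- new_cluster(nm, "within", nm,
                                    as.data.frame(x)[keep, , drop = FALSE])
    }
  }
  new_cluster_set(clusters, min_interactions, "within")
}

#' Build between-complex interaction clusters
#'
#' For every unordered pair of distinct complexes (X, Y), collects the
#' interactions with one gene in X and the other in Y. A cluster id is the
#' lexicographically sorted pair of complex names joined by `"|"`. With
#' overlapping complexes an interaction can contribute to several pairs; with
#' `exclude_within = TRUE`, interactions whose two genes co-occur in any
#' single complex are removed from all between-complex clusters.
#'
#' @inheritParams build_within_clusters
#' @param exclude_within Drop interactions that are internal to some complex.
#'
#' @return A `cluster_set` of between-complex clusters.
#' @export
build_between_clusters <- function(x, catalog, min_interactions = 2,
                                   exclude_within = FALSE) {
  stopifnot(inherits(x, "interaction_set"),
            inherits(catalog, "gene_set_catalog"))
  if (attr(catalog, "kind") != "complexes") {
    stop("catalog must have kind = 'complexes'")
  }
  # gene -> complexes membership map
  membership <- list()
  for (nm in names(catalog)) {
    for (g in catalog[[nm]]) membership[[g]] <- c(membership[[g]], nm)
  }
  assign_rows <- list()
  for (i in seq_len(nrow(x))) {
    ca <- membership[[x$gene_a[i]]]
    cb <- membership[[x$gene_b[i]]]
    if (is.null(ca) || is.null(cb)) next
    if (exclude_within && length(intersect(ca, cb)) > 0) next
    pairs <- unique(unlist(lapply(ca, function(p) {
      q <- cb[cb != p]
      if (length(q) == 0) return(character(0))
      paste(pmin(p, q), pmax(p, q), sep = "|")
    })))
    for (key in pairs) assign_rows[[key]] <- c(assign_rows[[key]], i)
  }
  clusters <- list()
  for (key in sort(names(assign_rows))) {
    idx <- assign_rows[[key]]
    if (length(idx) >= min_interactions) {
      clusters[[key]] <- new_cluster(key, "between",
                                     strsplit(key, "|", fixed = TRUE)[[1]],
                                     as.data.frame(x)[idx, , drop = FALSE])
    }
  }
  new_cluster_set(clusters, min_interactions, "between")
}

#' Assign protein complexes to cellular subsystems
#'
#' A complex is assigned to a subsystem if and only if every member gene
#' belongs to that subsystem's gene list; a complex satisfying this for
#' several subsystems is assigned to all of them.
#'
#' @param catalog A [gene_set_catalog()] of complexes.
#' @param subsystems A [gene_set_catalog()] with `kind = "subsystem"`.
#'
#' @return Named list: complex name -> character vector of subsystem names
#'   (possibly empty).
#' @export
assign_subsystems <- function(catalog, subsystems) {
  stopifnot(inherits(catalog, "gene_set_catalog"),
            inherits(subsystems, "gene_set_catalog"))
  if (attr(subsystems, "kind") != "subsystem") {
    stop("subsystems catalog must have kind = 'subsystem'")
  }
  lapply(stats::setNames(names(catalog), names(catalog)), function(nm) {
    members <- catalog[[nm]]
    hits <- vapply(subsystems, function(g) all(members %in% g), logical(1))
    names(subsystems)[hits]
  })
}

#' Tabulate a cluster set
#'
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return Data frame with one row per cluster: id, kind, complexes,
#'   n_total, n_positive, n_negative.
#' @export
as.data.frame.cluster_set <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(cluster_id = character(), kind = character(),
                      complexes = character(), n_total = integer(),
                      n_positive = integer(), n_negative = integer()))
  }
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(cluster_id = cl$id, kind = cl$kind,
               complexes = paste(cl$complexes, collapse = "|"),
               n_total = cl$n_total, n_positive = cl$n_positive,
               n_negative = cl$n_negative,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- if (length(x) > 0) cluster_sizes(x) else integer(0)
  cat(sprintf(
    "%s-complex cluster set: %d cluster(s) (min %d interactions), %d interaction slot(s)\n",
    x$kind, length(x), x$min_interactions, sum(sizes)))
  invisible(x)
}
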