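#' Complex-level genetic-interaction network
#'
#' Builds a graph whose nodes are protein complexes and whose edges are
#' between-complex clusters, each carrying the cluster's signed purity
#' `beta`, its interaction count, the arithmetic mean of its interaction
#' scores and the dominant sign. With `only_highly_monochromatic = TRUE`
#' only clusters with `|beta|` strictly above the population MCI are kept.
#'
#' @param between A `cluster_set` of between-complex clusters.
#' @param scores The [population_score()] computed on `between`.
#' @param only_highly_monochromatic Keep only highly monochromatic clusters.
#' @param subsystem_of Optional named list/vector mapping complex names to a
#'   subsystem or module label, stored as a node attribute.
#'
#' @return An [igraph::igraph] object with edge attributes `beta`,
#'   `n_total`, `mean_epsilon`, `sign` and node attribute `subsystem`.
#' @export
build_complex_graph <- function(between, scores,
                                only_highly_monochromatic = FALSE,
                                subsystem_of = NULL) {
  stopifnot(inherits(between, "cluster_set"),
            inherits(scores, "population_score"))
  keep <- between$clusters
  if (only_highly_monochromatic) {
    keep <- keep[vapply(keep, function(cl) abs(cluster_beta(cl)) > scores$mci,
                        logical(1))]
  }
  if (length(keep) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  edges <- do.call(rbind, lapply(keep, function(cl) {
    beta <- cluster_beta(cl)
    data.frame(from = cl$complexes[1], to = cl$complexes[2],
               beta = beta, n_total = cl$n_total,
               mean_epsilon = mean(cl$interactions$epsilon),
               sign = if (beta >= 0) "pos" else "neg",
               stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  sub <- rep("", igraph::vcount(g))
  if (!is.null(subsystem_of)) {
    sub <- vapply(igraph::V(g)$name, function(nm) {
      s <- subsystem_of[[nm]]
      if (is.null(s) || length(s) == 0) "" else paste(s, collapse = ";")
    }, character(1))
  }
  igraph::V(g)$subsystem <- unname(sub)
  g
}

#' Serialize a complex-level network
#'
#' Formats: `"sif"` (one line per edge, interaction token `pos`/`neg`; edge
#' attributes are written to a sibling `<path>.attrs.tsv` table since SIF
#' itself carries none), `"graphml"` (attributes embedded; round-trippable
#' with [read_complex_graph()]), `"json"` (node-link document with `nodes`
#' and `links` lists, also round-trippable).
#'
#' @param graph An igraph object from [build_complex_graph()].
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_complex_graph <- function(graph, path, format = c("sif", "graphml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "igraph"))
  el <- igraph::as_data_frame(graph, what = "edges")
  if (format == "sif") {
    lines <- if (nrow(el) > 0) paste(el$from, el$sign, el$to, sep = "\t")
             else character(0)
    writeLines(lines, path)
    if (nrow(el) > 0) {
      utils::write.table(el, paste0(path, ".attrs.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  } else if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- igraph::as_data_frame(graph, what = "vertices")
    doc <- list(directed = FALSE,
                nodes = if (nrow(nodes) > 0) nodes else list(),
                links = if (nrow(el) > 0) el else list())
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read back a serialized complex-level network
#'
#' @param path File written by [write_complex_graph()].
#' @param format `"graphml"` or `"json"`.
#' @return An igraph object.
#' @export
read_complex_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc$links) == 0 || is.null(nrow(doc$links))) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  igraph::graph_from_data_frame(doc$links, directed = FALSE,
                                vertices = doc$nodes)
}
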