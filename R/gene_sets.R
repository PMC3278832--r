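#' Construct a gene-set catalog
#'
#' A catalog is a named list of character vectors of gene identifiers, used
#' either as a protein-complex membership list (`kind = "complexes"`) or as
#' flat subsystem gene lists (`kind = "subsystem"`). Members are deduplicated
#' and matched case-insensitively. Complexes require at least two members;
#' smaller sets are dropped with a warning. Membership may overlap across
#' sets, as it does in consensus complex catalogs.
#'
#' @param sets Named list of character vectors.
#' @param kind `"complexes"` or `"subsystem"`.
#'
#' @return An object of class `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, kind = c("complexes", "subsystem")) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every gene set must be named")
  }
  sets <- lapply(sets, function(g) unique(normalize_gene(g)))
  if (kind == "complexes") {
    small <- vapply(sets, length, integer(1)) < 2
    if (any(small)) {
      warning(sprintf("dropped %d complex(es) with fewer than 2 members: %s",
                      sum(small),
                      paste(names(sets)[small], collapse = ", ")))
      sets <- sets[!small]
    }
  }
  structure(sets, kind = kind, class = "gene_set_catalog")
}

#' Read a gene-set catalog from GMT or two-column text
#'
#' GMT files are tab-separated with one set per line: name, description, then
#' member genes. Two-column files are headerless tab-separated
#' (set name, gene) with one membership per line.
#'
#' @param path Path to the file.
#' @param format `"gmt"` or `"two-column"`.
#' @param kind Passed to [gene_set_catalog()].
#'
#' @return A `gene_set_catalog`.
#' @export
read_gene_sets <- function(path, format = c("gmt", "two-column"),
                           kind = c("complexes", "subsystem")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, integer(1)) < 3
    if (any(bad)) stop("malformed GMT line(s): need name, description, genes")
    sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                            vapply(fields, `[`, character(1), 1))
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("two-column format needs columns: set, gene")
    sets <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  gene_set_catalog(sets, kind = kind)
}

#' Write a catalog as GMT
#'
#' @param catalog A [gene_set_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  lines <- vapply(names(catalog), function(nm) {
    paste(c(nm, attr(catalog, "kind"), catalog[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  sizes <- vapply(x, length, integer(1))
  cat(sprintf("Gene-set catalog (%s): %d set(s), %d distinct gene(s)\n",
              attr(x, "kind"), length(x), length(unique(unlist(x)))))
  if (length(x) > 0) {
    cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}
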