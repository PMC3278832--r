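#' Genetic interaction score under the multiplicative model
#'
#' Computes the deviation of a double-mutant fitness from the product of the
#' two single-mutant fitnesses, `epsilon = phi_ab - phi_a * phi_b`. Positive
#' values are alleviating (less sick than expected), negative values are
#' aggravating interactions, with synthetic lethality the extreme case.
#'
#' @param phi_ab Double-mutant fitness relative to wild type (>= 0).
#' @param phi_a,phi_b Single-mutant fitness values relative to wild type
#'   (>= 0). All three arguments are vectorized and recycled.
#'
#' @return Numeric vector of interaction scores.
#' @examples
#' epsilon_score(0.5, 1.0, 0.5)  # 0: no interaction
#' epsilon_score(0.2, 0.8, 0.5)  # -0.2: aggravating
#' @export
epsilon_score <- function(phi_ab, phi_a, phi_b) {
  if (any(phi_ab < 0, na.rm = TRUE) || any(phi_a < 0, na.rm = TRUE) ||
      any(phi_b < 0, na.rm = TRUE)) {
    stop("fitness values are relative to wild type and must be >= 0")
  }
  phi_ab - phi_a * phi_b
}

interaction_sign <- function(epsilon) {
  ifelse(epsilon > 0, "positive", "negative")
}

normalize_gene <- function(x) toupper(trimws(as.character(x)))

#' Construct an interaction set
#'
#' An interaction set is a data frame of gene pairs with columns `gene_a`,
#' `gene_b`, `epsilon`, `p_value` and a derived `sign` column, carrying the
#' applied significance cutoff and the pair-orientation policy as attributes.
#' Gene identifiers are trimmed and upper-cased so matching against gene-set
#' catalogs is case-insensitive. Self-pairs and rows with `epsilon == 0`
#' (sign undefined) are rejected.
#'
#' @param df Data frame with columns `gene_a`, `gene_b`, `epsilon`, `p_value`.
#' @param cutoff_level One of `"raw"`, `"lenient"`, `"intermediate"`,
#'   `"stringent"`; the filter the rows are known to satisfy.
#' @param pair_policy `"ordered"` (query x array orientation preserved, a pair
#'   may appear in both orientations) or `"unordered-collapsed"` (one row per
#'   unordered pair).
#'
#' @return A data frame of class `interaction_set`.
#' @seealso [read_interactions()], [apply_cutoff()], [collapse_duplicates()]
#' @export
interaction_set <- function(df, cutoff_level = "raw", pair_policy = "ordered") {
  cutoff_level <- match.arg(cutoff_level,
                            c("raw", "lenient", "intermediate", "stringent"))
  pair_policy <- match.arg(pair_policy, c("ordered", "unordered-collapsed"))
  required <- c("gene_a", "gene_b", "epsilon", "p_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$gene_a <- normalize_gene(df$gene_a)
  df$gene_b <- normalize_gene(df$gene_b)
  df$epsilon <- as.numeric(df$epsilon)
  df$p_value <- as.numeric(df$p_value)
  if (any(df$gene_a == df$gene_b)) {
    stop("self-interactions (gene_a == gene_b) are not allowed")
  }
  if (any(df$epsilon == 0)) {
    stop("epsilon == 0 has no sign; drop such rows before construction")
  }
  if (any(df$p_value < 0 | df$p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  df$sign <- interaction_sign(df$epsilon)
  rownames(df) <- NULL
  structure(df,
            cutoff_level = cutoff_level,
            pair_policy = pair_policy,
            class = c("interaction_set", "data.frame"))
}

#' Read an SGA-style genetic interaction table
#'
#' Reads a delimited text file (header required) with one gene pair per row
#' and maps its columns onto `gene_a`, `gene_b`, `epsilon`, `p_value`. Rows
#' with a missing score or p-value, self-pairs, and rows with an exactly zero
#' score are dropped; the counts are reported via [message()].
#'
#' @param path Path to the delimited file.
#' @param column_map Named list or character vector mapping the canonical
#'   names (`gene_a`, `gene_b`, `epsilon`, `p_value`) to column names in the
#'   file, or the path to a YAML file holding that mapping. `NULL` assumes the
#'   file already uses the canonical names.
#' @param delim Field delimiter, tab by default.
#' @param pair_policy Orientation policy recorded on the result; SGA
#'   query x array output is `"ordered"`.
#'
#' @return An [interaction_set()] with `cutoff_level = "raw"`.
#' @export
read_interactions <- function(path, column_map = NULL, delim = "\t",
                              pair_policy = "ordered") {
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(column_map) && length(column_map) == 1 &&
      file.exists(column_map)) {
    column_map <- yaml::read_yaml(column_map)
  }
  canonical <- c("gene_a", "gene_b", "epsilon", "p_value")
  if (is.null(column_map)) {
    column_map <- stats::setNames(as.list(canonical), canonical)
  }
  for (nm in canonical) {
    src <- column_map[[nm]]
    if (is.null(src) || !src %in% names(raw)) {
      stop("cannot map column '", nm, "': '",
           if (is.null(src)) "<unset>" else src, "' not found in ", path)
    }
  }
  df <- data.frame(gene_a = raw[[column_map$gene_a]],
                   gene_b = raw[[column_map$gene_b]],
                   epsilon = suppressWarnings(as.numeric(raw[[column_map$epsilon]])),
                   p_value = suppressWarnings(as.numeric(raw[[column_map$p_value]])),
                   stringsAsFactors = FALSE)
  n0 <- nrow(df)
  df <- df[!is.na(df$epsilon) & !is.na(df$p_value), , drop = FALSE]
  n_missing <- n0 - nrow(df)
  zero <- df$epsilon == 0
  n_zero <- sum(zero)
  df <- df[!zero, , drop = FALSE]
  self <- normalize_gene(df$gene_a) == normalize_gene(df$gene_b)
  n_self <- sum(self)
  df <- df[!self, , drop = FALSE]
  if (n_missing + n_zero + n_self > 0) {
    message(sprintf(
      "read_interactions: dropped %d row(s) with missing values, %d with epsilon == 0, %d self-pair(s)",
      n_missing, n_zero, n_self))
  }
  interaction_set(df, cutoff_level = "raw", pair_policy = pair_policy)
}

#' Filter interactions at a published significance cutoff
#'
#' Applies one of the three score/p-value cutoffs used for SGA interaction
#' calls: lenient keeps `p < 0.05`; intermediate keeps `p < 0.05` and
#' `|epsilon| > 0.08`; stringent keeps `epsilon > 0.16 & p < 0.05` or
#' `epsilon < -0.12 & p < 0.05`. Stringent calls are always a subset of
#' lenient and intermediate calls.
#'
#' @param x An [interaction_set()] with `cutoff_level = "raw"`.
#' @param level `"lenient"`, `"intermediate"` or `"stringent"`.
#'
#' @return A filtered `interaction_set` with `cutoff_level = level`.
#' @export
apply_cutoff <- function(x, level = c("lenient", "intermediate", "stringent")) {
  stopifnot(inherits(x, "interaction_set"))
  level <- match.arg(level)
  if (attr(x, "cutoff_level") != "raw") {
    stop("apply_cutoff expects an unfiltered set (cutoff_level = 'raw'), got '",
         attr(x, "cutoff_level"), "'")
  }
  keep <- switch(level,
    lenient = x$p_value < 0.05,
    intermediate = x$p_value < 0.05 & abs(x$epsilon) > 0.08,
    stringent = (x$epsilon > 0.16 & x$p_value < 0.05) |
                (x$epsilon < -0.12 & x$p_value < 0.05))
  out <- as.data.frame(x)[keep, , drop = FALSE]
  interaction_set(out, cutoff_level = level,
                  pair_policy = attr(x, "pair_policy"))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Collapse the two screening orientations of each gene pair
#'
#' SGA screens a pair in the query x array and array x query orientations, so
#' an ordered table can report the same unordered pair twice. Duplicates with
#' concordant sign are merged (mean `epsilon`, minimum `p_value`); pairs whose
#' orientations disagree in sign are removed entirely, with the count reported
#' via [message()].
#'
#' @param x An [interaction_set()] with `pair_policy = "ordered"`.
#'
#' @return An `interaction_set` with `pair_policy = "unordered-collapsed"`;
#'   in every output row `gene_a` sorts before `gene_b`.
#' @export
collapse_duplicates <- function(x) {
  stopifnot(inherits(x, "interaction_set"))
  if (attr(x, "pair_policy") != "ordered") {
    stop("collapse_duplicates expects pair_policy = 'ordered'")
  }
  a <- pmin(x$gene_a, x$gene_b)
  b <- pmax(x$gene_a, x$gene_b)
  key <- pair_key(x$gene_a, x$gene_b)
  groups <- split(seq_len(nrow(x)), key)
  # preserve first-appearance order of pairs
  groups <- groups[order(vapply(groups, min, integer(1)))]
  n_discordant <- 0L
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    eps <- x$epsilon[idx]
    if (length(unique(sign(eps))) > 1) {
      n_discordant <- n_discordant + 1L
      next
    }
    j <- idx[1]
    rows[[i]] <- data.frame(gene_a = a[j], gene_b = b[j],
                            epsilon = mean(eps),
                            p_value = min(x$p_value[idx]),
                            stringsAsFactors = FALSE)
  }
  if (n_discordant > 0) {
    message(sprintf(
      "collapse_duplicates: removed %d pair(s) with discordant signs between orientations",
      n_discordant))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      epsilon = numeric(), p_value = numeric())
  }
  interaction_set(out, cutoff_level = attr(x, "cutoff_level"),
                  pair_policy = "unordered-collapsed")
}

#' Sign composition of an interaction population
#'
#' Summarizes the positive/negative balance of a filtered interaction set:
#' counts of each sign, the positive fraction `f_positive`, and the signed
#' imbalance `alpha = (n_positive - n_negative) / n_total` in `[-1, 1]`.
#' `alpha` describes the background against which per-cluster purity is
#' judged; SGA backgrounds grow strongly negative as the cutoff tightens.
#'
#' @param x A non-empty [interaction_set()].
#'
#' @return An object of class `background_composition`: a list with
#'   `n_positive`, `n_negative`, `f_positive`, `alpha`.
#' @export
background_composition <- function(x) {
  stopifnot(inherits(x, "interaction_set"))
  if (nrow(x) == 0) stop("background composition of an empty set is undefined")
  np <- sum(x$sign == "positive")
  nn <- sum(x$sign == "negative")
  structure(list(n_positive = np, n_negative = nn,
                 f_positive = np / (np + nn),
                 alpha = (np - nn) / (np + nn)),
            class = "background_composition")
}

#' @export
print.background_composition <- function(x, ...) {
  cat(sprintf(
    "Background: %d positive / %d negative (f+ = %.3f, alpha = %+.3f)\n",
    x$n_positive, x$n_negative, x$f_positive, x$alpha))
  invisible(x)
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("Interaction set: %d pair(s), cutoff = %s, pairs %s\n",
              nrow(x), attr(x, "cutoff_level"), attr(x, "pair_policy")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}
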