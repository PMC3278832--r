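#' Pure-cluster counts of a population
#'
#' @param pop A [population_score()].
#' @return Named integer vector: clusters with `beta = 1` (pure positive),
#'   `beta = -1` (pure negative), and the rest (mixed).
#' @export
pure_cluster_counts <- function(pop) {
  stopifnot(inherits(pop, "population_score"))
  beta <- pop$per_cluster$beta
  c(pure_positive = sum(beta == 1),
    pure_negative = sum(beta == -1),
    mixed = sum(abs(beta) < 1))
}

analyze_population <- function(clusters, pool, b, seed, run_null = TRUE) {
  if (length(clusters) == 0) return(NULL)
  pop <- population_score(clusters)
  out <- list(score = pop, pure = pure_cluster_counts(pop),
              highly = highly_monochromatic(pop))
  if (run_null) {
    out$null_mci <- permutation_null(clusters, pool, b = b, seed = seed,
                                     statistic = "mci")
    out$null_smci <- permutation_null(clusters, pool, b = b, seed = seed + 1L,
                                      statistic = "smci")
  }
  out
}

#' Full monochromaticity analysis of an interaction dataset
#'
#' Orchestrates the complete procedure: optional significance-cutoff
#' filtering, construction of within-complex and between-complex clusters,
#' per-cluster and population purity scores (MCI, sMCI), MP-score
#' classification with the exact binomial test, permutation nulls with
#' Z-scores and empirical p-values, and per-subsystem breakdowns for every
#' subsystem holding at least `min_subsystem_clusters` eligible clusters
#' (smaller subsystems are skipped with a message, mirroring how sparsely
#' screened subsystems must be left out).
#'
#' @param interactions An [interaction_set()].
#' @param complexes A [gene_set_catalog()] of protein complexes.
#' @param subsystems Optional [gene_set_catalog()] of subsystem gene lists.
#' @param cutoff Cutoff to apply when `interactions` is still raw
#'   (`"lenient"`, `"intermediate"`, `"stringent"`), or `NULL` to analyze the
#'   set as supplied.
#' @param min_interactions Minimum interactions per retained cluster.
#' @param exclude_within Passed to [build_between_clusters()].
#' @param b Permutation replicates per null distribution.
#' @param seed Integer seed driving all permutation draws.
#' @param min_subsystem_clusters Minimum number of eligible clusters (within
#'   plus between) for a subsystem to be analyzed.
#'
#' @return An object of class `mci_analysis`: list with `cutoff_level`,
#'   `background`, `within` and `between` sections (each a population score,
#'   pure/highly monochromatic breakdowns and the two permutation nulls),
#'   `mp_summary` (per-complex MP results, classification counts and
#'   [binom_upper_tail()] result) and `per_subsystem`.
#' @export
run_analysis <- function(interactions, complexes, subsystems = NULL,
                         cutoff = NULL, min_interactions = 2,
                         exclude_within = FALSE, b = 1000, seed = 20111130,
                         min_subsystem_clusters = 2) {
  stopifnot(inherits(interactions, "interaction_set"),
            inherits(complexes, "gene_set_catalog"))
  if (!is.null(cutoff)) {
    interactions <- apply_cutoff(interactions, cutoff)
  }
  if (nrow(interactions) == 0) stop("no interactions after filtering")
  background <- background_composition(interactions)
  within <- build_within_clusters(interactions, complexes, min_interactions)
  between <- build_between_clusters(interactions, complexes, min_interactions,
                                    exclude_within = exclude_within)

  report <- list(cutoff_level = attr(interactions, "cutoff_level"),
                 background = background,
                 min_interactions = min_interactions,
                 b = b, seed = as.integer(seed))
  report$within <- analyze_population(within, interactions, b, seed)
  report$between <- analyze_population(between, interactions, b, seed + 100L)

  # MP-score comparison on within-complex clusters
  if (!is.null(report$within)) {
    mp <- lapply(within$clusters, mp_score, background = background)
    counts <- classify_mp(mp)
    x_mono <- counts[["positive_monochromatic"]] +
      counts[["negative_monochromatic"]]
    report$mp_summary <- list(results = mp, counts = counts,
                              binom = binom_upper_tail(length(within), x_mono))
  }

  if (!is.null(subsystems)) {
    assignment <- assign_subsystems(complexes, subsystems)
    report$per_subsystem <- list()
    for (ss in names(subsystems)) {
      cplx <- names(assignment)[vapply(assignment, function(a) ss %in% a,
                                       logical(1))]
      w_sub <- within
      w_sub$clusters <- within$clusters[
        vapply(within$clusters, function(cl) cl$complexes %in% cplx, logical(1))]
      b_sub <- between
      b_sub$clusters <- between$clusters[
        vapply(between$clusters, function(cl) all(cl$complexes %in% cplx),
               logical(1))]
      n_eligible <- length(w_sub) + length(b_sub)
      if (n_eligible < min_subsystem_clusters) {
        message(sprintf(
          "subsystem '%s' skipped: %d eligible cluster(s) (need >= %d)",
          ss, n_eligible, min_subsystem_clusters))
        next
      }
      report$per_subsystem[[ss]] <- list(
        n_complexes = length(cplx),
        within = analyze_population(w_sub, interactions, b, seed + 1000L),
        between = analyze_population(b_sub, interactions, b, seed + 2000L))
    }
  }
  structure(report, class = "mci_analysis")
}

section_line <- function(name, sec) {
  if (is.null(sec)) return(sprintf("  %s: no eligible clusters\n", name))
  pc <- sec$pure
  paste0(sprintf(
    "  %s: %d cluster(s), %d interactions\n    MCI = %.4f (null %.4f +/- %.4f, z = %s, p %s)\n    sMCI = %.4f\n",
    name, sec$score$n_clusters, sec$score$total_interactions,
    sec$score$mci, sec$null_mci$mean, sec$null_mci$std,
    if (sec$null_mci$degenerate) "undef" else sprintf("%.2f", sec$null_mci$z),
    if (sec$null_mci$empirical_p == 0) sec$null_mci$p_display
    else paste("=", sec$null_mci$p_display),
    sec$score$smci),
    sprintf("    pure: %d positive, %d negative, %d mixed; highly monochromatic: %d+/%d-\n",
            pc[["pure_positive"]], pc[["pure_negative"]], pc[["mixed"]],
            attr(sec$highly, "n_positive"), attr(sec$highly, "n_negative")))
}

#' @export
print.mci_analysis <- function(x, ...) {
  cat(sprintf("Monochromaticity analysis (cutoff: %s, B = %d, seed = %d)\n",
              x$cutoff_level, x$b, x$seed))
  print(x$background)
  cat(section_line("within-complex", x$within))
  cat(section_line("between-complex", x$between))
  if (!is.null(x$mp_summary)) {
    cat(sprintf("  MP-score: %d+/%d- monochromatic of %d complexes, binomial p = %.3g\n",
                x$mp_summary$counts[["positive_monochromatic"]],
                x$mp_summary$counts[["negative_monochromatic"]],
                x$mp_summary$binom$n, x$mp_summary$binom$p_value))
  }
  for (ss in names(x$per_subsystem)) {
    sec <- x$per_subsystem[[ss]]
    cat(sprintf("Subsystem '%s' (%d complexes):\n", ss, sec$n_complexes))
    cat(section_line("within-complex", sec$within))
    cat(section_line("between-complex", sec$between))
  }
  invisible(x)
}

#' @export
summary.mci_analysis <- function(object, ...) {
  grab <- function(sec) {
    if (is.null(sec)) return(NULL)
    data.frame(n_clusters = sec$score$n_clusters,
               total_interactions = sec$score$total_interactions,
               mci = sec$score$mci, smci = sec$score$smci,
               null_mean = sec$null_mci$mean, null_sd = sec$null_mci$std,
               z = sec$null_mci$z, empirical_p = sec$null_mci$empirical_p)
  }
  rows <- list(within = grab(object$within), between = grab(object$between))
  for (ss in names(object$per_subsystem)) {
    rows[[paste0(ss, ":within")]] <- grab(object$per_subsystem[[ss]]$within)
    rows[[paste0(ss, ":between")]] <- grab(object$per_subsystem[[ss]]$between)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  out <- cbind(section = names(rows), out)
  rownames(out) <- NULL
  out
}

#' Null-distribution panels of an analysis
#'
#' Draws the permutation null histogram of the MCI for the within- and
#' between-complex populations, with the observed value marked in red.
#'
#' @param x An `mci_analysis`.
#' @param ... Passed to [plot.null_distribution()].
#' @return `x`, invisibly.
#' @export
plot.mci_analysis <- function(x, ...) {
  secs <- Filter(Negate(is.null), list(within = x$within, between = x$between))
  old <- graphics::par(mfrow = c(1, length(secs)))
  on.exit(graphics::par(old))
  for (nm in names(secs)) plot(secs[[nm]]$null_mci, ...)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `scores_within.tsv` / `scores_between.tsv` (per-cluster purity
#' tables with the highly-monochromatic flag), `summary.tsv` (one row per
#' analyzed population) and `report.json` (machine-readable summary, null
#' summaries included).
#'
#' @param x An `mci_analysis`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "mci_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  score_table <- function(sec) {
    tab <- sec$score$per_cluster
    tab$highly_monochromatic <- abs(tab$beta) > sec$score$mci
    tab$sign <- ifelse(tab$beta > 0, "positive",
                       ifelse(tab$beta < 0, "negative", "balanced"))
    tab
  }
  for (nm in c("within", "between")) {
    if (is.null(x[[nm]])) next
    utils::write.table(score_table(x[[nm]]),
                       file.path(dir, paste0("scores_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(summary(x), file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  null_summary <- function(nd) {
    list(observed = nd$observed, b = nd$b, seed = nd$seed, mean = nd$mean,
         std = nd$std, z = nd$z, empirical_p = nd$empirical_p,
         p_display = nd$p_display)
  }
  sec_json <- function(sec) {
    if (is.null(sec)) return(NULL)
    list(mci = sec$score$mci, smci = sec$score$smci,
         n_clusters = sec$score$n_clusters,
         total_interactions = sec$score$total_interactions,
         pure = as.list(sec$pure),
         highly_monochromatic = list(
           positive = attr(sec$highly, "n_positive"),
           negative = attr(sec$highly, "n_negative")),
         null_mci = null_summary(sec$null_mci),
         null_smci = null_summary(sec$null_smci))
  }
  doc <- list(cutoff_level = x$cutoff_level,
              background = unclass(x$background),
              b = x$b, seed = x$seed,
              within = sec_json(x$within), between = sec_json(x$between))
  if (!is.null(x$mp_summary)) {
    doc$mp_summary <- list(counts = as.list(x$mp_summary$counts),
                           binomial = unclass(x$mp_summary$binom))
  }
  doc$per_subsystem <- lapply(x$per_subsystem, function(sec) {
    list(n_complexes = sec$n_complexes,
         within = sec_json(sec$within), between = sec_json(sec$between))
  })
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
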