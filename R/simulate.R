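#' Parameters for the synthetic interaction-data generator
#'
#' Defines a planted-purity model of a quantitative genetic-interaction
#' screen over a set of protein complexes. Complexes are disjoint gene sets
#' with sizes drawn uniformly from `size_range`. Every unordered gene pair
#' inside a complex interacts with probability `within_density`; every pair
#' spanning two complexes interacts with probability `between_density`. Each
#' cluster (a complex, or a complex pair) is given a majority sign, positive
#' with probability `f_positive`, and each of its interactions takes that
#' sign with probability `purity` (so `purity = 1` plants pure clusters and
#' `purity = 0.5` plants no signal). Interaction strengths `|epsilon|` are
#' log-normal with parameters `epsilon_meanlog` / `epsilon_sdlog`; p-values
#' are a mixture, below 0.05 with probability `p_sig` and uniform on (0, 1)
#' otherwise, so the lenient/intermediate/stringent filters all bite.
#'
#' @param n_complexes Number of complexes.
#' @param size_range Integer `c(min, max)` of complex sizes (uniform).
#' @param within_density Probability an intra-complex pair interacts.
#' @param between_density Probability an inter-complex pair interacts.
#' @param purity Probability an interaction takes its cluster's majority sign.
#' @param f_positive Probability a cluster's majority sign is positive.
#' @param epsilon_meanlog,epsilon_sdlog Log-normal parameters of `|epsilon|`.
#' @param p_sig Mixture weight of sub-0.05 p-values.
#' @param seed Integer seed.
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_complexes = 20, size_range = c(4, 8),
                              within_density = 0.6, between_density = 0.05,
                              purity = 0.9, f_positive = 0.5,
                              epsilon_meanlog = log(0.15),
                              epsilon_sdlog = 0.6,
                              p_sig = 0.9, seed = 1L) {
  check_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("parameter '%s' must be a probability in [0, 1]", nm))
    }
  }
  if (!is.numeric(n_complexes) || n_complexes < 1) {
    stop("parameter 'n_complexes' must be a positive count")
  }
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[1] > size_range[2]) {
    stop("parameter 'size_range' must be c(min, max) with 2 <= min <= max")
  }
  check_prob(within_density, "within_density")
  check_prob(between_density, "between_density")
  check_prob(purity, "purity")
  check_prob(f_positive, "f_positive")
  check_prob(p_sig, "p_sig")
  if (!is.numeric(epsilon_sdlog) || epsilon_sdlog <= 0) {
    stop("parameter 'epsilon_sdlog' must be > 0")
  }
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 within_density = within_density,
                 between_density = between_density,
                 purity = purity, f_positive = f_positive,
                 epsilon_meanlog = epsilon_meanlog,
                 epsilon_sdlog = epsilon_sdlog,
                 p_sig = p_sig, seed = as.integer(seed)),
            class = "simulation_params")
}

sim_pvalues <- function(n, p_sig) {
  sig <- stats::runif(n) < p_sig
  ifelse(sig, stats::runif(n, 0, 0.05), stats::runif(n))
}

#' Generate a synthetic interaction dataset with known ground truth
#'
#' Draws a complex catalog and an interaction table from the planted-purity
#' model described in [simulation_params()]. The result is deterministic
#' given the seed carried by `params`.
#'
#' @param params A [simulation_params()] object.
#' @return List with `catalog` (a [gene_set_catalog()] of complexes),
#'   `interactions` (an [interaction_set()], `cutoff_level = "raw"`,
#'   `pair_policy = "unordered-collapsed"`), and `truth`, a data frame
#'   recording each planted cluster's majority sign, interaction count and
#'   realized purity.
#' @export
generate_interaction_data <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  sizes <- sample(seq(params$size_range[1], params$size_range[2]),
                  params$n_complexes, replace = TRUE)
  gene_pool <- sprintf("G%05d", seq_len(sum(sizes)))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  catalog <- gene_set_catalog(stats::setNames(
    lapply(seq_len(params$n_complexes),
           function(i) gene_pool[starts[i]:stops[i]]),
    sprintf("CPLX%03d", seq_len(params$n_complexes))), kind = "complexes")

  draw_cluster <- function(members_a, members_b = NULL) {
    pairs <- if (is.null(members_b)) {
      t(utils::combn(members_a, 2))
    } else {
      as.matrix(expand.grid(members_a, members_b, stringsAsFactors = FALSE))
    }
    density <- if (is.null(members_b)) params$within_density
               else params$between_density
    keep <- stats::runif(nrow(pairs)) < density
    pairs <- pairs[keep, , drop = FALSE]
    n <- nrow(pairs)
    majority <- if (stats::runif(1) < params$f_positive) 1 else -1
    if (n == 0) {
      return(list(rows = NULL, majority = majority, n = 0L, purity = NA_real_))
    }
    match_majority <- stats::runif(n) < params$purity
    sgn <- ifelse(match_majority, majority, -majority)
    rows <- data.frame(
      gene_a = pairs[, 1], gene_b = pairs[, 2],
      epsilon = sgn * stats::rlnorm(n, params$epsilon_meanlog,
                                    params$epsilon_sdlog),
      p_value = sim_pvalues(n, params$p_sig),
      stringsAsFactors = FALSE)
    list(rows = rows, majority = majority, n = as.integer(n),
         purity = mean(sgn == majority))
  }

  all_rows <- list()
  truth <- list()
  for (i in seq_len(params$n_complexes)) {
    cl <- draw_cluster(catalog[[i]])
    all_rows[[length(all_rows) + 1]] <- cl$rows
    truth[[length(truth) + 1]] <- data.frame(
      cluster_id = names(catalog)[i], kind = "within",
      majority_sign = if (cl$majority > 0) "positive" else "negative",
      n_interactions = cl$n, realized_purity = cl$purity,
      stringsAsFactors = FALSE)
  }
  if (params$between_density > 0 && params$n_complexes > 1) {
    for (i in seq_len(params$n_complexes - 1)) {
      for (j in seq(i + 1, params$n_complexes)) {
        cl <- draw_cluster(catalog[[i]], catalog[[j]])
        all_rows[[length(all_rows) + 1]] <- cl$rows
        truth[[length(truth) + 1]] <- data.frame(
          cluster_id = paste(names(catalog)[i], names(catalog)[j], sep = "|"),
          kind = "between",
          majority_sign = if (cl$majority > 0) "positive" else "negative",
          n_interactions = cl$n, realized_purity = cl$purity,
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, all_rows[!vapply(all_rows, is.null, logical(1))])
  if (is.null(rows)) {
    rows <- data.frame(gene_a = character(), gene_b = character(),
                       epsilon = numeric(), p_value = numeric())
  }
  list(catalog = catalog,
       interactions = interaction_set(rows, cutoff_level = "raw",
                                      pair_policy = "unordered-collapsed"),
       truth = do.call(rbind, truth))
}

#' Write a generated dataset in the formats the readers consume
#'
#' Emits `interactions.tsv` (gene_a, gene_b, epsilon, p_value),
#' `complexes.gmt` and `truth.tsv` under `dir`.
#'
#' @param data Result of [generate_interaction_data()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    as.data.frame(data$interactions)[c("gene_a", "gene_b", "epsilon", "p_value")],
    file.path(dir, "interactions.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  write_gene_sets(data$catalog, file.path(dir, "complexes.gmt"))
  utils::write.table(data$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Independent Monte-Carlo oracle for the expected MCI
#'
#' Re-simulates the planted-purity model directly in terms of cluster sizes
#' and sign counts — without building gene tables or running the cluster
#' pipeline — and returns the expected MCI of the retained cluster
#' population. Serves as an independent reference for parameter-recovery
#' checks of the full pipeline.
#'
#' @param params A [simulation_params()] object; its seed is NOT used here
#'   (pass `oracle_seed` so the oracle stays independent of the dataset).
#' @param replicates Number of Monte-Carlo replicates (>= 100).
#' @param kind Which cluster population to emulate, `"within"` or
#'   `"between"`.
#' @param min_interactions Retention threshold matching the pipeline.
#' @param oracle_seed Seed for the oracle's own randomness.
#' @return List with `value` (mean over replicates), `se` (standard error of
#'   that mean), `sd` (between-replicate standard deviation, i.e. the
#'   sampling spread of a single dataset's MCI) and `replicates`.
#' @export
expected_mci <- function(params, replicates = 200,
                         kind = c("within", "between"),
                         min_interactions = 2, oracle_seed = 999) {
  stopifnot(inherits(params, "simulation_params"))
  kind <- match.arg(kind)
  if (replicates < 100) stop("need >= 100 oracle replicates")
  set.seed(as.integer(oracle_seed))
  smin <- params$size_range[1]
  smax <- params$size_range[2]
  one_replicate <- function() {
    sizes <- sample(seq(smin, smax), params$n_complexes, replace = TRUE)
    n_pairs <- if (kind == "within") {
      choose(sizes, 2)
    } else {
      idx <- utils::combn(params$n_complexes, 2)
      sizes[idx[1, ]] * sizes[idx[2, ]]
    }
    density <- if (kind == "within") params$within_density
               else params$between_density
    n_int <- stats::rbinom(length(n_pairs), n_pairs, density)
    n_int <- n_int[n_int >= min_interactions]
    if (length(n_int) == 0) return(NA_real_)
    x_major <- stats::rbinom(length(n_int), n_int, params$purity)
    abs_beta <- abs(2 * x_major - n_int) / n_int
    sum(n_int * abs_beta) / sum(n_int)
  }
  values <- vapply(seq_len(replicates), function(r) one_replicate(), numeric(1))
  values <- values[!is.na(values)]
  list(value = mean(values),
       se = stats::sd(values) / sqrt(length(values)),
       sd = stats::sd(values),
       replicates = length(values))
}
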