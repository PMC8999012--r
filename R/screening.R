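#' Degree-preserving randomization null model for network proximity
#'
#' Builds the reference distance distribution for one (drug, disease, metric)
#' combination: in each repetition both modules are replaced by random node
#' sets of the same size and (binned) degree distribution, and the proximity is
#' recomputed under the same metric and target-drop rules. The observed
#' proximity is then standardized against the mean and standard deviation of
#' these samples.
#'
#' @param g An `interactome`.
#' @param drug,disease Modules (character vectors or [gene_module()]s); only
#'   the mapped genes are used.
#' @param metric One of [PROXIMITY_METRICS] (or several; see Value).
#' @param n_reps Number of randomization repetitions (default 1000).
#' @param bins A `degree_bins` object; built with `min_bin_size` 100 (or the
#'   node count, if smaller) when omitted.
#' @param seed Optional integer seed; the caller's RNG stream is restored
#'   afterwards. With the same seed the samples are reproduced exactly.
#' @param fix_disease If `TRUE`, only the drug module is randomized (faster;
#'   the default re-samples both modules each repetition).
#' @return A `null_model` object: list with `samples` (numeric matrix,
#'   `n_reps` rows, one column per metric), `mu` and `sigma` (named per-metric
#'   mean and sd, sd with denominator n - 1), `n_reps`, `metric`, `seed`.
#' @export
build_null <- function(g, drug, disease, metric = "minimum", n_reps = 1000,
                       bins = NULL, seed = NULL, fix_disease = FALSE) {
  for (m in metric) check_metric_(m)
  stopifnot(n_reps >= 1)
  tmod <- as_gene_module_(drug, g, "drug")
  smod <- as_gene_module_(disease, g, "disease")
  if (is.null(bins)) {
    bins <- build_degree_bins(g, min_bin_size = min(100L, igraph::vcount(g)))
  }
  samples <- with_seed_(seed, {
    vapply(seq_len(n_reps), function(i) {
      t_rand <- sample_degree_matched(bins, tmod$mapped)
      s_rand <- if (fix_disease) smod$mapped else sample_degree_matched(bins, smod$mapped)
      d <- module_distance_matrix_(g, t_rand, s_rand)
      summarize_matrix_(d, metric)$values
    }, numeric(length(metric)))
  })
  samples <- matrix(samples, nrow = n_reps, ncol = length(metric),
                    byrow = TRUE, dimnames = list(NULL, metric))
  structure(
    list(
      samples = samples,
      mu = colMeans(samples),
      sigma = apply(samples, 2L, stats::sd),
      n_reps = n_reps,
      metric = metric,
      seed = seed
    ),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> ", x$n_reps, " degree-preserving repetitions\n", sep = "")
  for (m in x$metric) {
    cat("  ", format(m, width = 8), " mu = ", signif(x$mu[[m]], 4),
        ", sigma = ", signif(x$sigma[[m]], 4), "\n", sep = "")
  }
  invisible(x)
}

#' Significance of an observed proximity against a null model
#'
#' Standardizes the observed proximity: z = (observed - mu) / sigma, with the
#' one-sided lower-tail normal p-value (small distances, i.e. proximal
#' modules, are the signal). The empirical p-value
#' (1 + #\{samples <= observed\}) / (n_reps + 1) is always reported alongside;
#' when sigma is zero the z-based p-value is undefined and falls back to the
#' empirical one, flagged by `degenerate`.
#'
#' @param observed Observed proximity value.
#' @param null A `null_model` from [build_null()].
#' @param metric Which metric column of the null to use (defaults to the
#'   null's only metric).
#' @return A one-row tibble: `observed`, `mu`, `sigma`, `z`, `p_value`,
#'   `empirical_p`, `degenerate`.
#' @export
significance <- function(observed, null, metric = NULL) {
  stopifnot(inherits(null, "null_model"))
  metric <- metric %||% null$metric[[1L]]
  if (!metric %in% null$metric) abort(paste0("null model has no metric '", metric, "'"))
  samples <- null$samples[, metric]
  mu <- null$mu[[metric]]
  sigma <- null$sigma[[metric]]
  empirical_p <- (1 + sum(samples <= observed)) / (null$n_reps + 1)
  if (is.na(sigma) || sigma == 0) {
    tibble(observed = observed, mu = mu, sigma = sigma, z = NA_real_,
           p_value = empirical_p, empirical_p = empirical_p, degenerate = TRUE)
  } else {
    z <- (observed - mu) / sigma
    tibble(observed = observed, mu = mu, sigma = sigma, z = z,
           p_value = stats::pnorm(z), empirical_p = empirical_p,
           degenerate = FALSE)
  }
}

#' Screen candidate drugs against a disease module
#'
#' Runs the full proximity + randomization-null significance test for every
#' drug under every requested metric and flags drugs closer to the disease
#' module than expected by chance at level `alpha`. Drugs failing the
#' preconditions (no mapped target, fewer than `min_targets` mapped targets,
#' or every target unreachable) are reported in a skip log attached to the
#' result, never silently dropped. Per drug, one set of random draws is
#' shared across metrics (each random distance matrix is summarized under all
#' requested metrics); repetitions remain independent.
#'
#' @param g An `interactome`.
#' @param drugs Drug target sets: a data frame with columns `drug`/`set` and
#'   `gene` (as from [read_gene_sets()]), or a named list of character vectors.
#' @param disease Disease module (character vector or [gene_module()]).
#' @param metrics Metrics to screen under (default: all five).
#' @param n_reps Randomization repetitions per drug (default 1000).
#' @param alpha Significance level on the p-value (default 0.05).
#' @param seed Integer seed governing all randomization (required for
#'   reproducibility; `NULL` uses the current RNG stream).
#' @param bins Optional precomputed `degree_bins`; built once with
#'   `min_bin_size` (capped at the node count) when omitted.
#' @param min_bin_size Used when `bins` is omitted (default 100).
#' @param min_targets Passed to [proximity()] (default 2).
#' @param p_type `"normal"` (default; matches the z-statistic formulation) or
#'   `"empirical"` — which p-value drives the `significant` flag.
#' @param fix_disease Randomize only the drug module (default `FALSE`:
#'   both modules are re-drawn each repetition).
#' @param disease_name Label for plain character `disease`.
#' @return A `proximity_screen` tibble, one row per (drug, metric), sorted by
#'   (metric, p_value, drug), with columns `drug`, `disease`, `metric`,
#'   `observed`, `mu`, `sigma`, `z`, `p_value`, `empirical_p`, `degenerate`,
#'   `significant`, `n_targets_used`, `n_targets_dropped`. The skip log is in
#'   `attr(x, "skip_log")` (tibble `drug`, `reason`) and via [skip_log()].
#' @export
screen <- function(g, drugs, disease, metrics = PROXIMITY_METRICS,
                   n_reps = 1000, alpha = 0.05, seed = NULL, bins = NULL,
                   min_bin_size = 100, min_targets = 2,
                   p_type = c("normal", "empirical"), fix_disease = FALSE,
                   disease_name = "disease") {
  p_type <- match.arg(p_type)
  for (m in metrics) check_metric_(m)
  drug_list <- gene_sets_to_list_(drugs)
  smod <- as_gene_module_(disease, g, disease_name)
  if (length(smod$mapped) == 0L) {
    abort(paste0("disease module '", smod$name, "' has no genes in the interactome"))
  }
  if (is.null(bins)) {
    bins <- build_degree_bins(g, min_bin_size = min(min_bin_size, igraph::vcount(g)))
  }

  rows <- list()
  skips <- list()
  with_seed_(seed, {
    for (drug_name in names(drug_list)) {
      obs <- tryCatch(
        proximity(g, drug_list[[drug_name]], smod, metric = metrics,
                  min_targets = min_targets, drug_name = drug_name),
        error = function(e) conditionMessage(e)
      )
      if (is.character(obs)) {
        skips[[length(skips) + 1L]] <- tibble(drug = drug_name, reason = obs)
        next
      }
      null <- build_null(g, drug_list[[drug_name]], smod, metric = metrics,
                         n_reps = n_reps, bins = bins, seed = NULL,
                         fix_disease = fix_disease)
      sig <- dplyr::bind_rows(lapply(metrics, function(m) {
        significance(obs$proximity[obs$metric == m], null, metric = m)
      }))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(drug = drug_name, disease = smod$name, metric = metrics),
        sig,
        tibble(n_targets_used = obs$n_targets_used[1L],
               n_targets_dropped = obs$n_targets_dropped[1L])
      )
    }
  })

  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble(drug = character(), disease = character(), metric = character(),
           observed = numeric(), mu = numeric(), sigma = numeric(),
           z = numeric(), p_value = numeric(), empirical_p = numeric(),
           degenerate = logical(), n_targets_used = integer(),
           n_targets_dropped = integer())
  pcol <- if (p_type == "normal") out$p_value else out$empirical_p
  out$significant <- pcol <= alpha
  out <- dplyr::arrange(out, factor(.data$metric, levels = metrics),
                        .data$p_value, .data$drug)
  attr(out, "skip_log") <- if (length(skips) > 0L) dplyr::bind_rows(skips) else
    tibble(drug = character(), reason = character())
  attr(out, "alpha") <- alpha
  attr(out, "p_type") <- p_type
  class(out) <- c("proximity_screen", class(out))
  out
}

#' @rdname screen
#' @param x A `proximity_screen`.
#' @export
skip_log <- function(x) {
  attr(x, "skip_log")
}

#' @export
tidy.proximity_screen <- function(x, ...) {
  out <- x
  attr(out, "skip_log") <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "p_type") <- NULL
  class(out) <- setdiff(class(out), "proximity_screen")
  as_tibble(out)
}

#' @export
glance.proximity_screen <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tidy(x), .data$metric),
    n_drugs = dplyr::n(),
    n_significant = sum(.data$significant),
    frac_significant = mean(.data$significant),
    .groups = "drop"
  )
}

#' Annotate screened drugs with known medical indications
#'
#' Adds a `has_known_indication` flag to screen records and summarizes, per
#' metric, the percentage of significant drugs that already have a known
#' indication for the screened disease (the sanity check that a screen
#' recovers established therapies).
#'
#' @param records A `proximity_screen` (or compatible tibble with `drug`,
#'   `metric`, `significant`).
#' @param indications A data frame with columns `drug` and `indication`, or a
#'   named list drug -> character vector of indication terms. Drugs unknown to
#'   the screen trigger a warning and are ignored.
#' @return `records` with an added `has_known_indication` column and an
#'   `indication_summary` attribute: tibble with `metric`, `n_significant`,
#'   `n_with_indication`, `pct_with_indication` (`NA` when a metric has no
#'   significant drug). Retrieve it with [indication_summary()].
#' @export
annotate_known_indications <- function(records, indications) {
  annotated_drugs <- if (is.data.frame(indications)) {
    unique(as.character(indications[[1L]]))
  } else {
    names(indications)
  }
  unknown <- setdiff(annotated_drugs, unique(records$drug))
  if (length(unknown) > 0L) {
    warn(paste0("indication annotations for drug(s) not in the screen ignored: ",
                paste(unknown, collapse = ", ")))
  }
  records$has_known_indication <- records$drug %in% annotated_drugs
  summary <- dplyr::summarise(
    dplyr::group_by(as_tibble(records), .data$metric),
    n_significant = sum(.data$significant),
    n_with_indication = sum(.data$significant & .data$has_known_indication),
    .groups = "drop"
  )
  summary <- dplyr::mutate(
    summary,
    pct_with_indication = ifelse(.data$n_significant > 0,
                                 100 * .data$n_with_indication / .data$n_significant,
                                 NA_real_)
  )
  attr(records, "indication_summary") <- summary
  records
}

#' @rdname annotate_known_indications
#' @param x Annotated records.
#' @export
indication_summary <- function(x) {
  attr(x, "indication_summary")
}
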