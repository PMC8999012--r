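#' The five distance-summary metrics
#'
#' Network proximity between a drug module T and a disease module S is the
#' average over drug targets t of a per-target summary f of the shortest-path
#' distances d(t, s) to the disease genes s. The classic choice of f is the
#' minimum (distance to the nearest disease gene); this package also supports
#' maximum, mean, median and mode.
#'
#' @format Character vector of the five metric names.
#' @export
PROXIMITY_METRICS <- c("minimum", "maximum", "mean", "median", "mode")

check_metric_ <- function(metric) {
  if (length(metric) != 1L || !metric %in% PROXIMITY_METRICS) {
    abort(paste0("unknown metric: ", paste(metric, collapse = ", "),
                 " (must be one of ", paste(PROXIMITY_METRICS, collapse = ", "), ")"))
  }
  metric
}

#' Summarize a vector of shortest-path distances under one metric
#'
#' @param values Non-empty numeric vector of finite, non-negative distances.
#' @param metric One of `"minimum"`, `"maximum"`, `"mean"`, `"median"`,
#'   `"mode"`. The median of an even-length vector is the mean of the two
#'   central values; the mode is the most frequent value, ties broken towards
#'   the smallest tied value.
#' @return A single numeric summary.
#' @examples
#' summarize_distances(c(3, 4), "mode")    # tie broken low -> 3
#' summarize_distances(c(2, 2, 7), "mean") # 11/3
#' @export
summarize_distances <- function(values, metric) {
  check_metric_(metric)
  if (length(values) == 0L) abort("cannot summarize an empty distance vector")
  if (any(!is.finite(values))) abort("distance vector contains non-finite values")
  switch(metric,
    minimum = min(values),
    maximum = max(values),
    mean = mean(values),
    median = stats::median(values),
    mode = mode_low_(values)
  )
}

# most frequent value; ties broken by the smallest tied value
mode_low_ <- function(values) {
  tab <- table(values)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes the first maximum;
  # table() sorts its names ascending, so the first maximum is the smallest
}

# Distance matrix between mapped drug targets (rows) and disease genes
# (columns); one BFS per target via igraph.
module_distance_matrix_ <- function(g, t_nodes, s_nodes) {
  d <- igraph::distances(g, v = t_nodes, to = s_nodes, algorithm = "unweighted")
  rownames(d) <- t_nodes
  d
}

# Summarize a precomputed distance matrix under one or more metrics.
# Targets whose whole distance row is infinite are dropped and counted.
# Returns list(values = named numeric per metric, per_target = list of named
# numeric vectors per metric, n_used, n_dropped).
summarize_matrix_ <- function(d, metrics) {
  finite_rows <- apply(is.finite(d), 1L, any)
  n_dropped <- sum(!finite_rows)
  d <- d[finite_rows, , drop = FALSE]
  if (nrow(d) == 0L) {
    abort("all drug targets dropped: no finite distance to any disease gene")
  }
  per_target <- lapply(metrics, function(m) {
    vapply(seq_len(nrow(d)), function(i) {
      row <- d[i, ]
      summarize_distances(row[is.finite(row)], m)
    }, numeric(1L)) |> setNames(rownames(d))
  })
  names(per_target) <- metrics
  list(
    values = vapply(per_target, mean, numeric(1L)),
    per_target = per_target,
    n_used = nrow(d),
    n_dropped = n_dropped
  )
}

#' Network proximity between a drug module and a disease module
#'
#' Computes p(T, S): for each mapped drug target t, the summary `metric` of its
#' shortest-path distances to the mapped disease genes, then the arithmetic
#' mean over targets. Targets with no finite distance to any disease gene are
#' dropped and counted. Note p(T, S) is generally not equal to p(S, T): the
#' outer mean always runs over the drug targets.
#'
#' @param g An `interactome`.
#' @param drug Drug module: character vector of target genes or a
#'   [gene_module()].
#' @param disease Disease module: character vector of disease genes or a
#'   [gene_module()].
#' @param metric One of [PROXIMITY_METRICS], or a vector of several.
#' @param min_targets Minimum number of mapped targets required (default 2,
#'   mirroring the restriction to drugs with at least two annotated targets);
#'   set to 1 to score single-target drugs.
#' @param drug_name,disease_name Labels used when `drug`/`disease` are plain
#'   character vectors.
#' @return A tibble with one row per metric: `drug`, `disease`, `metric`,
#'   `proximity`, `n_targets_used`, `n_targets_dropped`, and a list-column
#'   `per_target` of named per-target summaries.
#' @examples
#' g <- as_interactome(data.frame(
#'   from = c("a", "b", "c", "d"), to = c("b", "c", "d", "e")))
#' proximity(g, c("a", "d"), c("c", "e"), metric = "minimum")
#' @export
proximity <- function(g, drug, disease, metric = "minimum", min_targets = 2,
                      drug_name = "drug", disease_name = "disease") {
  for (m in metric) check_metric_(m)
  tmod <- as_gene_module_(drug, g, drug_name)
  smod <- as_gene_module_(disease, g, disease_name)
  if (length(smod$mapped) == 0L) {
    abort(paste0("disease module '", smod$name, "' has no genes in the interactome"))
  }
  if (length(tmod$mapped) == 0L) {
    abort(paste0("drug module '", tmod$name, "' has no targets in the interactome"))
  }
  if (length(tmod$mapped) < min_targets) {
    abort(paste0("drug module '", tmod$name, "' has ", length(tmod$mapped),
                 " mapped target(s), fewer than min_targets = ", min_targets))
  }
  d <- module_distance_matrix_(g, tmod$mapped, smod$mapped)
  res <- summarize_matrix_(d, metric)
  tibble(
    drug = tmod$name,
    disease = smod$name,
    metric = metric,
    proximity = unname(res$values),
    n_targets_used = res$n_used,
    n_targets_dropped = res$n_dropped,
    per_target = unname(res$per_target)
  )
}

#' @rdname proximity
#' @param ... Passed on to [proximity()].
#' @details `proximity_all_metrics()` computes each target's distance vector
#'   once and summarizes it under all five metrics, so it is equivalent to but
#'   faster than five separate `proximity()` calls.
#' @export
proximity_all_metrics <- function(g, drug, disease, ...) {
  proximity(g, drug, disease, metric = PROXIMITY_METRICS, ...)
}
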