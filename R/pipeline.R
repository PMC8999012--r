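#' Run the full proximity-screening and validation pipeline
#'
#' Orchestrates the whole analysis: load (or accept) the interactome, screen
#' every drug module against the disease module under the requested metrics
#' with the degree-preserving null, optionally annotate known indications,
#' optionally build the disease signature from paired expression and score
#' drug ranked lists for counteraction, and write all result tables plus a
#' machine-readable JSON summary.
#'
#' @param graph An `interactome` or path to an edge-list file.
#' @param drug_targets Drug target sets: data frame/named list, or path to a
#'   two-column TSV / GMT file.
#' @param disease_genes Disease module: character vector, or path to a
#'   gene-set file (all sets therein are pooled unless exactly one is present).
#' @param out_dir Output directory; created if missing.
#' @param metrics,n_reps,alpha,min_targets,min_bin_size,p_type Passed to
#'   [screen()].
#' @param seed Integer seed for all randomization (mandatory).
#' @param lcc Restrict the analysis to the largest connected component
#'   (default `TRUE`; with `FALSE` unreachable distances are excluded from the
#'   inner summaries and counted per drug).
#' @param expression,pairs Optional paths (or a `paired_expression`) for the
#'   disease-signature stage.
#' @param rankings Optional drug ranked lists (named list, data frame, or
#'   path) for the connectivity stage.
#' @param indications Optional drug -> indication table (data frame or path).
#' @param adj_threshold,tag_size Signature / connectivity parameters.
#' @return Invisibly, a list with elements `screen`, `signature`,
#'   `connectivity`, `summary` and the written file paths. Files written:
#'   `screen.tsv`, `skip_log.tsv`, and when inputs allow `signature.tsv` and
#'   `connectivity.tsv`, plus `summary.json` with per-metric counts of
#'   significant drugs, the percentage with known indications, and the
#'   percentage of counteracting drugs.
#' @export
run_pipeline <- function(graph, drug_targets, disease_genes, out_dir,
                         metrics = PROXIMITY_METRICS, n_reps = 1000,
                         alpha = 0.05, seed = NULL, lcc = TRUE,
                         min_targets = 2, min_bin_size = 100,
                         p_type = "normal",
                         expression = NULL, pairs = NULL, rankings = NULL,
                         indications = NULL, adj_threshold = 0.01,
                         tag_size = 150) {
  if (is.null(seed)) abort("a seed is required for the randomization null")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  g <- if (is.character(graph)) load_edge_list(graph) else graph
  if (lcc) g <- largest_component(g)
  drugs <- if (is.character(drug_targets) && length(drug_targets) == 1L &&
               file.exists(drug_targets)) {
    read_gene_sets(drug_targets)
  } else drug_targets
  disease <- if (is.character(disease_genes) && length(disease_genes) == 1L &&
                 file.exists(disease_genes)) {
    sets <- read_gene_sets(disease_genes)
    sets$gene
  } else disease_genes

  records <- screen(g, drugs, disease, metrics = metrics, n_reps = n_reps,
                    alpha = alpha, seed = seed, min_bin_size = min_bin_size,
                    min_targets = min_targets, p_type = p_type)
  ind_summary <- NULL
  if (!is.null(indications)) {
    if (is.character(indications)) indications <- read_gene_sets(indications)
    records <- suppressWarnings(annotate_known_indications(records, indications))
    ind_summary <- indication_summary(records)
  }
  readr::write_tsv(dplyr::select(tidy(records), -dplyr::any_of("per_target")),
                   file.path(out_dir, "screen.tsv"))
  readr::write_tsv(skip_log(records), file.path(out_dir, "skip_log.tsv"))

  signature <- NULL
  if (!is.null(expression)) {
    pe <- if (inherits(expression, "paired_expression")) expression else
      read_paired_expression(expression, pairs)
    signature <- build_disease_signature(pe, adj_threshold = adj_threshold)
    readr::write_tsv(tidy(signature), file.path(out_dir, "signature.tsv"))
  }

  scores <- NULL
  if (!is.null(rankings) && !is.null(signature)) {
    if (is.character(rankings)) rankings <- read_rankings(rankings)
    scores <- score_drugs(rankings, signature, tag_size = tag_size)
    readr::write_tsv(as_tibble(scores), file.path(out_dir, "connectivity.tsv"))
  }

  per_metric <- glance(records)
  summary <- list(
    seed = seed,
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_drugs_screened = length(unique(records$drug)),
    n_drugs_skipped = nrow(skip_log(records)),
    alpha = alpha,
    n_reps = n_reps,
    per_metric = lapply(seq_len(nrow(per_metric)), function(i) {
      row <- as.list(per_metric[i, ])
      if (!is.null(ind_summary)) {
        row$pct_with_known_indication <-
          ind_summary$pct_with_indication[ind_summary$metric == row$metric]
      }
      row
    }),
    signature = if (!is.null(signature)) as.list(glance(signature)),
    connectivity = if (!is.null(scores)) as.list(glance(scores))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (nrow(records) == 0L) warn("screen produced no records; see skip_log.tsv")
  invisible(list(screen = records, signature = signature,
                 connectivity = scores, summary = summary,
                 out_dir = out_dir))
}
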