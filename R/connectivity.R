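#' Kolmogorov-Smirnov enrichment statistic for a tag set in a ranked list
#'
#' The classic connectivity-map running-sum statistic: given the positions of
#' a set of tag genes within a ranked list of n genes, with sorted positions
#' V(1..t),
#' a = max_j ( j/t - V(j)/n ) and b = max_j ( V(j)/n - (j-1)/t );
#' the statistic is a if a > b, else -b. Positive values mean the tags
#' concentrate near the top of the list, negative near the bottom.
#'
#' @param tag_positions Distinct integer positions in 1..n.
#' @param n Length of the ranked list.
#' @return A single value in (-1, 1].
#' @examples
#' ks_enrichment(c(1, 2), 10)   #  0.8: tags at the very top
#' ks_enrichment(c(9, 10), 10)  # -0.9: tags at the very bottom
#' @export
ks_enrichment <- function(tag_positions, n) {
  if (length(tag_positions) == 0L) abort("empty tag set")
  v <- sort(as.numeric(tag_positions))
  t <- length(v)
  if (anyDuplicated(v) || any(v < 1) || any(v > n)) {
    abort("tag positions must be distinct integers in 1..n")
  }
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

# coerce a ranked drug list (character vector, or tibble with gene [+ rank])
# to an ordered character vector, position 1 = most up-regulated by the drug
as_ranked_list_ <- function(x) {
  if (is.character(x)) {
    genes <- x
  } else if (is.data.frame(x)) {
    genes <- if ("rank" %in% names(x)) {
      as.character(x$gene[order(x$rank)])
    } else {
      as.character(x$gene)
    }
  } else {
    abort("a ranked list must be a character vector or a data frame with a `gene` column")
  }
  if (anyDuplicated(genes)) abort("ranked list contains duplicate genes")
  if (length(genes) < 2L) abort("ranked list must contain at least 2 genes")
  genes
}

#' Enrichment of a disease signature in a drug's ranked expression list
#'
#' Scores whether a drug's transcriptional response opposes a disease's: the
#' top disease up-regulated genes and top down-regulated genes (up to
#' `tag_size` each) are located in the drug's ranked list and scored with
#' [ks_enrichment()]. When the two one-sided scores have opposite signs, the
#' combined score is es = (es_up - es_down) / 2; when they share a sign the
#' evidence is contradictory and es = 0. A drug with es < 0 ranks the
#' disease's up genes low and its down genes high — a complementary profile —
#' and gets counteraction score 1.
#'
#' @param drug_ranking Ordered gene list of the drug signature (position 1 =
#'   most up-regulated by the drug): character vector or data frame with
#'   `gene` (and optional `rank`) columns.
#' @param disease A `disease_signature` from [build_disease_signature()], or a
#'   list with ordered `up` and `down` gene vectors.
#' @param tag_size Maximum number of up (and down) tag genes used
#'   (default 150); truncated to the available signature genes.
#' @return A one-row tibble: `es`, `es_up`, `es_down`, `counteraction` (1 if
#'   es < 0 else 0), `n_tags_up`, `n_tags_down`, `n_missing` (signature tag
#'   genes absent from the drug list, dropped).
#' @export
enrichment <- function(drug_ranking, disease, tag_size = 150) {
  genes <- as_ranked_list_(drug_ranking)
  n <- length(genes)
  up <- head(disease$up, tag_size)
  down <- head(disease$down, tag_size)
  pos_up <- match(up, genes)
  pos_down <- match(down, genes)
  n_missing <- sum(is.na(pos_up)) + sum(is.na(pos_down))
  pos_up <- pos_up[!is.na(pos_up)]
  pos_down <- pos_down[!is.na(pos_down)]
  if (length(pos_up) == 0L && length(pos_down) == 0L) {
    abort("no disease signature gene found in the drug ranked list")
  }
  es_up <- if (length(pos_up) > 0L) ks_enrichment(pos_up, n) else NA_real_
  es_down <- if (length(pos_down) > 0L) ks_enrichment(pos_down, n) else NA_real_
  es <- if (is.na(es_down)) {
    es_up
  } else if (is.na(es_up)) {
    -es_down
  } else if (sign(es_up) == sign(es_down)) {
    0
  } else {
    (es_up - es_down) / 2
  }
  tibble(
    es = es, es_up = es_up, es_down = es_down,
    counteraction = as.integer(es < 0),
    n_tags_up = length(pos_up), n_tags_down = length(pos_down),
    n_missing = n_missing
  )
}

#' Score a collection of drug signatures against a disease signature
#'
#' Applies [enrichment()] to every drug ranked list and summarizes the
#' percentage of drugs with counteraction score 1 (es < 0), i.e. drugs whose
#' expression response potentially reverses the disease phenotype. A drug
#' whose scoring fails (for example, no signature gene in its list) gets `NA`
#' scores and a warning rather than stopping the batch.
#'
#' @param drug_lists Named list of ranked gene lists, or a data frame with
#'   columns `drug`, `gene` and optionally `rank` (rows in rank order
#'   otherwise).
#' @param disease A `disease_signature`.
#' @param tag_size Passed to [enrichment()].
#' @return A `connectivity_scores` tibble, one row per drug (`drug`, `es`,
#'   `es_up`, `es_down`, `counteraction`, ...), with the summary percentage in
#'   `attr(x, "pct_counteracting")` (`NA` if no drug could be scored);
#'   [glance()] returns it with the counts.
#' @export
score_drugs <- function(drug_lists, disease, tag_size = 150) {
  if (is.data.frame(drug_lists)) {
    stopifnot("drug" %in% names(drug_lists), "gene" %in% names(drug_lists))
    if ("rank" %in% names(drug_lists)) {
      drug_lists <- dplyr::arrange(drug_lists, .data$drug, .data$rank)
    }
    drug_lists <- split(as.character(drug_lists$gene), as.character(drug_lists$drug))
  }
  if (length(drug_lists) == 0L) abort("no drug ranked lists supplied")
  rows <- purrr::imap(drug_lists, function(genes, drug_name) {
    res <- tryCatch(enrichment(genes, disease, tag_size = tag_size),
                    error = function(e) {
                      warn(paste0("drug '", drug_name, "' not scored: ",
                                  conditionMessage(e)))
                      tibble(es = NA_real_, es_up = NA_real_, es_down = NA_real_,
                             counteraction = NA_integer_, n_tags_up = 0L,
                             n_tags_down = 0L, n_missing = NA_integer_)
                    })
    dplyr::bind_cols(tibble(drug = drug_name), res)
  })
  out <- dplyr::bind_rows(rows)
  scored <- !is.na(out$counteraction)
  pct <- if (any(scored)) 100 * mean(out$counteraction[scored] == 1L) else NA_real_
  attr(out, "pct_counteracting") <- pct
  class(out) <- c("connectivity_scores", class(out))
  out
}

#' @export
glance.connectivity_scores <- function(x, ...) {
  tibble(
    n_drugs = nrow(x),
    n_scored = sum(!is.na(x$counteraction)),
    n_counteracting = sum(x$counteraction == 1L, na.rm = TRUE),
    pct_counteracting = attr(x, "pct_counteracting")
  )
}

#' Read drug ranked gene lists
#'
#' Accepts either a three-column TSV `drug gene rank` or a GMT-like file with
#' one drug per row (name, description, then genes in rank order).
#'
#' @param path Input file.
#' @param format `"auto"` (by `.gmt` extension), `"tsv"` or `"gmt"`.
#' @return Named list of ordered gene character vectors.
#' @export
read_rankings <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    sets <- read_gene_sets(path, format = "gmt")
    split(sets$gene, sets$set)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("drug", "gene", "rank") %in% names(tab)))
    tab <- dplyr::arrange(tab, .data$drug, .data$rank)
    split(as.character(tab$gene), as.character(tab$drug))
  }
}
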