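#' Paired tumor/normal expression container
#'
#' Holds a genes-by-samples matrix of non-negative normalized expression
#' values together with the tumor/normal sample pairing. Rows with missing
#' values are dropped at construction and reported.
#'
#' @param values A numeric matrix (genes in rows, samples in columns, with
#'   row and column names) or a data frame whose first column is the gene
#'   identifier and remaining columns are samples.
#' @param pairs A data frame with columns `tumor` and `normal` giving matched
#'   sample identifiers; every identifier must be a column of `values` and
#'   each tumor has exactly one matched normal.
#' @return A `paired_expression` object: list with `genes`, `pairs` (tibble),
#'   `tumor` and `normal` (aligned genes x pairs matrices) and attribute-like
#'   element `n_dropped_genes`.
#' @export
paired_expression <- function(values, pairs) {
  if (is.data.frame(values)) {
    genes <- as.character(values[[1L]])
    m <- as.matrix(values[, -1L, drop = FALSE])
    rownames(m) <- genes
  } else {
    m <- values
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("`values` must have gene row names and sample column names")
  }
  storage.mode(m) <- "double"
  pairs <- tibble(tumor = as.character(pairs[[1L]]),
                  normal = as.character(pairs[[2L]]))
  if (anyDuplicated(pairs$tumor) || anyDuplicated(pairs$normal)) {
    abort("each tumor sample must have exactly one matched normal (duplicated ids)")
  }
  missing_cols <- setdiff(c(pairs$tumor, pairs$normal), colnames(m))
  if (length(missing_cols) > 0L) {
    abort(paste0("sample(s) in pairing absent from expression matrix: ",
                 paste(missing_cols, collapse = ", ")))
  }
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    inform(paste0("dropped ", n_dropped, " gene(s) with missing values"))
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) == 0L) abort("no genes left after dropping rows with missing values")
  structure(
    list(
      genes = rownames(m),
      pairs = pairs,
      tumor = m[, pairs$tumor, drop = FALSE],
      normal = m[, pairs$normal, drop = FALSE],
      n_dropped_genes = n_dropped
    ),
    class = "paired_expression"
  )
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("<paired_expression> ", length(x$genes), " gene(s) x ", nrow(x$pairs),
      " tumor/normal pair(s)\n", sep = "")
  invisible(x)
}

#' Read a paired expression matrix and its sample pairing from TSV files
#'
#' @param expression_path TSV with the gene identifier in the first column and
#'   one column per sample.
#' @param pairs_path Two-column TSV `tumor_id normal_id` (no header required;
#'   a header row is detected when its fields are not sample columns).
#' @param delimiter Field separator.
#' @return A [paired_expression()] object.
#' @export
read_paired_expression <- function(expression_path, pairs_path, delimiter = "\t") {
  expr <- readr::read_delim(expression_path, delim = delimiter,
                            show_col_types = FALSE, progress = FALSE)
  pr <- readr::read_delim(pairs_path, delim = delimiter, col_names = FALSE,
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(pr) < 2L) abort("pairing file must have two columns: tumor_id, normal_id")
  samp <- colnames(expr)[-1L]
  if (!(pr[[1L]][1L] %in% samp) && !(pr[[2L]][1L] %in% samp)) pr <- pr[-1L, ]
  paired_expression(expr, pr)
}

#' Log2-transform expression values
#'
#' Maps every value v to log2(v + pseudocount). The default pseudocount of 1
#' keeps zero abundances at zero on the log scale.
#'
#' @param m A `paired_expression`.
#' @param pseudocount Non-negative offset added before the log (default 1).
#' @return The transformed `paired_expression`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "paired_expression"), pseudocount >= 0)
  if (any(m$tumor < 0) || any(m$normal < 0)) {
    abort("expression values must be non-negative before log transformation")
  }
  m$tumor <- log2(m$tumor + pseudocount)
  m$normal <- log2(m$normal + pseudocount)
  m
}

#' Filter out low-variability genes by interquartile range
#'
#' Computes each gene's IQR (75th minus 25th percentile of its values across
#' all samples, linear interpolation between order statistics) and removes
#' genes whose IQR falls strictly below the `percentile_cut`-th percentile of
#' the gene-IQR distribution. These are the genes least scattered around their
#' median, carrying little differential signal.
#'
#' @param m A `paired_expression` (typically already log-transformed).
#' @param percentile_cut Percentile of the gene-IQR distribution used as the
#'   cut (default 10; 0 removes nothing).
#' @return The filtered `paired_expression`, with the removed gene names in
#'   `attr(x, "removed_genes")`.
#' @export
iqr_filter <- function(m, percentile_cut = 10) {
  stopifnot(inherits(m, "paired_expression"))
  if (ncol(m$tumor) + ncol(m$normal) < 2L) abort("need at least 2 samples per gene")
  all_values <- cbind(m$tumor, m$normal)
  iqr <- apply(all_values, 1L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2L] - q[1L]
  })
  cut <- stats::quantile(iqr, percentile_cut / 100, type = 7, names = FALSE)
  keep <- iqr >= cut
  if (!any(keep)) abort("IQR filter removed every gene")
  removed <- m$genes[!keep]
  m$tumor <- m$tumor[keep, , drop = FALSE]
  m$normal <- m$normal[keep, , drop = FALSE]
  m$genes <- m$genes[keep]
  attr(m, "removed_genes") <- removed
  m
}

#' Paired t-test per gene
#'
#' For each gene, tests the per-pair differences tumor - normal against zero
#' (two-sided, df = n - 1). Genes whose differences have zero variance get
#' p = 1 and are flagged rather than excluded, keeping the gene universe
#' aligned across pipeline stages.
#'
#' @param m A `paired_expression` with at least 2 sample pairs.
#' @return A tibble with columns `gene`, `mean_diff` (mean tumor - normal
#'   difference; the log2 fold change when `m` is log2-transformed), `t`,
#'   `p_value`, `zero_variance`.
#' @export
paired_t_test <- function(m) {
  stopifnot(inherits(m, "paired_expression"))
  n <- nrow(m$pairs)
  if (n < 2L) abort("paired t-test needs at least 2 sample pairs")
  delta <- m$tumor - m$normal
  mean_d <- rowMeans(delta)
  # sd via the one-pass identity; guard tiny negatives from cancellation
  ss <- rowSums((delta - mean_d)^2)
  sd_d <- sqrt(pmax(ss, 0) / (n - 1L))
  zero_var <- sd_d == 0
  tstat <- ifelse(zero_var, NA_real_, mean_d / (sd_d / sqrt(n)))
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df = n - 1L))
  tibble(gene = m$genes, mean_diff = unname(mean_d), t = unname(tstat),
         p_value = unname(p), zero_variance = unname(zero_var))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, adj_(i) = min over j >= i of p_(j) * m / j, capped at 1 and
#' returned in the original input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Build a disease signature from paired tumor/normal expression
#'
#' Runs the full differential-expression pipeline — log2 transform, IQR
#' filter, per-gene paired t-test, Benjamini-Hochberg adjustment — and splits
#' the genes passing the adjusted-p threshold by the sign of their log2 fold
#' change into up- and down-regulated lists, each ranked by absolute fold
#' change (up: descending fold change; down: ascending, most repressed first).
#'
#' @param m A `paired_expression` of raw (non-negative, normalized) values.
#' @param adj_threshold Threshold on the BH-adjusted p-value (default 0.01).
#' @param percentile_cut IQR-filter percentile (default 10).
#' @param pseudocount Pseudocount for the log2 transform (default 1).
#' @return A `disease_signature` object: list with `up` and `down` (ordered
#'   gene vectors), and `stats`, a tibble with `gene`, `lfc` (log2 fold
#'   change), `t`, `p_value`, `adj_p`, `significant`, `direction`
#'   (`"up"`/`"down"`/`NA`). An empty signature triggers a warning.
#' @export
build_disease_signature <- function(m, adj_threshold = 0.01,
                                    percentile_cut = 10, pseudocount = 1) {
  m <- log_transform(m, pseudocount = pseudocount)
  m <- iqr_filter(m, percentile_cut = percentile_cut)
  res <- paired_t_test(m)
  res$adj_p <- bh_adjust(res$p_value)
  res$significant <- res$adj_p <= adj_threshold
  res$direction <- ifelse(res$significant,
                          ifelse(res$mean_diff > 0, "up", "down"),
                          NA_character_)
  stats <- dplyr::rename(res, lfc = "mean_diff")
  sig <- stats[stats$significant, ]
  up <- sig$gene[sig$lfc > 0][order(-sig$lfc[sig$lfc > 0])]
  down <- sig$gene[sig$lfc < 0][order(sig$lfc[sig$lfc < 0])]
  if (length(up) + length(down) == 0L) {
    warn(paste0("no gene passed adjusted p <= ", adj_threshold,
                ": empty disease signature"))
  }
  structure(
    list(up = up, down = down, stats = stats,
         adj_threshold = adj_threshold,
         removed_by_iqr = attr(m, "removed_genes")),
    class = "disease_signature"
  )
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("<disease_signature> ", length(x$up), " up-regulated, ", length(x$down),
      " down-regulated gene(s) at adjusted p <= ", x$adj_threshold, "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.disease_signature <- function(x, ...) {
  x$stats
}

#' @export
glance.disease_signature <- function(x, ...) {
  tibble(
    n_tested = nrow(x$stats),
    n_up = length(x$up),
    n_down = length(x$down),
    n_removed_by_iqr = length(x$removed_by_iqr),
    adj_threshold = x$adj_threshold
  )
}
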