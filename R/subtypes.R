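#' Breast-cancer subtype from ER/PR/HER2 receptor status
#'
#' Classifies patients into the clinical surrogate subtypes defined by the
#' estrogen (ER), progesterone (PR) and HER2 receptor statuses:
#'
#' | ER | PR | HER2 | Subtype |
#' |----|----|------|---------|
#' | + | + | - | LuminalA |
#' | + | + | + | LuminalB_like_PRpos |
#' | + | - | + | LuminalB_like_PRneg |
#' | + | - | - | LuminalB |
#' | - | - | + | HER2_enriched |
#' | - | - | - | TripleNegative |
#'
#' The two remaining combinations (ER-negative, PR-positive) map to
#' `Unclassified`. The four luminal subtypes are the clinically less
#' aggressive group; HER2-enriched and triple negative the more aggressive
#' one.
#'
#' @param status A data frame with columns `er`, `pr`, `her2` (case
#'   insensitive), each `"positive"`/`"negative"` (`"+"`/`"-"` and
#'   `"pos"`/`"neg"` also accepted). Any other token is an error.
#' @return `status` as a tibble with added columns `subtype` and
#'   `aggressiveness` (`"less"`, `"more"`, or `NA` for `Unclassified`).
#' @examples
#' classify_breast_subtype(data.frame(er = "+", pr = "+", her2 = "-"))
#' @export
classify_breast_subtype <- function(status) {
  stopifnot(is.data.frame(status))
  names(status) <- tolower(names(status))
  need <- c("er", "pr", "her2")
  if (!all(need %in% names(status))) {
    abort("`status` must have columns er, pr, her2")
  }
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    out <- dplyr::case_when(
      x %in% c("positive", "pos", "+") ~ "+",
      x %in% c("negative", "neg", "-") ~ "-",
      TRUE ~ NA_character_
    )
    if (anyNA(out)) {
      abort(paste0("unknown receptor status token: ",
                   paste(unique(x[is.na(out)]), collapse = ", ")))
    }
    out
  }
  key <- paste0(norm(status$er), norm(status$pr), norm(status$her2))
  map <- c(
    "++-" = "LuminalA",
    "+++" = "LuminalB_like_PRpos",
    "+-+" = "LuminalB_like_PRneg",
    "+--" = "LuminalB",
    "--+" = "HER2_enriched",
    "---" = "TripleNegative"
  )
  subtype <- unname(map[key])
  subtype[is.na(subtype)] <- "Unclassified"
  aggressiveness <- dplyr::case_when(
    subtype %in% c("LuminalA", "LuminalB_like_PRpos",
                   "LuminalB_like_PRneg", "LuminalB") ~ "less",
    subtype %in% c("HER2_enriched", "TripleNegative") ~ "more",
    TRUE ~ NA_character_
  )
  dplyr::mutate(as_tibble(status), subtype = subtype,
                aggressiveness = aggressiveness)
}

# round half away from zero, as clinical percentages are usually reported
round_half_up_ <- function(x) {
  floor(x + 0.5)
}

#' Summarize subtype counts into aggressiveness percentages
#'
#' Computes the percentage of classified patients falling in the less
#' aggressive (luminal) versus more aggressive (HER2-enriched, triple
#' negative) groups, rounded half-up to integer percent.
#'
#' @param counts Subtype counts: a named numeric vector, or a data frame with
#'   columns `subtype` and `n`. `Unclassified` entries are excluded from the
#'   denominator.
#' @return A one-row tibble: `n_classified`, `n_less_aggressive`,
#'   `n_more_aggressive`, `percent_less_aggressive`,
#'   `percent_more_aggressive` (both `NA` when nothing is classified).
#' @examples
#' summarize_subtypes(c(LuminalA = 38, LuminalB_like_PRpos = 15,
#'                      LuminalB_like_PRneg = 2, LuminalB = 7,
#'                      HER2_enriched = 4, TripleNegative = 11))
#' @export
summarize_subtypes <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(as.numeric(counts$n), as.character(counts$subtype))
  }
  if (any(counts < 0)) abort("subtype counts must be non-negative")
  less <- c("LuminalA", "LuminalB_like_PRpos", "LuminalB_like_PRneg", "LuminalB")
  more <- c("HER2_enriched", "TripleNegative")
  unknown <- setdiff(names(counts), c(less, more, "Unclassified"))
  if (length(unknown) > 0L) {
    abort(paste0("unknown subtype name(s): ", paste(unknown, collapse = ", ")))
  }
  n_less <- sum(counts[intersect(names(counts), less)])
  n_more <- sum(counts[intersect(names(counts), more)])
  n <- n_less + n_more
  tibble(
    n_classified = n,
    n_less_aggressive = n_less,
    n_more_aggressive = n_more,
    percent_less_aggressive = if (n > 0) round_half_up_(100 * n_less / n) else NA_real_,
    percent_more_aggressive = if (n > 0) round_half_up_(100 * n_more / n) else NA_real_
  )
}
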