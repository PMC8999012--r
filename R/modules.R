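#' Map a gene set onto an interactome as a module
#'
#' A gene module is a named set of genes (a drug's targets or a disease's
#' associated genes) split into the genes found in the interactome (`mapped`)
#' and those absent from it (`dropped`). All proximity computations operate on
#' the mapped part only.
#'
#' @param genes Character vector of gene identifiers.
#' @param g An `interactome`.
#' @param name Module name (e.g. the drug or disease identifier).
#' @return A `gene_module` object: list with `name`, `genes`, `mapped`,
#'   `dropped`.
#' @export
gene_module <- function(genes, g, name = "module") {
  genes <- unique(as.character(genes))
  nodes <- igraph::V(g)$name
  mapped <- intersect(genes, nodes)
  structure(
    list(
      name = name,
      genes = genes,
      mapped = mapped,
      dropped = setdiff(genes, mapped)
    ),
    class = "gene_module"
  )
}

#' @export
print.gene_module <- function(x, ...) {
  cat("<gene_module> ", x$name, ": ", length(x$genes), " gene(s), ",
      length(x$mapped), " mapped, ", length(x$dropped), " dropped\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_module <- function(x, ...) {
  tibble(
    module = x$name,
    gene = x$genes,
    mapped = x$genes %in% x$mapped
  )
}

# normalize a drug/disease input (character vector or gene_module) to a module
as_gene_module_ <- function(x, g, name) {
  if (inherits(x, "gene_module")) return(x)
  gene_module(x, g, name = name)
}

#' Read gene sets from a two-column TSV or a GMT file
#'
#' Two formats are supported: a delimited file with columns `set_name gene`
#' (one gene per row, `#` comments ignored), or GMT (one set per line:
#' name, description, then the member genes). The format is chosen by file
#' extension (`.gmt`) unless `format` is given.
#'
#' @param path Input file path.
#' @param format `"auto"`, `"tsv"` or `"gmt"`.
#' @param delimiter Field separator for the tabular format.
#' @return A tibble with columns `set` and `gene`.
#' @export
read_gene_sets <- function(path, format = c("auto", "tsv", "gmt"),
                           delimiter = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("gene-set file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty gene-set file: ", path))
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad) > 0L) {
      abort(paste0("GMT line ", bad[1L], " has fewer than 3 fields"))
    }
    dplyr::bind_rows(lapply(fields, function(f) {
      tibble(set = f[[1L]], gene = f[-(1:2)])
    }))
  } else {
    fields <- strsplit(lines, delimiter, fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad) > 0L) {
      abort(paste0("gene-set row with fewer than 2 fields at line ", bad[1L]))
    }
    tibble(
      set = trimws(vapply(fields, `[[`, "", 1L)),
      gene = trimws(vapply(fields, `[[`, "", 2L))
    )
  }
}

# split a (set, gene) tibble into a named list of gene vectors
gene_sets_to_list_ <- function(sets) {
  if (is.list(sets) && !is.data.frame(sets)) return(sets)
  stopifnot(is.data.frame(sets), ncol(sets) >= 2L)
  split(as.character(sets[[2L]]), as.character(sets[[1L]]))
}
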