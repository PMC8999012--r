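#' Read a protein-protein interaction edge list
#'
#' Parses a delimited two-column edge list (one interaction per line) into a
#' tibble of edges. Lines starting with `#` are ignored. A header line is
#' auto-detected: the first row is treated as data only if both of its fields
#' occur again somewhere in the file as node names; pass `header = TRUE` or
#' `FALSE` to override the heuristic.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator (default tab).
#' @param header `NULL` (auto-detect), `TRUE` (first non-comment row is a
#'   header and is skipped) or `FALSE` (first row is data).
#' @return A tibble with character columns `from` and `to`, one row per line
#'   read (duplicates and self-loops are *not* removed here; see
#'   [as_interactome()]).
#' @seealso [as_interactome()], [write_edge_list()]
#' @export
read_edge_list <- function(path, delimiter = "\t", header = NULL) {
  if (!file.exists(path)) abort(paste0("edge-list file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) abort(paste0("empty edge-list file: ", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short) > 0L) {
    abort(paste0("edge-list row with fewer than 2 fields at line ",
                 line_no[short[1L]], " of ", path))
  }
  from <- trimws(vapply(fields, `[[`, "", 1L))
  to <- trimws(vapply(fields, `[[`, "", 2L))
  drop_first <- if (is.null(header)) {
    # header heuristic: a data row's fields re-occur as node names
    length(from) > 1L &&
      !(from[1L] %in% c(from[-1L], to[-1L]) && to[1L] %in% c(from[-1L], to[-1L]))
  } else {
    isTRUE(header)
  }
  if (drop_first) {
    from <- from[-1L]
    to <- to[-1L]
    if (length(from) == 0L) abort(paste0("edge-list file has a header but no data rows: ", path))
  }
  tibble(from = from, to = to)
}

#' Build an interactome graph from an edge table
#'
#' Constructs an undirected simple graph over gene identifiers from a
#' two-column data frame of edges. Self-loops and duplicate edges (in either
#' orientation) are dropped and counted in a load report; isolated nodes cannot
#' arise because nodes exist only through edges. Node order is canonicalized
#' lexicographically so downstream results are reproducible.
#'
#' @param edges Data frame whose first two columns are the interacting gene
#'   identifiers (coerced to character).
#' @return An `interactome` object (an undirected simple [igraph][igraph::graph]
#'   graph) with a `load_report` attribute, a named list with elements
#'   `n_input`, `duplicates` and `self_loops`.
#' @examples
#' g <- as_interactome(data.frame(a = c("a", "b", "b"), b = c("b", "c", "c")))
#' load_report(g)
#' @export
as_interactome <- function(edges) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    abort("`edges` must be a data frame with at least two columns")
  }
  if (nrow(edges) == 0L) abort("`edges` contains no rows")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (anyNA(from) || anyNA(to)) abort("`edges` contains missing node identifiers")
  n_input <- length(from)
  loops <- from == to
  from <- from[!loops]
  to <- to[!loops]
  # canonical unordered pair for duplicate detection
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]
  b <- b[!dup]
  if (length(a) == 0L) abort("no edges remain after removing self-loops")
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE,
                                     vertices = nodes)
  g <- canonicalize_(g)
  igraph::graph_attr(g, "load_report") <- list(
    n_input = n_input,
    duplicates = sum(dup),
    self_loops = sum(loops)
  )
  class(g) <- c("interactome", class(g))
  g
}

# reorder vertices lexicographically (stable canonical form)
canonicalize_ <- function(g) {
  ord <- order(igraph::V(g)$name)
  igraph::permute(g, order(ord))
}

#' @rdname as_interactome
#' @param path,delimiter,header Passed to [read_edge_list()].
#' @export
load_edge_list <- function(path, delimiter = "\t", header = NULL) {
  as_interactome(read_edge_list(path, delimiter = delimiter, header = header))
}

#' @export
print.interactome <- function(x, ...) {
  rep <- load_report(x)
  cat("<interactome> ", igraph::vcount(x), " nodes, ", igraph::ecount(x),
      " edges\n", sep = "")
  if (!is.null(rep)) {
    cat("  load report: ", rep$duplicates, " duplicate edge(s), ",
        rep$self_loops, " self-loop(s) dropped\n", sep = "")
  }
  invisible(x)
}

#' @rdname as_interactome
#' @param g An `interactome`.
#' @export
load_report <- function(g) {
  igraph::graph_attr(g, "load_report")
}

#' Write an interactome back to a delimited edge list
#'
#' Writes one `from<delimiter>to` line per edge with endpoints of each edge in
#' lexicographic order and edges sorted, so that
#' `load_edge_list(write_edge_list(g, f))` reproduces `g` exactly.
#'
#' @param g An `interactome`.
#' @param path Output file path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, delimiter = "\t") {
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  writeLines(paste(a[ord], b[ord], sep = delimiter), path)
  invisible(path)
}

#' Largest connected component of an interactome
#'
#' Returns the induced subgraph on the largest connected component. Size ties
#' are broken in favour of the component containing the lexicographically
#' smallest node name.
#'
#' @param g An `interactome`.
#' @return An `interactome` restricted to the largest component.
#' @export
largest_component <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # among tied components, pick the one holding the smallest node name
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, "")
    best <- best[order(firsts)[1L]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  sub <- canonicalize_(sub)
  class(sub) <- unique(c("interactome", class(sub)))
  sub
}

#' Shortest-path distances from one node to a set of targets
#'
#' Unweighted (breadth-first) shortest-path lengths from `source` to each
#' member of `targets`. Unreachable targets get `Inf`.
#'
#' @param g An `interactome`.
#' @param source A single node identifier present in `g`.
#' @param targets Character vector of node identifiers present in `g`.
#' @return A tibble with columns `target` and `distance` (`Inf` when no path
#'   exists; `0` for `target == source`).
#' @export
distances_from <- function(g, source, targets) {
  nodes <- igraph::V(g)$name
  if (length(source) != 1L || !source %in% nodes) {
    abort(paste0("source node not in graph: ", source[1L]))
  }
  missing <- setdiff(targets, nodes)
  if (length(missing) > 0L) {
    abort(paste0("target node(s) not in graph: ", paste(missing, collapse = ", ")))
  }
  d <- igraph::distances(g, v = source, to = targets, algorithm = "unweighted")
  tibble(target = targets, distance = as.numeric(d[1L, ]))
}

#' Degree bins for degree-preserving random sampling
#'
#' Groups nodes by exact degree (ascending) and merges adjacent degree groups
#' until every bin holds at least `min_bin_size` nodes; a short final bin is
#' merged leftward into its predecessor. Random node sets drawn bin-wise from
#' this structure match the degree distribution of a reference set, which is
#' the basis of the randomization null model.
#'
#' @param g An `interactome`.
#' @param min_bin_size Minimum number of nodes per bin (default 100).
#' @return A `degree_bins` object: list with `bins` (list of character vectors
#'   of member nodes), `ranges` (tibble of `degree_min`, `degree_max`,
#'   `n_nodes`) and `lookup` (named integer vector node -> bin index).
#' @export
build_degree_bins <- function(g, min_bin_size = 100) {
  stopifnot(min_bin_size >= 1)
  deg <- igraph::degree(g)
  if (min_bin_size > length(deg)) {
    abort(paste0("min_bin_size (", min_bin_size, ") exceeds number of nodes (",
                 length(deg), ")"))
  }
  by_degree <- split(names(deg), deg)  # names are degrees, sorted ascending
  degrees <- as.integer(names(by_degree))
  ord <- order(degrees)
  by_degree <- by_degree[ord]
  degrees <- degrees[ord]

  bins <- list()
  lo <- integer()
  hi <- integer()
  cur <- character()
  cur_lo <- NA_integer_
  for (i in seq_along(by_degree)) {
    if (length(cur) == 0L) cur_lo <- degrees[i]
    cur <- c(cur, by_degree[[i]])
    if (length(cur) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- cur
      lo <- c(lo, cur_lo)
      hi <- c(hi, degrees[i])
      cur <- character()
    }
  }
  if (length(cur) > 0L) {
    if (length(bins) == 0L) {
      bins[[1L]] <- cur
      lo <- cur_lo
      hi <- degrees[length(degrees)]
    } else {
      # merge the short tail leftward into the last closed bin
      bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
      hi[length(hi)] <- degrees[length(degrees)]
    }
  }
  lookup <- integer()
  for (i in seq_along(bins)) {
    lookup[bins[[i]]] <- i
  }
  structure(
    list(
      bins = bins,
      ranges = tibble(degree_min = lo, degree_max = hi,
                      n_nodes = vapply(bins, length, 1L)),
      lookup = lookup,
      min_bin_size = min_bin_size
    ),
    class = "degree_bins"
  )
}

#' @export
print.degree_bins <- function(x, ...) {
  cat("<degree_bins> ", length(x$bins), " bin(s) over ", length(x$lookup),
      " nodes (min_bin_size = ", x$min_bin_size, ")\n", sep = "")
  print(x$ranges)
  invisible(x)
}

#' Draw a degree-matched random node set
#'
#' Samples one node per reference node from that node's degree bin, without
#' replacement within the sample, producing a random set of the same size and
#' (binned) degree distribution as `reference`. Uses the current RNG stream;
#' seed it with [set.seed()] for reproducibility.
#'
#' @param bins A `degree_bins` object from [build_degree_bins()].
#' @param reference Character vector of node identifiers (all must be binned).
#' @return Character vector of `length(reference)` distinct sampled nodes.
#' @export
sample_degree_matched <- function(bins, reference) {
  idx <- bins$lookup[reference]
  if (anyNA(idx)) {
    abort(paste0("reference node(s) not in degree bins: ",
                 paste(reference[is.na(idx)], collapse = ", ")))
  }
  need <- table(idx)
  out <- character(0)
  for (b in names(need)) {
    members <- bins$bins[[as.integer(b)]]
    k <- as.integer(need[[b]])
    if (k > length(members)) {
      abort(paste0("degree bin ", b, " exhausted (", k, " draws requested, ",
                   length(members), " members); increase min_bin_size"))
    }
    out <- c(out, sample(members, k, replace = FALSE))
  }
  out
}

#' @export
tidy.interactome <- function(x, ...) {
  el <- igraph::as_edgelist(x)
  tibble(from = el[, 1L], to = el[, 2L])
}

#' @export
glance.interactome <- function(x, ...) {
  comp <- igraph::components(x)
  tibble(
    n_nodes = igraph::vcount(x),
    n_edges = igraph::ecount(x),
    n_components = comp$no,
    max_degree = max(igraph::degree(x)),
    median_degree = stats::median(igraph::degree(x))
  )
}
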