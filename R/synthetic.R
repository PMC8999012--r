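#' Generate a synthetic scale-free interactome
#'
#' Grows a connected preferential-attachment graph: starting from a seed pair
#' of nodes, each new node attaches `m` edges (fewer while fewer nodes exist)
#' to distinct existing nodes chosen with probability proportional to their
#' current degree (uniformly while all degrees are zero). The resulting degree
#' distribution is heavy-tailed, which stresses the degree-binned null model
#' the way a real interactome does. With `m = 2` the graph has exactly
#' `2 * (n_nodes - 2)` edges.
#'
#' @param n_nodes Number of nodes (>= 10).
#' @param m Edges attached by each incoming node (default 2).
#' @param seed Integer seed; the generator is a pure function of
#'   `(n_nodes, m, seed)`.
#' @return A connected `interactome` with zero-padded node names
#'   (`g0001`, ...), lexicographic order matching generation order.
#' @export
generate_interactome <- function(n_nodes, m = 2, seed = 1) {
  if (n_nodes < 10) abort("n_nodes must be at least 10")
  if (m < 1) abort("m must be at least 1")
  width <- nchar(as.character(n_nodes))
  node <- function(i) sprintf("g%0*d", width, i)
  with_seed_(seed, {
    deg <- numeric(n_nodes)
    from <- integer(0)
    to <- integer(0)
    for (k in 3:n_nodes) {
      existing <- seq_len(k - 1L)
      n_new <- min(m, k - 1L)
      w <- deg[existing]
      if (sum(w) == 0) w <- rep(1, length(existing))
      picked <- sample(existing, n_new, replace = FALSE, prob = w)
      from <- c(from, rep(k, n_new))
      to <- c(to, picked)
      deg[k] <- deg[k] + n_new
      deg[picked] <- deg[picked] + 1
    }
    as_interactome(data.frame(from = node(from), to = node(to)))
  })
}

#' Plant a disease module and a drug module with known proximity class
#'
#' Builds ground truth for testing the proximity screen. The disease module S
#' is a breadth-first ball around a random seed node, truncated to
#' `disease_size` (so it is connected and localized, as disease modules are
#' assumed to be). The drug module T is either
#' \describe{
#'   \item{proximal}{drawn from the 1-hop neighborhood of S (excluding S
#'     itself unless `overlap = "full"`, which samples T inside S), so every
#'     target sits at distance <= 1 from the disease module;}
#'   \item{random}{a degree-matched random set: a proximal-style reference is
#'     drawn first and then replaced bin-wise through
#'     [sample_degree_matched()], giving the same size and degree profile but
#'     arbitrary placement.}
#' }
#'
#' @param g An `interactome`.
#' @param disease_size,drug_size Module sizes (each <= n_nodes / 4).
#' @param proximity_class `"proximal"` or `"random"`.
#' @param seed Integer seed.
#' @param overlap `"none"` (default) or `"full"` (T drawn inside S).
#' @param min_bin_size Degree-bin size for the random class (default 25).
#' @return A list with `disease` and `drug` [gene_module()]s and
#'   `proximity_class`.
#' @export
plant_modules <- function(g, disease_size, drug_size,
                          proximity_class = c("proximal", "random"),
                          seed = 1, overlap = c("none", "full"),
                          min_bin_size = 25) {
  proximity_class <- match.arg(proximity_class)
  overlap <- match.arg(overlap)
  n <- igraph::vcount(g)
  if (disease_size > n / 4 || drug_size > n / 4) {
    abort("module sizes must not exceed a quarter of the node count")
  }
  with_seed_(seed, {
    nodes <- igraph::V(g)$name
    root <- sample(nodes, 1L)
    bfs_order <- igraph::bfs(g, root = root, order = TRUE)$order
    s_nodes <- igraph::V(g)$name[bfs_order[seq_len(disease_size)]]

    draw_proximal <- function() {
      nbrs <- setdiff(
        igraph::V(g)$name[unlist(igraph::adjacent_vertices(g, s_nodes))],
        s_nodes)
      if (length(nbrs) < drug_size) {
        abort("1-hop neighborhood of the disease module is too small for drug_size")
      }
      sample(nbrs, drug_size)
    }
    t_nodes <- if (overlap == "full") {
      sample(s_nodes, min(drug_size, disease_size))
    } else if (proximity_class == "proximal") {
      draw_proximal()
    } else {
      bins <- build_degree_bins(g, min_bin_size = min(min_bin_size, n))
      sample_degree_matched(bins, draw_proximal())
    }
    list(
      disease = gene_module(s_nodes, g, name = "planted_disease"),
      drug = gene_module(t_nodes, g, name = paste0("planted_", proximity_class)),
      proximity_class = proximity_class
    )
  })
}

#' Generate paired tumor/normal expression with planted differential genes
#'
#' Emulates a paired tumor/normal RNA-seq design on the normalized-abundance
#' scale. Per gene, a log2 baseline is drawn (normal ~ N(7, 1.5)) with
#' per-gene biological spread, normal samples scatter around it, and tumor
#' samples equal their matched normal plus per-pair noise; the `n_de` planted
#' differential genes additionally get a shift of `effect * noise_sd` log2
#' units with random sign. Values are returned as `2^x` so they are
#' non-negative abundances ready for the log2(+1) pipeline.
#'
#' @param n_genes Total genes (default 1000).
#' @param n_pairs Tumor/normal pairs (default 20).
#' @param n_de Number of differentially expressed genes (default 50).
#' @param effect Shift of the planted genes in units of `noise_sd`
#'   (default 2).
#' @param noise_sd Standard deviation of the per-pair tumor-normal noise on
#'   the log2 scale (default 0.5).
#' @param seed Integer seed.
#' @return A list: `expression` (a [paired_expression()]), `de_genes`
#'   (character truth set) and `direction` (named +1/-1 vector of planted
#'   signs).
#' @export
generate_paired_expression <- function(n_genes = 1000, n_pairs = 20,
                                       n_de = 50, effect = 2, noise_sd = 0.5,
                                       seed = 1) {
  if (n_de > n_genes) abort("n_de must not exceed n_genes")
  if (n_pairs < 2) abort("need at least 2 sample pairs")
  with_seed_(seed, {
    gw <- nchar(as.character(n_genes))
    genes <- sprintf("e%0*d", gw, seq_len(n_genes))
    baseline <- rnorm(n_genes, mean = 7, sd = 1.5)
    spread <- runif(n_genes, 0.3, 1.0)  # per-gene biological sd (log2)
    normal <- baseline + matrix(rnorm(n_genes * n_pairs), n_genes) * spread
    noise <- matrix(rnorm(n_genes * n_pairs, sd = noise_sd), n_genes)
    de_idx <- sample.int(n_genes, n_de)
    sign_de <- sample(c(-1, 1), n_de, replace = TRUE)
    shift <- numeric(n_genes)
    shift[de_idx] <- sign_de * effect * noise_sd
    tumor <- normal + noise + shift
    tumor_ids <- sprintf("tumor_%02d", seq_len(n_pairs))
    normal_ids <- sprintf("normal_%02d", seq_len(n_pairs))
    values <- cbind(2^tumor, 2^normal)
    rownames(values) <- genes
    colnames(values) <- c(tumor_ids, normal_ids)
    list(
      expression = paired_expression(values,
                                     data.frame(tumor = tumor_ids,
                                                normal = normal_ids)),
      de_genes = genes[de_idx],
      direction = setNames(sign_de, genes[de_idx])
    )
  })
}

#' Generate drug ranked lists with planted antidotes
#'
#' Emulates drug transcriptional signatures over the gene universe of a
#' disease signature. An *antidote* drug ranks the disease's down-regulated
#' genes at the top of its list and the up-regulated genes at the bottom
#' (a perfectly complementary profile), optionally perturbed by swapping a
#' fraction `noise` of random position pairs; the remaining drugs are uniform
#' random permutations of the universe.
#'
#' @param disease A `disease_signature` (or list with `up`, `down`, and
#'   either `stats$gene` or a `universe` element).
#' @param n_drugs Total number of drugs (default 20).
#' @param n_antidotes How many of them are antidotes (default half).
#' @param noise Fraction of positions pair-swapped in antidote lists
#'   (default 0).
#' @param seed Integer seed.
#' @return A list: `rankings` (named list of ordered gene vectors) and
#'   `truth` (tibble `drug`, `is_antidote`).
#' @export
generate_drug_rankings <- function(disease, n_drugs = 20,
                                   n_antidotes = n_drugs %/% 2, noise = 0,
                                   seed = 1) {
  if (n_antidotes > n_drugs) abort("n_antidotes must not exceed n_drugs")
  universe <- if (!is.null(disease$stats)) disease$stats$gene else disease$universe
  if (is.null(universe)) abort("disease signature carries no gene universe")
  up <- disease$up
  down <- disease$down
  rest <- setdiff(universe, c(up, down))
  dw <- nchar(as.character(max(n_drugs, 1L)))
  with_seed_(seed, {
    rankings <- list()
    for (i in seq_len(n_drugs)) {
      name <- sprintf("drug_%0*d", dw, i)
      if (i <= n_antidotes) {
        # complementary profile: disease-down on top, disease-up at the bottom
        lst <- c(rev(down), sample(rest), rev(up))
        if (noise > 0) {
          n_swaps <- ceiling(noise * length(lst) / 2)
          for (s in seq_len(n_swaps)) {
            ij <- sample.int(length(lst), 2L)
            lst[ij] <- lst[rev(ij)]
          }
        }
      } else {
        lst <- sample(universe)
      }
      rankings[[name]] <- lst
    }
    list(
      rankings = rankings,
      truth = tibble(drug = names(rankings),
                     is_antidote = seq_len(n_drugs) <= n_antidotes)
    )
  })
}

#' Write a full synthetic scenario to disk
#'
#' Generates an interactome, planted proximal and random drug modules, a
#' paired expression matrix, and drug ranked lists, and writes them in the
#' plain-text formats every loader of this package reads back:
#' `edges.tsv`, `modules.tsv`, `expression.tsv`, `pairs.tsv`, `rankings.tsv`
#' and `truth.json`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_nodes,m Interactome size and attachment parameter.
#' @param disease_size,drug_size Planted module sizes.
#' @param n_genes,n_pairs,n_de,effect,noise_sd Expression generator
#'   parameters (see [generate_paired_expression()]).
#' @param n_drugs,n_antidotes Ranking generator parameters.
#' @param seed Integer master seed.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_scenario <- function(out_dir, n_nodes = 500, m = 2, disease_size = 25,
                           drug_size = 5, n_genes = 1000, n_pairs = 20,
                           n_de = 50, effect = 2, noise_sd = 0.5,
                           n_drugs = 20, n_antidotes = n_drugs %/% 2, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_interactome(n_nodes, m = m, seed = seed)
  prox <- plant_modules(g, disease_size, drug_size, "proximal", seed = seed + 1)
  rand <- plant_modules(g, disease_size, drug_size, "random", seed = seed + 1)
  expr <- generate_paired_expression(n_genes, n_pairs, n_de, effect, noise_sd,
                                     seed = seed + 2)
  sig <- suppressWarnings(build_disease_signature(expr$expression))
  rk <- generate_drug_rankings(sig, n_drugs, n_antidotes, seed = seed + 3)

  paths <- list(
    edges = file.path(out_dir, "edges.tsv"),
    modules = file.path(out_dir, "modules.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"),
    rankings = file.path(out_dir, "rankings.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_edge_list(g, paths$edges)
  mods <- dplyr::bind_rows(
    tibble(set = "disease", gene = prox$disease$genes),
    tibble(set = "drug_proximal", gene = prox$drug$genes),
    tibble(set = "drug_random", gene = rand$drug$genes)
  )
  readr::write_tsv(mods, paths$modules, col_names = FALSE)
  pe <- expr$expression
  expr_tab <- as_tibble(cbind(
    tibble(gene = pe$genes),
    as.data.frame(pe$tumor), as.data.frame(pe$normal)))
  readr::write_tsv(expr_tab, paths$expression)
  readr::write_tsv(pe$pairs, paths$pairs, col_names = FALSE)
  rank_tab <- dplyr::bind_rows(purrr::imap(rk$rankings, function(genes, d) {
    tibble(drug = d, gene = genes, rank = seq_along(genes))
  }))
  readr::write_tsv(rank_tab, paths$rankings)
  jsonlite::write_json(
    list(de_genes = expr$de_genes,
         de_direction = as.list(expr$direction),
         antidotes = rk$truth$drug[rk$truth$is_antidote],
         disease_module = prox$disease$genes,
         drug_proximal = prox$drug$genes,
         drug_random = rand$drug$genes,
         seed = seed),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
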