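test_that("edge loading dedups, drops self-loops and reports counts", {
  g <- as_interactome(data.frame(a = c("a", "b", "b", "c"),
                                 b = c("b", "c", "c", "c")))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  rep <- load_report(g)
  expect_equal(rep$duplicates, 1)
  expect_equal(rep$self_loops, 1)

  g1 <- as_interactome(data.frame(from = "a", to = "b"))
  expect_equal(igraph::vcount(g1), 2)
  expect_equal(unname(igraph::degree(g1)), c(1, 1))
})

test_that("reversed duplicate edges collapse to one undirected edge", {
  g <- as_interactome(data.frame(from = c("x", "y"), to = c("y", "x")))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(load_report(g)$duplicates, 1)
})

test_that("edge-list file round-trips and matches an independent line count", {
  set.seed(11)
  n <- 10
  nodes <- sprintf("v%02d", 1:n)
  from <- sample(nodes, 25, replace = TRUE)
  to <- sample(nodes, 25, replace = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line", paste(from, to, sep = "\t")), path)
  g <- load_edge_list(path)

  # independent parse: count unique unordered non-loop pairs by hand
  seen <- character()
  for (i in seq_along(from)) {
    if (from[i] == to[i]) next
    key <- paste(sort(c(from[i], to[i])), collapse = "|")
    if (!key %in% seen) seen <- c(seen, key)
  }
  expect_equal(igraph::ecount(g), length(seen))
  expect_equal(igraph::vcount(g),
               length(unique(unlist(strsplit(seen, "|", fixed = TRUE)))))

  # round trip through the writer is the identity on the canonical graph
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path2)
  g2 <- load_edge_list(path2)
  expect_identical(igraph::V(g2)$name, igraph::V(g)$name)
  canon <- function(gg) {
    el <- igraph::as_edgelist(gg)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(g2), canon(g))
})

test_that("header lines are auto-detected and parse errors name the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "a\tb", "b\tc"), path)
  expect_equal(nrow(read_edge_list(path)), 2)  # header skipped
  writeLines(c("a\tb", "b\ta"), path)
  expect_equal(nrow(read_edge_list(path)), 2)  # data kept: fields re-occur
  writeLines(c("a\tb", "lonely"), path)
  expect_error(read_edge_list(path), "line 2")
  writeLines(character(), path)
  expect_error(read_edge_list(path), "empty")
})

test_that("largest component selection and its tie-break", {
  g <- as_interactome(data.frame(from = c("a", "b", "x"),
                                 to = c("b", "c", "y")))
  lcc <- largest_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c"))

  conn <- as_interactome(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_identical(igraph::V(largest_component(conn))$name,
                   igraph::V(conn)$name)

  tied <- as_interactome(data.frame(from = c("c", "a"), to = c("d", "b")))
  expect_setequal(igraph::V(largest_component(tied))$name, c("a", "b"))
})

test_that("distances_from gives BFS distances, Inf when unreachable", {
  path5 <- as_interactome(data.frame(from = c("a", "b", "c", "d"),
                                     to = c("b", "c", "d", "e")))
  d <- distances_from(path5, "a", c("d", "e"))
  expect_equal(d$distance, c(3, 4))
  expect_equal(distances_from(path5, "d", "d")$distance, 0)

  g <- as_interactome(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(distances_from(g, "a", "c")$distance, Inf)
  expect_error(distances_from(g, "zz", "a"), "zz")
  expect_error(distances_from(g, "a", "zz"), "zz")
})

test_that("BFS distances agree with Floyd-Warshall on random graphs", {
  for (seed in c(1, 2, 3, 4, 5)) {
    g <- random_interactome(sample(10:50, 1), p = 0.12, seed = seed)
    ref <- fw_distances(g)
    nodes <- igraph::V(g)$name
    src <- sample(nodes, 3)
    for (s in src) {
      got <- distances_from(g, s, nodes)
      expect_equal(got$distance, unname(ref[s, nodes]))
    }
  }
})

test_that("triangle inequality holds for finite distances", {
  g <- random_interactome(30, p = 0.15, seed = 9)
  d <- igraph::distances(g)
  nodes <- seq_len(igraph::vcount(g))
  set.seed(1)
  for (i in 1:200) {
    trip <- sample(nodes, 3)
    if (all(is.finite(d[trip, trip]))) {
      expect_lte(d[trip[1], trip[3]], d[trip[1], trip[2]] + d[trip[2], trip[3]])
    }
  }
})

test_that("degree bins merge ascending and respect min_bin_size", {
  g2 <- as_interactome(data.frame(
    from = c("a", "b", "c", "d", "d", "e", "e", "e"),
    to   = c("e", "e", "e", "e1", "e2", "e1", "e2", "e3")))
  deg <- igraph::degree(g2)
  bins <- build_degree_bins(g2, min_bin_size = 3)
  # every node in exactly one bin
  expect_setequal(unlist(bins$bins), igraph::V(g2)$name)
  expect_equal(sum(lengths(bins$bins)), igraph::vcount(g2))
  # bins are ascending, contiguous in degree
  expect_true(all(diff(bins$ranges$degree_min) > 0))
  for (i in seq_along(bins$bins)) {
    expect_true(all(deg[bins$bins[[i]]] >= bins$ranges$degree_min[i] &
                    deg[bins$bins[[i]]] <= bins$ranges$degree_max[i]))
  }
  # all but the last bin hold >= min_bin_size
  sizes <- lengths(bins$bins)
  if (length(sizes) > 1) expect_true(all(sizes[-length(sizes)] >= 3))

  # min_bin_size 1: one bin per distinct degree
  b1 <- build_degree_bins(g2, 1)
  expect_equal(length(b1$bins), length(unique(deg)))
  # all same degree: a single bin
  cyc <- as_interactome(data.frame(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")))
  expect_equal(length(build_degree_bins(cyc, 2)$bins), 1)
  expect_error(build_degree_bins(cyc, 10), "exceeds")
})

test_that("degree-bin merging trace matches the ascending-merge rule", {
  # star: a,b,c have degree 1, d degree 2, e degree 5
  # with min_bin_size 3 the trace gives bins [{a,b,c}, {d,e}]
  g <- as_interactome(data.frame(
    from = c("a", "b", "c", "d", "d", "e", "e", "e"),
    to   = c("e", "e", "e", "x", "y", "x", "y", "z")))
  deg <- igraph::degree(g)
  d1 <- names(deg)[deg == 1]   # a, b, c, z
  bins <- build_degree_bins(g, min_bin_size = 3)
  expect_setequal(bins$bins[[1]], d1)
  expect_setequal(bins$bins[[length(bins$bins)]],
                  setdiff(names(deg), d1))
})

test_that("degree-matched samples preserve bin membership per draw", {
  g <- generate_interactome(200, 2, seed = 4)
  bins <- build_degree_bins(g, 20)
  set.seed(7)
  ref <- sample(igraph::V(g)$name, 12)
  for (i in 1:20) {
    s <- sample_degree_matched(bins, ref)
    expect_equal(length(s), length(ref))
    expect_false(anyDuplicated(s) > 0)
    expect_equal(sort(unname(bins$lookup[s])), sort(unname(bins$lookup[ref])))
  }
})

test_that("singleton bins force the sample to equal the reference", {
  # path graph: degrees 1,2,2,1 -> with min_bin_size 1 bins {deg1}, {deg2}
  g <- as_interactome(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
  bins <- build_degree_bins(g, 1)
  # a reference exhausting each bin is reproduced as a set
  set.seed(1)
  s <- sample_degree_matched(bins, c("a", "d", "b", "c"))
  expect_setequal(s, c("a", "b", "c", "d"))
  expect_error(sample_degree_matched(bins, c("a", "a", "d", "d")),
               "exhausted")
})

test_that("bin members are drawn uniformly (Monte-Carlo frequency check)", {
  g <- generate_interactome(200, 2, seed = 10)
  bins <- build_degree_bins(g, 50)
  set.seed(3)
  ref <- sample(igraph::V(g)$name, 5)
  n_draws <- 2000
  draws <- replicate(n_draws, sample_degree_matched(bins, ref))
  counts <- table(factor(draws, levels = igraph::V(g)$name))
  # each member of the bin holding k reference nodes is drawn with
  # probability k/bin_size per sample; check 99% binomial bounds
  ref_bins <- table(bins$lookup[ref])
  for (b in names(ref_bins)) {
    members <- bins$bins[[as.integer(b)]]
    p <- as.integer(ref_bins[[b]]) / length(members)
    obs <- as.integer(counts[members])
    lo <- qbinom(0.005, n_draws, p)
    hi <- qbinom(0.995, n_draws, p)
    frac_in <- mean(obs >= lo & obs <= hi)
    expect_gte(frac_in, 0.95)  # allow a few boundary misses across members
  }
})
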