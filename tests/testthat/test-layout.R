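test_that("break_cycles leaves DAGs untouched and deletes lightest cycle edges", {
  g <- graph_obj(c("a", "b", "c"),
                 edges_df(c("a", "b"), c("b", "c"), c(10L, 20L)))
  out <- break_cycles(g)
  expect_equal(out$edges, g$edges)
  expect_equal(nrow(attr(out, "removed_edges")), 0)

  cyc <- graph_obj(c("a", "b", "c"),
                   edges_df(c("a", "b", "c"), c("b", "c", "a"), c(5L, 7L, 9L)))
  out <- break_cycles(cyc)
  removed <- attr(out, "removed_edges")
  expect_equal(nrow(removed), 1)
  expect_equal(removed$weight, 5L)
  expect_true(is_dag_oracle(out))

  two <- graph_obj(
    c("a", "b", "c", "x", "y", "z"),
    edges_df(c("a", "b", "c", "x", "y", "z"),
             c("b", "c", "a", "y", "z", "x"),
             c(5L, 7L, 9L, 3L, 8L, 2L))
  )
  out <- break_cycles(two)
  expect_equal(nrow(attr(out, "removed_edges")), 2)
  expect_true(is_dag_oracle(out))
})

test_that("break_cycles removes exactly the logged edges on planted cycles", {
  set.seed(205)
  for (rep in 1:100) {
    g <- plant_cycles(random_dag(sample(4:10, 1)), n_back = sample(1:3, 1))
    out <- break_cycles(g)
    removed <- attr(out, "removed_edges")
    expect_true(is_dag_oracle(out))
    key <- function(e) paste(e$from, e$to)
    expect_setequal(key(g$edges), c(key(out$edges), key(removed)))
    expect_no_error(heaviest_path(out))
  }
})

test_that("heaviest_path matches brute-force enumeration", {
  g1 <- graph_obj("solo", edges_df())
  p <- heaviest_path(g1)
  expect_equal(p$nodes, "solo")
  expect_equal(p$weight, 0L)

  g3 <- graph_obj(c("a", "b", "c"),
                  edges_df(c("a", "b", "a"), c("b", "c", "c"),
                           c(10L, 20L, 25L)))
  p <- heaviest_path(g3)
  expect_equal(p$nodes, c("a", "b", "c"))
  expect_equal(p$weight, 30L)
  expect_equal(p$weight, brute_force_max_path_weight(g3))

  expect_error(heaviest_path(graph_obj(character(0), edges_df())), "empty")

  set.seed(77)
  for (rep in 1:60) {
    g <- random_dag(sample(2:12, 1))
    expect_equal(heaviest_path(g)$weight, brute_force_max_path_weight(g))
  }
})

test_that("successive extracted path weights never increase", {
  set.seed(15)
  g <- random_dag(12, edge_prob = 0.4)
  weights <- integer(0)
  while (length(g$nodes)) {
    p <- heaviest_path(g)
    weights <- c(weights, p$weight)
    g$nodes <- g$nodes[setdiff(names(g$nodes), p$nodes)]
    g$edges <- g$edges[!(g$edges$from %in% p$nodes | g$edges$to %in% p$nodes), ]
  }
  expect_true(all(diff(weights) <= 0))
})

test_that("consensus concatenates cores and keeps them as exact substrings", {
  s <- random_cds(33, seed = 8)                  # 99 nt
  a <- make_core("a", substr(s, 1, 60))
  b <- make_core("b", substr(s, 40, 99))         # 60 nt, 21-nt overlap
  cores <- list(a = a, b = b)
  path <- structure(list(
    nodes = c("a", "b"),
    edges = data.frame(from = "a", to = "b", weight = 21L, offset = 39L,
                       stringsAsFactors = FALSE),
    weight = 21L), class = "assembly_path")
  ctg <- path_consensus(path, cores)
  expect_equal(ctg$length, 99L)
  expect_equal(ctg$seq, s)
  expect_equal(ctg$members$start, c(0L, 39L))
  for (k in seq_len(nrow(ctg$members))) {
    m <- ctg$members[k, ]
    expect_equal(substr(ctg$seq, m$start + 1, m$start + m$len),
                 cores[[m$core_id]]$seq)
  }

  solo <- structure(list(nodes = "a", edges = path$edges[0, ], weight = 0L),
                    class = "assembly_path")
  ctg1 <- path_consensus(solo, cores)
  expect_equal(ctg1$seq, a$seq)
  expect_equal(ctg1$avg_coverage, 1)
})

test_that("a tiled 5-core path gives the expected length and coverage", {
  s <- random_cds(60, seed = 9)                  # 180 nt
  ids <- paste0("c", 1:5)
  cores <- stats::setNames(
    lapply(0:4, function(i) make_core(paste0("c", i + 1),
                                      substr(s, 30 * i + 1, 30 * i + 60))),
    ids)
  edges <- data.frame(from = ids[1:4], to = ids[2:5], weight = 30L,
                      offset = 30L, stringsAsFactors = FALSE)
  path <- structure(list(nodes = ids, edges = edges, weight = 120L),
                    class = "assembly_path")
  ctg <- path_consensus(path, cores)
  expect_equal(ctg$length, 180L)
  expect_equal(ctg$seq, s)
  expect_equal(ctg$n_reads, 5L)
  expect_equal(ctg$avg_coverage, 300 / 180)
})

test_that("contig filters are inclusive bounds and singletons are dropped", {
  expect_equal(extract_contigs(graph_obj(character(0), edges_df())), list(),
               ignore_attr = TRUE)

  make_pair_graph <- function(total_len) {
    s <- random_cds(ceiling(total_len / 3) + 10, seed = total_len)
    a <- make_core("a", substr(s, 1, 110))
    b_len <- total_len - 110 + 21
    b <- make_core("b", substr(s, 90, 89 + b_len))
    g <- structure(list(
      nodes = list(a = a, b = b),
      edges = data.frame(from = "a", to = "b", weight = 21L, offset = 89L,
                         ref = "p", stringsAsFactors = FALSE)),
      class = "overlap_graph")
    g
  }
  p199 <- assembly_params(minLength = 200, minReads = 1)
  expect_length(extract_contigs(make_pair_graph(199L), p199), 0)
  expect_length(extract_contigs(make_pair_graph(200L), p199), 1)

  # a single isolated core is a 1-read candidate, discarded at minReads = 2
  iso <- structure(list(nodes = list(a = make_core("a", random_cds(100))),
                        edges = edges_df()), class = "overlap_graph")
  expect_length(extract_contigs(iso, assembly_params(minLength = 1)), 0)
  expect_length(extract_contigs(iso, assembly_params(minLength = 1,
                                                     minReads = 1)), 1)
})

test_that("no core appears in two contigs and filters are monotone", {
  spec <- simulation_spec(seed = 41, strand_flip_prob = 0.5)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec)
  alns <- simulate_alignments(reads, fam$references, spec)
  cores <- compute_cores(reads, alns)
  g <- build_overlap_graph(cores, project_all(cores, alns))
  g <- break_cycles(g)

  contigs <- extract_contigs(g, assembly_params(minLength = 50, minReads = 1))
  ids <- unlist(lapply(contigs, function(x) x$members$core_id))
  expect_equal(anyDuplicated(ids), 0)

  count <- function(...) length(extract_contigs(g, assembly_params(...)))
  base <- count(minLength = 50, minReads = 1)
  expect_lte(count(minLength = 300, minReads = 1), base)
  expect_lte(count(minLength = 50, minReads = 5), base)
  expect_lte(count(minLength = 50, minReads = 1, minAvCoverage = 2), base)
})
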