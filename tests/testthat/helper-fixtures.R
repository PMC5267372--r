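# Shared fixture builders and independent oracles. Everything is generated
# in code; no files ship with the tests.

# byte view of a string, for position-wise comparisons
.as_raw_chars <- function(s) charToRaw(s)

# one alignment row in internal (0-based half-open) coordinates
aln_row <- function(read_id, ref_id, bit_score, frame,
                    read_start, read_end, ref_start, ref_end, q_aln, s_aln) {
  data.frame(read_id = read_id, ref_id = ref_id, bit_score = bit_score,
             frame = as.integer(frame), read_start = as.integer(read_start),
             read_end = as.integer(read_end), ref_start = as.integer(ref_start),
             ref_end = as.integer(ref_end), q_aln = q_aln, s_aln = s_aln,
             stringsAsFactors = FALSE)
}

# a random stop-free coding DNA sequence of n_codons codons
random_cds <- function(n_codons, seed = 1) {
  set.seed(seed)
  b <- c("A", "C", "G", "T")
  codons <- setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
                    c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# Two reads whose protein alignments to one reference share exactly
# `shared_codons` doubly-ungapped positions, with identical DNA in the
# induced region and read b extending past read a. Defaults give the
# 4-codon case whose induced DNA overlap has length 12.
two_read_fixture <- function(shared_codons = 4L, seed = 1,
                             mutate_overlap = FALSE) {
  gene <- random_cds(20L, seed = seed)           # 60 nt, 20 codons
  prot <- translate_dna(gene)
  b_from <- 3L * (12L - shared_codons)           # a covers codons 0..11
  ra <- substr(gene, 1L, 36L)                    # codons 0..11
  rb <- substr(gene, b_from + 1L, 60L)           # codons (12-k)..19
  if (mutate_overlap) {
    # substitute one nucleotide of read b inside the shared region
    pos <- 2L
    old <- substr(rb, pos, pos)
    substr(rb, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  reads <- stats::setNames(c(ra, rb), c("ra", "rb"))
  alns <- rbind(
    aln_row("ra", "p1", 2 * 12, 1L, 0L, 36L, 0L, 12L,
            translate_dna(ra), substr(prot, 1L, 12L)),
    aln_row("rb", "p1", 2 * (20L - (12L - shared_codons)), 1L,
            0L, 60L - b_from, 12L - shared_codons, 20L,
            translate_dna(rb), substr(prot, 13L - shared_codons, 20L))
  )
  list(gene = gene, reads = reads, alignments = alns,
       expected_weight = 3L * shared_codons,
       expected_offset = b_from)
}

# bare graph object accepted by break_cycles / heaviest_path
graph_obj <- function(ids, edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  structure(list(nodes = stats::setNames(vector("list", length(ids)), ids),
                 edges = edges),
            class = "overlap_graph")
}

edges_df <- function(from = character(0), to = character(0),
                     weight = integer(0)) {
  data.frame(from = from, to = to, weight = as.integer(weight),
             stringsAsFactors = FALSE)
}

# a synthetic aligned core for layout-level tests
make_core <- function(id, seq) {
  structure(list(read_id = id, seq = seq, core_len = nchar(seq),
                 frame = 1L, read_start = 0L, read_end = nchar(seq),
                 ref_id = "p1", bit_score = 1),
            class = "aligned_core")
}

# a synthetic contig for merge-level tests
make_contig <- function(id, seq, n_reads = 2L) {
  structure(list(id = id, seq = seq, length = nchar(seq),
                 members = data.frame(core_id = paste0(id, "_m"),
                                      start = 0L, len = nchar(seq),
                                      stringsAsFactors = FALSE),
                 n_reads = as.integer(n_reads),
                 avg_coverage = as.numeric(n_reads)),
            class = "contig")
}

# random DAG: nodes in a random topological order, forward edges only
random_dag <- function(n_nodes, edge_prob = 0.35, max_w = 50L) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  perm <- sample(ids)
  from <- character(0); to <- character(0)
  if (n_nodes >= 2L) {
    for (i in seq_len(n_nodes - 1L)) {
      for (j in (i + 1L):n_nodes) {
        if (stats::runif(1) < edge_prob) {
          from <- c(from, perm[i]); to <- c(to, perm[j])
        }
      }
    }
  }
  w <- if (length(from)) sample.int(max_w, length(from), replace = TRUE) else integer(0)
  graph_obj(ids, edges_df(from, to, w))
}

# brute-force maximum path weight: enumerate all simple paths (a DAG has
# finitely many); independent of the relaxation implementation
brute_force_max_path_weight <- function(g) {
  edges <- g$edges
  best <- 0L
  walk <- function(u, w) {
    best <<- max(best, w)
    out <- which(edges$from == u)
    for (k in out) walk(edges$to[k], w + edges$weight[k])
  }
  for (u in names(g$nodes)) walk(u, 0L)
  best
}

# plant r extra back edges into a random DAG so it contains cycles
plant_cycles <- function(g, n_back = 2L, max_w = 50L) {
  edges <- g$edges
  if (nrow(edges) == 0L) return(g)
  for (k in seq_len(n_back)) {
    e <- edges[sample.int(nrow(edges), 1L), ]
    back <- data.frame(from = e$to, to = e$from,
                       weight = sample.int(max_w, 1L),
                       stringsAsFactors = FALSE)
    key <- paste(edges$from, edges$to)
    if (!(paste(back$from, back$to) %in% key)) edges <- rbind(edges, back)
  }
  g$edges <- edges
  rownames(g$edges) <- NULL
  g
}

# igraph-based acyclicity oracle
is_dag_oracle <- function(g) {
  if (nrow(g$edges) == 0L) return(TRUE)
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      vertices = names(g$nodes))
  igraph::is_dag(ig)
}
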