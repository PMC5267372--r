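# Layout and consensus: cycle breaking, maximum-weight path extraction, and
# overlap-aware concatenation of cores into contigs.
#
# Both graph classes used in this package (`overlap_graph` over cores and
# `contig_graph` over contigs) store their nodes as a named list and their
# edges as a data.frame with columns from, to, weight; the functions here
# operate on either.

# depth-first search for a directed cycle; returns a data.frame of the
# cycle's (from, to) pairs or NULL when the graph is acyclic. Iterative so
# that deep graphs do not hit R's recursion limit.
.find_cycle <- function(node_ids, edges) {
  if (nrow(edges) == 0L) return(NULL)
  ids <- sort(node_ids)
  adj <- lapply(stats::setNames(ids, ids), function(u) sort(edges$to[edges$from == u]))
  color <- stats::setNames(integer(length(ids)), ids)  # 0 white, 1 gray, 2 black
  for (s in ids) {
    if (color[[s]] != 0L) next
    path <- s
    kid <- 1L
    color[[s]] <- 1L
    while (length(path)) {
      u <- path[length(path)]
      kids <- adj[[u]]
      i <- kid[length(kid)]
      if (i > length(kids)) {
        color[[u]] <- 2L
        path <- path[-length(path)]
        kid <- kid[-length(kid)]
        next
      }
      kid[length(kid)] <- i + 1L
      v <- kids[i]
      if (color[[v]] == 1L) {
        cyc <- c(path[seq(match(v, path), length(path))], v)
        return(data.frame(from = cyc[-length(cyc)], to = cyc[-1L],
                          stringsAsFactors = FALSE))
      }
      if (color[[v]] == 0L) {
        color[[v]] <- 1L
        path <- c(path, v)
        kid <- c(kid, 1L)
      }
    }
  }
  NULL
}

#' Break directed cycles by deleting the lightest edge of each cycle
#'
#' Repeatedly searches the graph depth-first for a directed cycle and, on
#' finding one, deletes the cycle's minimum-weight edge (ties broken by the
#' lexicographically smallest (from, to) pair), until the graph is acyclic.
#' Each deletion removes an edge, so the procedure terminates. Cycles are
#' rare when assembling the reads of a single gene family, so few edges
#' are lost in practice.
#'
#' @param g an `overlap_graph` or `contig_graph`.
#' @return the same graph object with cycle edges removed; the deleted
#'   edges (a data.frame) are attached as attribute `removed_edges`.
#' @export
break_cycles <- function(g) {
  edges <- g$edges
  removed <- edges[0L, , drop = FALSE]
  repeat {
    cyc <- .find_cycle(names(g$nodes), edges)
    if (is.null(cyc)) break
    key <- paste(edges$from, edges$to, sep = "\r")
    idx <- match(paste(cyc$from, cyc$to, sep = "\r"), key)
    cand <- edges[idx, ]
    pick <- idx[order(cand$weight, cand$from, cand$to)][1L]
    removed <- rbind(removed, edges[pick, , drop = FALSE])
    edges <- edges[-pick, , drop = FALSE]
  }
  rownames(edges) <- NULL
  rownames(removed) <- NULL
  g$edges <- edges
  attr(g, "removed_edges") <- removed
  g
}

# Kahn topological order with deterministic smallest-id tie-break;
# errors if the graph has a cycle.
.topo_order <- function(node_ids, edges) {
  ids <- sort(node_ids)
  indeg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    tab <- table(edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  out_adj <- lapply(stats::setNames(ids, ids),
                    function(u) edges$to[edges$from == u])
  order_out <- character(length(ids))
  avail <- sort(ids[indeg == 0L])
  k <- 0L
  while (length(avail)) {
    u <- avail[1L]
    avail <- avail[-1L]
    k <- k + 1L
    order_out[k] <- u
    for (v in out_adj[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) avail <- sort(c(avail, v))
    }
  }
  if (k < length(ids)) stop("graph contains a directed cycle")
  order_out
}

#' Find a maximum-weight directed path
#'
#' Computes a path maximizing the sum of edge weights (the total number of
#' overlapping nucleotides along the path) by relaxing vertices in
#' topological order, which solves the problem in linear time on a DAG.
#' Single-node paths have weight 0, so the empty-ish answer on an edgeless
#' graph is a single node. Ties are broken deterministically: among
#' equal-weight predecessors the smaller node id wins, and among
#' equal-weight terminal nodes the smaller node id wins.
#'
#' @param g an acyclic `overlap_graph` or `contig_graph`.
#' @return an object of class `assembly_path` with elements `nodes`
#'   (ordered character vector), `edges` (data.frame of the path's edges)
#'   and `weight` (integer).
#' @export
heaviest_path <- function(g) {
  ids <- names(g$nodes)
  if (length(ids) == 0L) stop("heaviest_path: empty graph")
  edges <- g$edges
  topo <- .topo_order(ids, edges)
  dist <- stats::setNames(integer(length(ids)), ids)
  pred <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (u in topo) {
    out <- which(edges$from == u)
    for (k in out) {
      v <- edges$to[k]
      cand <- dist[[u]] + edges$weight[k]
      if (cand > dist[[v]]) {
        dist[[v]] <- cand
        pred[[v]] <- u
      } else if (cand == dist[[v]] && !is.na(pred[[v]]) && u < pred[[v]]) {
        pred[[v]] <- u
      }
    }
  }
  best <- max(dist)
  end <- sort(names(dist)[dist == best])[1L]
  nodes <- end
  while (!is.na(pred[[nodes[1L]]])) nodes <- c(pred[[nodes[1L]]], nodes)
  path_edges <- edges[0L, , drop = FALSE]
  if (length(nodes) > 1L) {
    idx <- vapply(seq_len(length(nodes) - 1L), function(i) {
      which(edges$from == nodes[i] & edges$to == nodes[i + 1L])[1L]
    }, integer(1))
    path_edges <- edges[idx, , drop = FALSE]
    rownames(path_edges) <- NULL
  }
  structure(list(nodes = nodes, edges = path_edges, weight = as.integer(best)),
            class = "assembly_path")
}

#' Build a contig from a path of cores
#'
#' Because all overlaps have perfect identity, the consensus is obtained by
#' plain concatenation: start from the first core and, for each edge, append
#' the target core minus its overlapped prefix. Every member core is then an
#' exact substring of the contig at its recorded start offset.
#'
#' @param path an `assembly_path`.
#' @param cores named list of `aligned_core` objects covering the path.
#' @param id contig id to assign.
#' @return an object of class `contig` with elements `id`, `seq`, `length`,
#'   `members` (data.frame core_id, start, len), `n_reads`, `avg_coverage`.
#' @export
path_consensus <- function(path, cores, id = "contig_1") {
  first <- cores[[path$nodes[1L]]]
  seq <- first$seq
  starts <- 0L
  if (nrow(path$edges)) {
    for (k in seq_len(nrow(path$edges))) {
      e <- path$edges[k, ]
      tgt <- cores[[e$to]]
      off <- starts[k] + e$offset
      w <- e$weight
      if (substr(seq, off + 1L, off + w) != substr(tgt$seq, 1L, w)) {
        stop("internal error: overlap inconsistency on edge ",
             e$from, "->", e$to)
      }
      seq <- paste0(seq, substr(tgt$seq, w + 1L, tgt$core_len))
      starts <- c(starts, off)
    }
  }
  lens <- vapply(path$nodes, function(n) cores[[n]]$core_len, integer(1))
  members <- data.frame(core_id = path$nodes, start = as.integer(starts),
                        len = as.integer(lens), stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(
    list(id = id, seq = seq, length = nchar(seq), members = members,
         n_reads = length(path$nodes),
         avg_coverage = sum(lens) / nchar(seq)),
    class = "contig"
  )
}

#' Extract contigs by repeated maximum-weight-path removal
#'
#' Repeats until the graph is empty: find the maximum-weight path, build its
#' consensus contig, report the contig if it passes the `minLength`,
#' `minReads` and `minAvCoverage` filters (all inclusive bounds), and remove
#' the path's nodes and incident edges from the graph. Candidates that fail
#' a filter still have their nodes removed, so no read is used twice.
#'
#' @param g an acyclic `overlap_graph` (run [break_cycles()] first).
#' @param params an [assembly_params()] object.
#' @return list of `contig` objects, ids `contig_1`, `contig_2`, ... in
#'   extraction order; the number of candidate paths examined is attached
#'   as attribute `n_candidates`.
#' @export
extract_contigs <- function(g, params = assembly_params()) {
  contigs <- list()
  n_cand <- 0L
  k <- 0L
  while (length(g$nodes)) {
    p <- heaviest_path(g)
    n_cand <- n_cand + 1L
    cand <- path_consensus(p, g$nodes, id = sprintf("contig_%d", k + 1L))
    if (cand$length >= params$minLength &&
        cand$n_reads >= params$minReads &&
        cand$avg_coverage >= params$minAvCoverage) {
      k <- k + 1L
      contigs[[k]] <- cand
    }
    g$nodes <- g$nodes[setdiff(names(g$nodes), p$nodes)]
    keep <- !(g$edges$from %in% p$nodes | g$edges$to %in% p$nodes)
    g$edges <- g$edges[keep, , drop = FALSE]
  }
  attr(contigs, "n_candidates") <- n_cand
  contigs
}
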