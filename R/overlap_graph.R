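# The read overlap graph G = (V, E).
#
# Nodes are aligned cores; a directed edge from core a to core b exists when
# a reference protein is aligned by both reads, the two protein alignments
# overlap on the reference, and the DNA suffix of a implied by that shared
# reference region equals the corresponding prefix of b exactly (gap-free,
# perfect identity). The edge weight is the length of the induced DNA
# overlap in nucleotides.
#
# With k reference sequences and n cores all pairwise overlapping on every
# reference, construction examines at most k * n * (n - 1) ordered pairs,
# i.e. O(k n^2) candidate edges; after collapsing parallel candidates at
# most one edge per ordered pair remains.

#' Group core projections by reference sequence
#'
#' @param projections list of `core_projection` objects.
#' @return named list (sorted by reference id) of projection lists, each
#'   ordered by smallest reference position, then core id.
#' @export
index_by_reference <- function(projections) {
  if (length(projections) == 0L) return(stats::setNames(list(), character(0)))
  refs <- vapply(projections, function(p) p$ref_id, character(1))
  out <- lapply(sort(unique(refs)), function(r) {
    ps <- projections[refs == r]
    first <- vapply(ps, function(p) p$ref_aa[1L], integer(1))
    ids <- vapply(ps, function(p) p$core_id, character(1))
    ps[order(first, ids)]
  })
  stats::setNames(out, sort(unique(refs)))
}

#' Induce a candidate DNA overlap edge from two projections
#'
#' Given two projections of distinct cores onto the same reference, finds
#' the reference positions shared by both, derives the implied placement of
#' core b within core a, and accepts the candidate only if the placement is
#' a proper suffix-prefix layout (b starts inside a and extends at least to
#' a's end), all shared positions imply the same placement (no indel between
#' the reads), and the overlapping DNA is exactly identical. The overlap
#' length ignores induced gaps by construction, because placements are
#' derived from doubly-ungapped columns and identity is checked on the
#' literal DNA suffix/prefix.
#'
#' @param a,b `core_projection` objects with `a$ref_id == b$ref_id`.
#' @param cores named list of `aligned_core` objects.
#' @param match_n if `FALSE` (default) the base N matches nothing, including
#'   another N, so overlaps containing N are rejected.
#' @return a list `(from, to, weight, offset, ref)` or `NULL`.
#' @export
induce_overlap <- function(a, b, cores, match_n = FALSE) {
  if (a$ref_id != b$ref_id) stop("projections do not share a reference")
  if (a$core_id == b$core_id) return(NULL)
  shared <- intersect(a$ref_aa, b$ref_aa)
  if (length(shared) == 0L) return(NULL)
  d <- a$core_off[match(shared, a$ref_aa)] - b$core_off[match(shared, b$ref_aa)]
  if (length(unique(d)) != 1L) return(NULL)  # inconsistent placement (indel)
  offset <- d[1L]
  if (offset < 0L) return(NULL)
  ca <- cores[[a$core_id]]; cb <- cores[[b$core_id]]
  weight <- ca$core_len - offset
  if (weight < 1L || weight > cb$core_len) return(NULL)  # no containment edges
  sa <- substr(ca$seq, offset + 1L, ca$core_len)
  sb <- substr(cb$seq, 1L, weight)
  if (!match_n && (grepl("N", sa, fixed = TRUE) || grepl("N", sb, fixed = TRUE))) {
    return(NULL)
  }
  if (sa != sb) return(NULL)
  list(from = a$core_id, to = b$core_id, weight = as.integer(weight),
       offset = as.integer(offset), ref = a$ref_id)
}

.empty_edges <- function() {
  data.frame(from = character(0), to = character(0), weight = integer(0),
             offset = integer(0), ref = character(0), stringsAsFactors = FALSE)
}

#' Build the read overlap graph
#'
#' For every reference sequence, all ordered pairs of projections onto it
#' are examined with [induce_overlap()]; candidates shorter than
#' `min_overlap` are discarded and parallel candidates for the same ordered
#' core pair are collapsed to the maximum weight (ties kept from the
#' lexicographically smallest inducing reference). The result is
#' independent of input order.
#'
#' @param cores named list of `aligned_core` objects (the nodes).
#' @param projections list of `core_projection` objects.
#' @param min_overlap minimum induced overlap length in nt (inclusive).
#' @param match_n passed to [induce_overlap()].
#' @return an object of class `overlap_graph` with elements `nodes` (the
#'   core list) and `edges` (data.frame from, to, weight, offset, ref).
#' @export
build_overlap_graph <- function(cores, projections, min_overlap = 20L,
                                match_n = FALSE) {
  stopifnot(min_overlap >= 1L)
  idx <- index_by_reference(projections)
  cand <- list(); n <- 0L
  for (ps in idx) {
    m <- length(ps)
    if (m < 2L) next
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        e <- induce_overlap(ps[[i]], ps[[j]], cores, match_n = match_n)
        if (!is.null(e) && e$weight >= min_overlap) {
          n <- n + 1L; cand[[n]] <- e
        }
      }
    }
  }
  if (n == 0L) {
    edges <- .empty_edges()
  } else {
    edges <- do.call(rbind, lapply(cand[seq_len(n)], as.data.frame,
                                   stringsAsFactors = FALSE))
    # collapse parallel candidates: max weight, then smallest inducing ref
    edges <- edges[order(edges$from, edges$to, -edges$weight, edges$ref), ]
    edges <- edges[!duplicated(edges[, c("from", "to")]), ]
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = cores, edges = edges), class = "overlap_graph")
}

#' Check the structural invariants of an overlap graph
#'
#' Asserts that every edge is a perfect suffix-prefix overlap between its
#' cores at the recorded offset and weight, that weights are within bounds,
#' that there are no self-edges, and that each ordered pair carries at most
#' one edge.
#'
#' @param g an `overlap_graph`.
#' @return `TRUE` invisibly; stops on the first violated invariant.
#' @export
validate_overlap_graph <- function(g) {
  e <- g$edges
  if (nrow(e) == 0L) return(invisible(TRUE))
  if (any(e$from == e$to)) stop("self-edge present")
  if (anyDuplicated(e[, c("from", "to")])) stop("parallel edges present")
  for (i in seq_len(nrow(e))) {
    a <- g$nodes[[e$from[i]]]; b <- g$nodes[[e$to[i]]]
    if (is.null(a) || is.null(b)) stop("edge references a missing node")
    w <- e$weight[i]; off <- e$offset[i]
    if (w < 1L || w > min(a$core_len, b$core_len)) {
      stop("edge ", e$from[i], "->", e$to[i], ": weight out of bounds")
    }
    if (off != a$core_len - w) {
      stop("edge ", e$from[i], "->", e$to[i], ": offset != core_len - weight")
    }
    if (substr(a$seq, off + 1L, a$core_len) != substr(b$seq, 1L, w)) {
      stop("edge ", e$from[i], "->", e$to[i],
           ": suffix-prefix identity violated")
    }
  }
  invisible(TRUE)
}

#' Dump a graph in GraphViz DOT format
#'
#' @param g an `overlap_graph` or `contig_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_graph_dot <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph overlap {", con)
  for (id in names(g$nodes)) writeLines(sprintf('  "%s";', id), con)
  e <- g$edges
  if (nrow(e)) {
    writeLines(sprintf('  "%s" -> "%s" [label=%d];', e$from, e$to, e$weight), con)
  }
  writeLines("}", con)
  invisible(path)
}
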