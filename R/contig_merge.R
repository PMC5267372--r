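# The second overlap graph H over contigs: containment removal and
# suffix-prefix merging.
#
# Contig-to-contig comparison is ungapped: a placement of one sequence
# against another at a fixed offset is scored by percent identity
# (matches / overlap length * 100). Exhaustive sliding placement is
# affordable here because a single gene family yields tens to hundreds of
# contigs at most, each on the order of a gene length.

# mismatch budget allowed for identity >= thr (%) over length L
.mm_budget <- function(L, thr) as.integer(floor(L * (1 - thr / 100) + 1e-9))

#' Identify contigs contained in longer contigs
#'
#' A contig is contained when some ungapped placement of its full sequence
#' within a strictly longer contig matches at `min_identity` percent or
#' more; such contigs are redundant (typically sequencing-error variants of
#' the longer contig) and are discarded. Two contigs of equal length that
#' match at or above the threshold are mutual duplicates; the one with the
#' lexicographically larger id is discarded.
#'
#' @param contigs list of `contig` objects.
#' @param min_identity percent identity threshold in (0, 100].
#' @return character vector of contig ids to discard.
#' @export
find_containments <- function(contigs, min_identity = 98) {
  stopifnot(min_identity > 0, min_identity <= 100)
  n <- length(contigs)
  if (n < 2L) return(character(0))
  ids <- vapply(contigs, function(x) x$id, character(1))
  lens <- vapply(contigs, function(x) x$length, integer(1))
  raws <- lapply(contigs, function(x) .as_raw(x$seq))
  contained <- character(0)
  for (i in seq_len(n)) {
    budget <- .mm_budget(lens[i], min_identity)
    for (j in seq_len(n)) {
      if (i == j) next
      if (lens[i] > lens[j]) next
      if (lens[i] == lens[j] && ids[i] < ids[j]) next  # keep the smaller id
      hit <- FALSE
      for (off in 0:(lens[j] - lens[i])) {
        if (.mismatches(raws[[j]][(off + 1L):(off + lens[i])], raws[[i]]) <= budget) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        contained <- c(contained, ids[i])
        break
      }
    }
  }
  unique(contained)
}

#' Build the contig overlap graph H
#'
#' Connects contig c to contig d by a directed edge when a suffix of c and
#' a prefix of d admit an ungapped overlap of length at least `min_overlap`
#' with percent identity at least `min_identity`; for each ordered pair the
#' longest qualifying overlap is stored. Containments should be removed
#' before calling this.
#'
#' @param contigs list of `contig` objects (containments removed).
#' @param min_overlap minimum overlap length in nt (inclusive).
#' @param min_identity percent identity threshold in (0, 100].
#' @return an object of class `contig_graph` with `nodes` (named list of
#'   contigs) and `edges` (data.frame from, to, weight, identity) where
#'   weight is the overlap length.
#' @export
build_contig_graph <- function(contigs, min_overlap = 20L, min_identity = 98) {
  stopifnot(min_overlap >= 1L, min_identity > 0, min_identity <= 100)
  ids <- vapply(contigs, function(x) x$id, character(1))
  nodes <- stats::setNames(contigs, ids)
  lens <- vapply(contigs, function(x) x$length, integer(1))
  raws <- lapply(contigs, function(x) .as_raw(x$seq))
  rows <- list(); nr <- 0L
  n <- length(contigs)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        Lmax <- min(lens[i], lens[j])
        if (Lmax < min_overlap) next
        for (L in seq(Lmax, min_overlap, by = -1L)) {
          mm <- .mismatches(raws[[i]][(lens[i] - L + 1L):lens[i]],
                            raws[[j]][1:L])
          if (mm <= .mm_budget(L, min_identity)) {
            nr <- nr + 1L
            rows[[nr]] <- data.frame(
              from = ids[i], to = ids[j], weight = as.integer(L),
              identity = 100 * (L - mm) / L, stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
  }
  edges <- if (nr) do.call(rbind, rows[seq_len(nr)]) else
    data.frame(from = character(0), to = character(0), weight = integer(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "contig_graph")
}

# per-position read coverage of a contig, from its member table
.contig_cov <- function(contig) {
  cov <- integer(contig$length)
  m <- contig$members
  for (k in seq_len(nrow(m))) {
    idx <- (m$start[k] + 1L):(m$start[k] + m$len[k])
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

# merge contig d onto the growing contig cur at global offset off with
# overlap L; overlap mismatches resolved by per-column read support
# (ties keep the earlier contig's character)
.merge_pair <- function(cur, d, L) {
  off <- cur$length - L
  cs <- .as_raw(cur$seq)
  ds <- .as_raw(d$seq)
  ov_cur <- cs[(off + 1L):(off + L)]
  ov_d <- ds[1:L]
  diff <- which(ov_cur != ov_d)
  if (length(diff)) {
    cov_cur <- .contig_cov(cur)[(off + 1L):(off + L)]
    cov_d <- .contig_cov(d)[1:L]
    take_d <- diff[cov_d[diff] > cov_cur[diff]]
    ov_cur[take_d] <- ov_d[take_d]
    cs[(off + 1L):(off + L)] <- ov_cur
  }
  merged_seq <- paste0(rawToChar(cs), rawToChar(ds[-(1:L)]))
  members <- rbind(
    cur$members,
    transform(d$members, start = start + off)
  )
  rownames(members) <- NULL
  structure(
    list(id = cur$id, seq = merged_seq, length = nchar(merged_seq),
         members = members, n_reads = cur$n_reads + d$n_reads,
         avg_coverage = sum(members$len) / nchar(merged_seq)),
    class = "contig"
  )
}

#' Merge overlapping contigs along maximum-weight paths of H
#'
#' Applies the same layout scheme used for reads to the contig graph:
#' cycles are broken by deleting the lightest edge, maximum-weight paths
#' are extracted repeatedly, and the contigs along each path are merged by
#' overlap-aware concatenation. Because contig overlaps tolerate up to
#' `100 - minPercentIdentityContigs` percent mismatches, a mismatching
#' overlap column takes the character from the contig with more reads
#' covering that column (ties keep the earlier contig in the path).
#' Contigs on single-node paths pass through unchanged.
#'
#' @param h a `contig_graph` (see [build_contig_graph()]).
#' @param params an [assembly_params()] object (unused thresholds are
#'   ignored; kept for interface symmetry).
#' @return list of `contig` objects; a merged contig keeps the id of the
#'   first contig on its path.
#' @export
merge_contigs <- function(h, params = assembly_params()) {
  h <- break_cycles(h)
  out <- list()
  while (length(h$nodes)) {
    p <- heaviest_path(h)
    cur <- h$nodes[[p$nodes[1L]]]
    if (length(p$nodes) > 1L) {
      for (k in seq_len(nrow(p$edges))) {
        cur <- .merge_pair(cur, h$nodes[[p$edges$to[k]]], p$edges$weight[k])
      }
    }
    out[[length(out) + 1L]] <- cur
    h$nodes <- h$nodes[setdiff(names(h$nodes), p$nodes)]
    keep <- !(h$edges$from %in% p$nodes | h$edges$to %in% p$nodes)
    h$edges <- h$edges[keep, , drop = FALSE]
  }
  out
}
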