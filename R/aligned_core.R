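# Aligned cores and core projections.
#
# The aligned core of a read is the read segment covered by the read's
# highest-scoring local protein alignment, oriented to the coding strand:
# if the defining alignment has a negative frame, the core sequence is the
# reverse complement of the forward-strand slice. The core is the node unit
# of the read overlap graph.
#
# A core projection maps reference amino-acid positions onto codon-start
# offsets within the core sequence, one entry per alignment column that is
# ungapped in both the query and the subject. Projections are the raw
# material from which induced DNA overlaps are computed.

#' Compute a read's aligned core
#'
#' Selects the alignment with the highest bit score (ties: longer read
#' interval, then lexicographically smaller reference id) and extracts the
#' covered read segment, reverse-complemented when the frame is negative.
#'
#' @param read list with elements `id` and `seq`.
#' @param alns data.frame of alignments, all with `read_id == read$id`.
#' @return an object of class `aligned_core` with elements `read_id`, `seq`,
#'   `core_len`, `frame`, `read_start`, `read_end`, `ref_id`, `bit_score`.
#' @export
compute_aligned_core <- function(read, alns) {
  if (is.null(alns) || nrow(alns) == 0L) {
    stop("read '", read$id, "' has no alignments")
  }
  if (!all(alns$read_id == read$id)) {
    stop("alignments for foreign read(s) passed for read '", read$id, "'")
  }
  if (any(alns$read_end > nchar(read$seq))) {
    stop("alignment extends past the end of read '", read$id, "'")
  }
  ord <- order(-alns$bit_score, -(alns$read_end - alns$read_start), alns$ref_id)
  a <- alns[ord[1L], ]
  slice <- substr(read$seq, a$read_start + 1L, a$read_end)
  core_seq <- if (a$frame > 0L) slice else revcomp(slice)
  structure(
    list(read_id = read$id, seq = core_seq, core_len = nchar(core_seq),
         frame = a$frame, read_start = a$read_start, read_end = a$read_end,
         ref_id = a$ref_id, bit_score = a$bit_score),
    class = "aligned_core"
  )
}

#' Compute aligned cores for all reads with alignments
#'
#' @param reads named character vector of read sequences.
#' @param alignments alignment data.frame.
#' @return named list of `aligned_core` objects, keyed and ordered by read id.
#' @export
compute_cores <- function(reads, alignments) {
  if (nrow(alignments) == 0L) return(stats::setNames(list(), character(0)))
  missing <- setdiff(unique(alignments$read_id), names(reads))
  if (length(missing)) {
    stop("alignment read id(s) absent from the read set: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  by_read <- split(alignments, alignments$read_id)
  ids <- sort(names(by_read))
  cores <- lapply(ids, function(id) {
    compute_aligned_core(list(id = id, seq = unname(reads[[id]])), by_read[[id]])
  })
  stats::setNames(cores, ids)
}

#' Project a protein alignment onto an aligned core
#'
#' Maps each alignment column that is ungapped in both the query and the
#' subject to a pair (reference amino-acid position, codon-start offset
#' within the core sequence). Columns whose codon falls outside the core
#' interval are dropped (foreign alignments are clipped to the core), and
#' alignments on the opposite strand of the core's defining alignment are
#' rejected because the core is single-stranded.
#'
#' @param core an `aligned_core`.
#' @param aln a single alignment (list or one-row data.frame) with
#'   `read_id == core$read_id`.
#' @return an object of class `core_projection` with integer vectors
#'   `ref_aa` and `core_off` (parallel, strictly increasing), or `NULL` if
#'   the strands disagree or no column survives clipping.
#' @export
project_alignment <- function(core, aln) {
  aln <- as.list(aln)
  if (aln$read_id != core$read_id) {
    stop("alignment for read '", aln$read_id,
         "' projected onto core of read '", core$read_id, "'")
  }
  if (sign(aln$frame) != sign(core$frame)) return(NULL)
  q <- .as_raw(aln$q_aln); s <- .as_raw(aln$s_aln); gap <- charToRaw("-")
  both <- q != gap & s != gap
  if (!any(both)) return(NULL)
  iq <- cumsum(q != gap) - 1L   # 0-based index among query residues
  is_ <- cumsum(s != gap) - 1L  # 0-based index among subject residues
  ref_aa <- aln$ref_start + is_[both]
  i <- iq[both]
  off <- if (core$frame > 0L) {
    (aln$read_start + 3L * i) - core$read_start
  } else {
    (core$read_end - aln$read_end) + 3L * i
  }
  keep <- off >= 0L & off <= core$core_len - 3L
  if (!any(keep)) return(NULL)
  structure(
    list(core_id = core$read_id, ref_id = aln$ref_id,
         ref_aa = as.integer(ref_aa[keep]), core_off = as.integer(off[keep]),
         frame_sign = sign(core$frame)),
    class = "core_projection"
  )
}

#' Project every alignment onto the core of its read
#'
#' @param cores named list of `aligned_core` objects.
#' @param alignments alignment data.frame.
#' @return list of `core_projection` objects (strand-inconsistent or fully
#'   clipped alignments are dropped).
#' @export
project_all <- function(cores, alignments) {
  if (nrow(alignments) == 0L) return(list())
  out <- vector("list", nrow(alignments))
  n <- 0L
  for (i in seq_len(nrow(alignments))) {
    core <- cores[[alignments$read_id[i]]]
    if (is.null(core)) next
    p <- project_alignment(core, alignments[i, ])
    if (!is.null(p)) { n <- n + 1L; out[[n]] <- p }
  }
  out[seq_len(n)]
}
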