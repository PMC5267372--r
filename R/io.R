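# FASTA read sets, the tabular protein-alignment format, and contig output.
#
# Reads are represented throughout the package as a named character vector:
# names are read ids (header token before the first whitespace), values are
# upper-case DNA sequences over A,C,G,T,N.
#
# Protein alignments are a data.frame with one row per local alignment and
# columns read_id, ref_id, bit_score, frame, read_start, read_end, ref_start,
# ref_end, q_aln, s_aln. Internally all coordinates are 0-based half-open on
# the read's forward strand (read_*, nt) and on the reference (ref_*, aa);
# the on-disk format uses the 1-based inclusive BLAST tabular convention with
# read_start > read_end signalling a minus-strand (negative frame) hit.

#' Read a FASTA file of sequencing reads
#'
#' @param path path to a FASTA file.
#' @return named character vector; names are ids, values upper-case DNA.
#'   An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA, line ", nonblank[1L], ": expected a '>' header")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA, line ",
         which(startsWith(trimws(lines), ">") & !nzchar(sub("^>\\s*", "", trimws(lines))))[1L],
         ": empty header")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate read id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("record '", ids[nchar(seqs) == 0L][1L], "' has an empty sequence")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(utils::head(ids[bad], 3L), collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# validate one internally-normalized alignment row; returns NULL or a message
.aln_row_problem <- function(r) {
  if (is.na(r$bit_score) || r$bit_score < 0) return("bit score is not a non-negative number")
  if (is.na(r$frame) || !(r$frame %in% c(-3L, -2L, -1L, 1L, 2L, 3L))) {
    return("frame outside {+1,+2,+3,-1,-2,-3}")
  }
  if (anyNA(c(r$read_start, r$read_end, r$ref_start, r$ref_end))) {
    return("non-integer coordinate")
  }
  if (!nzchar(r$q_aln) || nchar(r$q_aln) != nchar(r$s_aln)) {
    return("q_aln and s_aln must be non-empty and of equal length")
  }
  q <- .as_raw(r$q_aln); s <- .as_raw(r$s_aln); gap <- charToRaw("-")
  if (any(q == gap & s == gap)) return("column gapped in both q_aln and s_aln")
  if (r$read_start < 0L || r$read_start >= r$read_end) {
    return("read interval is empty or negative")
  }
  if (r$ref_start < 0L || r$ref_start >= r$ref_end) {
    return("reference interval is empty or negative")
  }
  if (sum(s != gap) != r$ref_end - r$ref_start) {
    return(sprintf("s_aln has %d residues but the reference span is %d aa",
                   sum(s != gap), r$ref_end - r$ref_start))
  }
  if (3L * sum(q != gap) != r$read_end - r$read_start) {
    return(sprintf("q_aln has %d residues (= %d nt) but the read span is %d nt",
                   sum(q != gap), 3L * sum(q != gap), r$read_end - r$read_start))
  }
  NULL
}

#' Parse tabular protein alignments
#'
#' Reads a 10-column tab-separated file with columns read_id, ref_id,
#' bit_score, frame, read_start, read_end, ref_start, ref_end, q_aln, s_aln.
#' On file, coordinates follow the BLAST tabular convention: 1-based
#' inclusive, with read_start > read_end for minus-strand (negative frame)
#' alignments. Returned coordinates are 0-based half-open on the read's
#' forward strand and on the reference.
#'
#' @param path path to the TSV file.
#' @param permissive if `TRUE`, malformed lines are skipped with a warning
#'   instead of raising an error.
#' @return data.frame of alignments (possibly 0 rows).
#' @export
parse_alignments <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  rows <- vector("list", sum(keep))
  k <- 0L
  bad <- function(i, msg) {
    if (permissive) {
      warning("line ", i, ": ", msg, " -- skipped", call. = FALSE)
      FALSE
    } else {
      stop("line ", i, ": ", msg, call. = FALSE)
    }
  }
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 10L) {
      bad(i, sprintf("expected 10 tab-separated columns, found %d", length(f)))
      next
    }
    score <- suppressWarnings(as.numeric(f[3L]))
    frame <- suppressWarnings(as.integer(f[4L]))
    co <- suppressWarnings(as.integer(f[5:8]))
    if (anyNA(co)) { bad(i, "non-integer coordinate"); next }
    if (is.na(frame) || !(frame %in% c(-3L, -2L, -1L, 1L, 2L, 3L))) {
      bad(i, "frame outside {+1,+2,+3,-1,-2,-3}"); next
    }
    # strand consistency of the on-file read coordinates
    if (frame > 0L && co[1L] > co[2L]) {
      bad(i, "positive frame but read_start > read_end"); next
    }
    if (frame < 0L && co[1L] <= co[2L]) {
      bad(i, "negative frame but read_start <= read_end"); next
    }
    r <- list(
      read_id = f[1L], ref_id = f[2L], bit_score = score, frame = frame,
      read_start = min(co[1L], co[2L]) - 1L, read_end = max(co[1L], co[2L]),
      ref_start = co[3L] - 1L, ref_end = co[4L],
      q_aln = toupper(f[9L]), s_aln = toupper(f[10L])
    )
    msg <- .aln_row_problem(r)
    if (!is.null(msg)) { bad(i, msg); next }
    k <- k + 1L
    rows[[k]] <- r
  }
  if (k == 0L) return(.empty_alignments())
  do.call(rbind, lapply(rows[seq_len(k)], function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

.empty_alignments <- function() {
  data.frame(
    read_id = character(0), ref_id = character(0), bit_score = numeric(0),
    frame = integer(0), read_start = integer(0), read_end = integer(0),
    ref_start = integer(0), ref_end = integer(0),
    q_aln = character(0), s_aln = character(0), stringsAsFactors = FALSE
  )
}

#' Write protein alignments in the tabular on-disk format
#'
#' Inverse of [parse_alignments()]: internal 0-based half-open coordinates
#' are converted to 1-based inclusive, with read start/end swapped for
#' negative frames.
#'
#' @param alignments alignment data.frame in internal coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  a <- alignments
  fs <- ifelse(a$frame > 0L, a$read_start + 1L, a$read_end)
  fe <- ifelse(a$frame > 0L, a$read_end, a$read_start + 1L)
  out <- data.frame(
    a$read_id, a$ref_id, a$bit_score, a$frame, fs, fe,
    a$ref_start + 1L, a$ref_end, a$q_aln, a$s_aln, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write contigs to FASTA
#'
#' Contigs are written in order of decreasing length (ties broken by id),
#' with headers of the form
#' `>contig_<k> length=<L> reads=<n> avgCoverage=<c>` (coverage with two
#' decimals).
#'
#' @param contigs list of contig objects (see [extract_contigs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  if (length(contigs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lens <- vapply(contigs, function(x) x$length, integer(1))
  ids <- vapply(contigs, function(x) x$id, character(1))
  ord <- order(-lens, ids)
  seqs <- vapply(contigs[ord], function(x) x$seq, character(1))
  hdr <- vapply(contigs[ord], function(x) {
    sprintf("%s length=%d reads=%d avgCoverage=%.2f",
            x$id, x$length, x$n_reads, x$avg_coverage)
  }, character(1))
  write_fasta(stats::setNames(seqs, hdr), path)
}
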