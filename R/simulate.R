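# Self-contained fixture simulator: a protein-coding gene, a family of
# diverged reference proteins, tiled reads, and the exact protein-alignment
# records that a translated search would produce for those reads.
#
# The simulated aligner is idealised: it knows each read's true origin, so
# alignment coordinates are exact, alignments are ungapped, and the read
# interval is trimmed to whole codons in the read's true frame (local
# protein alignment never covers partial codons). Read ids encode the true
# origin ("<prefix>|<gene start>|<f or r>") so assemblies can be checked
# against ground truth.

.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a simulated gene-family fixture
#'
#' @param gene_length_nt gene length in nt, a multiple of 3.
#' @param n_references number of reference proteins in the family.
#' @param reference_divergence per-site amino-acid substitution rate of the
#'   diverged references (reference 1 is always the exact translation).
#' @param read_length read length in nt (101 by default, a typical Illumina
#'   HiSeq read length).
#' @param tiling_step distance between consecutive read start positions.
#' @param strand_flip_prob probability that a read is sampled from the
#'   reverse strand.
#' @param substitution_rate per-nucleotide read error probability.
#' @param seed integer seed making the whole fixture reproducible.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(gene_length_nt = 999L,
                            n_references = 3L,
                            reference_divergence = 0.05,
                            read_length = 101L,
                            tiling_step = 50L,
                            strand_flip_prob = 0.5,
                            substitution_rate = 0,
                            seed = 1L) {
  s <- list(
    gene_length_nt = as.integer(gene_length_nt),
    n_references = as.integer(n_references),
    reference_divergence = reference_divergence,
    read_length = as.integer(read_length),
    tiling_step = as.integer(tiling_step),
    strand_flip_prob = strand_flip_prob,
    substitution_rate = substitution_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    s$gene_length_nt >= 3L, s$gene_length_nt %% 3L == 0L,
    s$n_references >= 1L, s$read_length >= 3L,
    s$read_length <= s$gene_length_nt, s$tiling_step >= 1L,
    s$reference_divergence >= 0, s$reference_divergence <= 1,
    s$strand_flip_prob >= 0, s$strand_flip_prob <= 1,
    s$substitution_rate >= 0, s$substitution_rate <= 1
  )
  structure(s, class = "simulation_spec")
}

#' Generate a gene and its reference protein family
#'
#' Draws a random codon sequence without internal stop codons; reference 1
#' is its exact translation and each further reference carries independent
#' per-site amino-acid substitutions at rate `reference_divergence`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `gene` (DNA string) and `references` (named character
#'   vector of protein sequences, ids `ref_1`, `ref_2`, ...).
#' @export
make_gene_family <- function(spec) {
  set.seed(spec$seed)
  n_codons <- spec$gene_length_nt %/% 3L
  gene <- paste(sample(.SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
  prot <- translate_dna(gene)
  refs <- character(spec$n_references)
  refs[1L] <- prot
  if (spec$n_references > 1L) {
    aa <- strsplit(prot, "")[[1L]]
    for (i in 2:spec$n_references) {
      mut <- aa
      hit <- which(stats::runif(length(aa)) < spec$reference_divergence)
      for (p in hit) mut[p] <- sample(setdiff(.AA20, aa[p]), 1L)
      refs[i] <- paste(mut, collapse = "")
    }
  }
  list(gene = gene,
       references = stats::setNames(refs, paste0("ref_", seq_along(refs))))
}

#' Sample tiled reads from a gene
#'
#' Reads of length `read_length` start every `tiling_step` nt; the last
#' window is clamped to the gene end so the tail is always covered. Each
#' read is reverse-complemented with probability `strand_flip_prob` and
#' each nucleotide substituted with probability `substitution_rate`.
#' Read ids are `<prefix>|<start>|<f|r>` with the 0-based gene start.
#'
#' @param gene DNA string.
#' @param spec a [simulation_spec()].
#' @param id_prefix prefix for read ids.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(gene, spec, id_prefix = "read") {
  set.seed(spec$seed + 1L)
  L <- nchar(gene)
  rl <- spec$read_length
  starts <- unique(c(seq(0L, L - rl, by = spec$tiling_step), L - rl))
  bases <- c("A", "C", "G", "T")
  reads <- character(length(starts))
  ids <- character(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    seg <- strsplit(substr(gene, s + 1L, s + rl), "")[[1L]]
    err <- which(stats::runif(rl) < spec$substitution_rate)
    for (p in err) seg[p] <- sample(setdiff(bases, seg[p]), 1L)
    seq <- paste(seg, collapse = "")
    flip <- stats::runif(1L) < spec$strand_flip_prob
    if (flip) seq <- revcomp(seq)
    ids[k] <- sprintf("%s|%d|%s", id_prefix, s, if (flip) "r" else "f")
    reads[k] <- seq
  }
  stats::setNames(reads, ids)
}

#' Decode the true origin encoded in simulated read ids
#'
#' @param ids character vector of read ids produced by [simulate_reads()].
#' @return data.frame with columns `id`, `prefix`, `start`, `strand`.
#' @export
read_origin <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("id does not encode an origin: ", ids[bad][1L])
  data.frame(
    id = ids,
    prefix = vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)], collapse = "|"), character(1)),
    start = as.integer(vapply(parts, function(p) p[length(p) - 1L], character(1))),
    strand = vapply(parts, function(p) p[length(p)], character(1)),
    stringsAsFactors = FALSE
  )
}

#' Emit the protein alignments implied by the reads' true origins
#'
#' For each read and each reference, produces the ungapped alignment record
#' a translated search would report: the read interval trimmed to whole
#' codons of the gene's reading frame, the frame derived from strand and
#' codon phase, the query string as the translation of the in-frame read
#' segment, the subject string as the corresponding reference segment, and
#' a bit score of twice the number of matching amino acids.
#'
#' @param reads named character vector from [simulate_reads()].
#' @param references named character vector of reference proteins.
#' @param spec a [simulation_spec()] (unused fields ignored; kept so the
#'   fixture is described by one object).
#' @return alignment data.frame in internal coordinates (see
#'   [parse_alignments()]).
#' @export
simulate_alignments <- function(reads, references, spec) {
  org <- read_origin(names(reads))
  rows <- list(); n <- 0L
  for (k in seq_along(reads)) {
    rl <- nchar(reads[[k]])
    g0 <- org$start[k]
    a0 <- as.integer(ceiling(g0 / 3) * 3)
    a1 <- as.integer(floor((g0 + rl) / 3) * 3)
    if (a1 - a0 < 3L) next
    forward <- org$strand[k] == "f"
    if (forward) {
      rs <- a0 - g0
      re <- a1 - g0
      frame <- (rs %% 3L) + 1L
      qdna <- substr(reads[[k]], rs + 1L, re)
    } else {
      rs <- g0 + rl - a1
      re <- g0 + rl - a0
      frame <- -((rl - re) %% 3L + 1L)
      qdna <- revcomp(substr(reads[[k]], rs + 1L, re))
    }
    q <- translate_dna(qdna)
    qr <- .as_raw(q)
    for (r in seq_along(references)) {
      s <- substr(references[[r]], a0 %/% 3L + 1L, a1 %/% 3L)
      matches <- sum(qr == .as_raw(s))
      n <- n + 1L
      rows[[n]] <- data.frame(
        read_id = org$id[k], ref_id = names(references)[r],
        bit_score = 2 * matches, frame = frame,
        read_start = rs, read_end = re,
        ref_start = a0 %/% 3L, ref_end = a1 %/% 3L,
        q_aln = q, s_aln = s, stringsAsFactors = FALSE
      )
    }
  }
  if (n == 0L) return(.empty_alignments())
  out <- do.call(rbind, rows[seq_len(n)])
  rownames(out) <- NULL
  out
}

#' Write a complete simulated fixture to disk
#'
#' Generates the gene family, reads and alignments for `spec` and writes
#' `reads.fasta`, `alignments.tsv` and `truth.tsv` (read origins) into
#' `dir`.
#'
#' @param dir output directory (created if needed).
#' @param spec a [simulation_spec()].
#' @param id_prefix prefix for read ids.
#' @return invisibly, a list with the generated `gene`, `references`,
#'   `reads`, `alignments` and the three file `paths`.
#' @export
write_fixture <- function(dir, spec = simulation_spec(), id_prefix = "read") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec, id_prefix = id_prefix)
  alns <- simulate_alignments(reads, fam$references, spec)
  paths <- list(
    reads = file.path(dir, "reads.fasta"),
    alignments = file.path(dir, "alignments.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(reads, paths$reads)
  write_alignments(alns, paths$alignments)
  utils::write.table(read_origin(names(reads)), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(gene = fam$gene, references = fam$references,
                 reads = reads, alignments = alns, paths = paths))
}
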