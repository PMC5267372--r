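# End-to-end driver: cores -> projections -> overlap graph -> layout ->
# containment removal -> contig merging.

#' Assemble a read set from its protein alignments
#'
#' Runs the full gene-centric pipeline in memory: compute aligned cores,
#' project all alignments, build and de-cycle the read overlap graph,
#' extract contigs as maximum-weight paths, remove contained contigs and
#' merge overlapping ones.
#'
#' @param reads named character vector of read sequences (see
#'   [read_fasta()]).
#' @param alignments alignment data.frame in internal coordinates (see
#'   [parse_alignments()]).
#' @param params an [assembly_params()] object.
#' @param match_n whether the base N may match another N in induced
#'   overlaps (default `FALSE`: N matches nothing).
#' @return list with `contigs` (list of `contig` objects), `graph` (the
#'   overlap graph after cycle breaking) and `stats` (named list of
#'   pipeline counts).
#' @export
assemble <- function(reads, alignments, params = assembly_params(),
                     match_n = FALSE) {
  stats <- list(reads_in = length(reads))
  if (nrow(alignments) == 0L) {
    warning("no aligned reads: the alignment set is empty", call. = FALSE)
    stats <- c(stats, list(
      reads_aligned = 0L, nodes = 0L, edges = 0L, cycles_broken = 0L,
      contigs_candidates = 0L, contigs_filtered = 0L, contained_removed = 0L,
      contigs_merged = 0L, final_contigs = 0L))
    return(list(contigs = list(), graph = NULL, stats = stats))
  }
  cores <- compute_cores(reads, alignments)
  projections <- project_all(cores, alignments)
  g <- build_overlap_graph(cores, projections,
                           min_overlap = params$minOverlapReads,
                           match_n = match_n)
  g <- break_cycles(g)
  removed <- attr(g, "removed_edges")
  contigs <- extract_contigs(g, params)
  n_candidates <- attr(contigs, "n_candidates")
  contained <- find_containments(contigs, params$minPercentIdentityContigs)
  kept <- Filter(function(x) !(x$id %in% contained), contigs)
  h <- build_contig_graph(kept,
                          min_overlap = params$minOverlapContigs,
                          min_identity = params$minPercentIdentityContigs)
  merged <- merge_contigs(h, params)
  stats <- c(stats, list(
    reads_aligned = length(cores),
    nodes = length(cores),
    edges = nrow(g$edges) + nrow(removed),
    cycles_broken = nrow(removed),
    contigs_candidates = n_candidates,
    contigs_filtered = length(contigs),
    contained_removed = length(contained),
    contigs_merged = length(kept) - length(merged),
    final_contigs = length(merged)
  ))
  list(contigs = merged, graph = g, stats = stats)
}

#' Run an assembly from files to files
#'
#' File-level wrapper around [assemble()]: reads a FASTA read set and a
#' tabular alignment file, checks that every aligned read is present in the
#' read set, assembles, and writes the contigs as FASTA. A one-line-per-
#' count summary is printed to standard error unless `quiet = TRUE`.
#'
#' @param reads_path FASTA file of reads.
#' @param alignments_path tabular protein-alignment file.
#' @param out_path output FASTA file for contigs.
#' @param params an [assembly_params()] object.
#' @param permissive passed to [parse_alignments()].
#' @param match_n passed to [assemble()].
#' @param dump_graph optional path: write the de-cycled overlap graph in
#'   GraphViz DOT format.
#' @param quiet suppress the summary on standard error.
#' @return invisibly, the [assemble()] result.
#' @export
run_assembly <- function(reads_path, alignments_path, out_path,
                         params = assembly_params(), permissive = FALSE,
                         match_n = FALSE, dump_graph = NULL, quiet = FALSE) {
  reads <- read_fasta(reads_path)
  alignments <- parse_alignments(alignments_path, permissive = permissive)
  missing <- setdiff(unique(alignments$read_id), names(reads))
  if (length(missing)) {
    stop("alignment read id(s) absent from the read set: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  res <- assemble(reads, alignments, params = params, match_n = match_n)
  write_contigs(res$contigs, out_path)
  if (!is.null(dump_graph) && !is.null(res$graph)) {
    dump_graph_dot(res$graph, dump_graph)
  }
  if (!quiet) {
    for (nm in names(res$stats)) {
      message(sprintf("%-20s %d", nm, res$stats[[nm]]))
    }
  }
  invisible(res)
}
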