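#' Assembly parameters
#'
#' Bundles the thresholds that control the two assembly stages. All length
#' and count thresholds are applied as inclusive lower bounds (`>=`).
#'
#' @param minOverlapReads minimum induced DNA overlap (nt) between two reads
#'   for an overlap-graph edge. Default 20.
#' @param minReads minimum number of reads in a reported contig. Default 2,
#'   which discards single-read contigs.
#' @param minLength minimum contig length (nt). Default 200.
#' @param minAvCoverage minimum average coverage of a contig, defined as the
#'   summed length of its member cores divided by the contig length.
#'   Default 0 (filter inactive).
#' @param minOverlapContigs minimum suffix-prefix overlap (nt) between two
#'   contigs for a contig-graph edge. Default 20.
#' @param minPercentIdentityContigs minimum percent identity at which contigs
#'   are deemed to overlap or to be contained, in (0, 100]. Default 98.
#' @return an object of class `assembly_params`.
#' @examples
#' assembly_params(minLength = 300)
#' @export
assembly_params <- function(minOverlapReads = 20L,
                            minReads = 2L,
                            minLength = 200L,
                            minAvCoverage = 0,
                            minOverlapContigs = 20L,
                            minPercentIdentityContigs = 98) {
  p <- list(
    minOverlapReads = as.integer(minOverlapReads),
    minReads = as.integer(minReads),
    minLength = as.integer(minLength),
    minAvCoverage = as.numeric(minAvCoverage),
    minOverlapContigs = as.integer(minOverlapContigs),
    minPercentIdentityContigs = as.numeric(minPercentIdentityContigs)
  )
  stopifnot(
    p$minOverlapReads >= 1L, p$minReads >= 0L, p$minLength >= 0L,
    p$minAvCoverage >= 0, p$minOverlapContigs >= 1L,
    p$minPercentIdentityContigs > 0, p$minPercentIdentityContigs <= 100
  )
  structure(p, class = "assembly_params")
}

#' @export
print.assembly_params <- function(x, ...) {
  cat("assembly parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
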