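test_that("gene family generation respects length and divergence settings", {
  spec0 <- simulation_spec(gene_length_nt = 999, n_references = 4,
                           reference_divergence = 0, seed = 60)
  fam0 <- make_gene_family(spec0)
  expect_equal(nchar(fam0$gene), 999)
  expect_equal(unname(nchar(fam0$references)), rep(333L, 4))
  expect_true(all(fam0$references == fam0$references[1]))
  expect_false(grepl("\\*", fam0$references[1]))   # no internal stops

  # substituted-site counts behave binomially at 5% over many seeds
  n_sites <- 333L
  subs <- vapply(1:60, function(s) {
    fam <- make_gene_family(simulation_spec(reference_divergence = 0.05,
                                            n_references = 2, seed = 1000 + s))
    sum(.as_raw_chars(fam$references[1]) != .as_raw_chars(fam$references[2]))
  }, numeric(1))
  total <- sum(subs)
  bounds <- qbinom(c(0.0005, 0.9995), 60L * n_sites, 0.05)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("reads tile the gene with the expected overlaps", {
  spec <- simulation_spec(gene_length_nt = 999, read_length = 101,
                          tiling_step = 50, strand_flip_prob = 0,
                          substitution_rate = 0, seed = 61)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec)
  expect_length(reads, 19)
  org <- read_origin(names(reads))
  expect_equal(org$start, c(seq(0, 850, by = 50), 898))
  overlaps <- 101 - diff(org$start)
  expect_equal(overlaps, c(rep(51, 17), 53))
  # error-free unflipped reads are exact gene substrings
  for (k in seq_along(reads)) {
    expect_equal(unname(reads[k]),
                 substr(fam$gene, org$start[k] + 1, org$start[k] + 101))
  }
})

test_that("read errors and strand flips occur at the configured rates", {
  spec <- simulation_spec(substitution_rate = 0.01, strand_flip_prob = 0.5,
                          seed = 62)
  fam <- make_gene_family(spec)
  total_mm <- 0L
  total_nt <- 0L
  flips <- 0L
  n_reads <- 0L
  for (s in 1:30) {
    sp <- simulation_spec(substitution_rate = 0.01, strand_flip_prob = 0.5,
                          seed = 2000 + s)
    reads <- simulate_reads(fam$gene, sp)
    org <- read_origin(names(reads))
    for (k in seq_along(reads)) {
      truth <- substr(fam$gene, org$start[k] + 1, org$start[k] + 101)
      obs <- if (org$strand[k] == "r") revcomp(reads[[k]]) else reads[[k]]
      total_mm <- total_mm + sum(.as_raw_chars(obs) != .as_raw_chars(truth))
      total_nt <- total_nt + 101L
    }
    flips <- flips + sum(org$strand == "r")
    n_reads <- n_reads + length(reads)
  }
  mm_bounds <- qbinom(c(0.0005, 0.9995), total_nt, 0.01)
  expect_gte(total_mm, mm_bounds[1])
  expect_lte(total_mm, mm_bounds[2])
  flip_bounds <- qbinom(c(0.0005, 0.9995), n_reads, 0.5)
  expect_gte(flips, flip_bounds[1])
  expect_lte(flips, flip_bounds[2])
})

test_that("simulated alignment records satisfy every record invariant", {
  spec <- simulation_spec(seed = 63, strand_flip_prob = 0.5,
                          substitution_rate = 0.02)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec)
  alns <- simulate_alignments(reads, fam$references, spec)
  expect_equal(nrow(alns), length(reads) * length(fam$references))
  for (i in seq_len(nrow(alns))) {
    r <- as.list(alns[i, ])
    expect_equal(nchar(r$q_aln), nchar(r$s_aln))
    expect_false(grepl("-", r$q_aln, fixed = TRUE))
    expect_equal(3L * nchar(r$q_aln), r$read_end - r$read_start)
    expect_equal(nchar(r$s_aln), r$ref_end - r$ref_start)
    expect_true(r$frame %in% c(-3:-1, 1:3))
    expect_gte(r$read_start, 0)
    expect_lte(r$read_end, nchar(reads[[r$read_id]]))
  }
})

test_that("a read error produces exactly one amino-acid mismatch column", {
  spec <- simulation_spec(strand_flip_prob = 0, substitution_rate = 0,
                          seed = 64)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec)[1]
  # plant one substitution mid-read, inside a whole codon of frame +1
  mutated <- reads
  old <- substr(mutated[[1]], 50, 50)
  new <- setdiff(c("A", "C", "G", "T"), old)
  hit <- FALSE
  for (nb in new) {                              # avoid a synonymous change
    cand <- mutated
    substr(cand[[1]], 50, 50) <- nb
    a <- simulate_alignments(cand, fam$references[1], spec)
    mm <- sum(.as_raw_chars(a$q_aln) != .as_raw_chars(a$s_aln))
    if (mm == 1) { hit <- TRUE; break }
  }
  expect_true(hit)
})

test_that("negative-frame records reproduce the core translation", {
  spec <- simulation_spec(strand_flip_prob = 1, substitution_rate = 0,
                          seed = 65)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec)
  alns <- simulate_alignments(reads, fam$references, spec)
  expect_true(all(alns$frame < 0))
  cores <- compute_cores(reads, alns)
  for (core in cores) {
    def <- alns[alns$read_id == core$read_id & alns$ref_id == core$ref_id, ][1, ]
    expect_equal(translate_dna(core$seq), def$q_aln)
  }
})

test_that("error-free consecutive reads recover exactly the true overlap", {
  spec <- simulation_spec(strand_flip_prob = 0.5, substitution_rate = 0,
                          reference_divergence = 0, seed = 66)
  fam <- make_gene_family(spec)
  reads <- simulate_reads(fam$gene, spec)
  alns <- simulate_alignments(reads, fam$references, spec)
  cores <- compute_cores(reads, alns)
  ps <- project_all(cores, alns)
  idx <- index_by_reference(ps)
  org <- read_origin(names(reads))
  ord <- order(org$start)
  for (k in seq_len(length(reads) - 1)) {
    id_a <- org$id[ord[k]]; id_b <- org$id[ord[k + 1]]
    pa <- Filter(function(p) p$core_id == id_a, idx$ref_1)[[1]]
    pb <- Filter(function(p) p$core_id == id_b, idx$ref_1)[[1]]
    e <- induce_overlap(pa, pb, cores)
    s_a <- org$start[ord[k]]; s_b <- org$start[ord[k + 1]]
    a1 <- floor((s_a + 101) / 3) * 3             # end of a's codon-trimmed core
    b0 <- ceiling(s_b / 3) * 3                   # start of b's codon-trimmed core
    expect_equal(e$weight, a1 - b0)
  }
})

test_that("write_fixture produces parseable, consistent files", {
  dir <- withr::local_tempdir()
  fx <- write_fixture(dir, simulation_spec(seed = 67))
  reads <- read_fasta(fx$paths$reads)
  expect_identical(reads, fx$reads)
  alns <- parse_alignments(fx$paths$alignments)
  expect_equal(alns, fx$alignments, tolerance = 1e-12)
  truth <- utils::read.delim(fx$paths$truth)
  expect_equal(nrow(truth), length(reads))
})
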