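test_that("generated reference has the requested CpG density, genes and islands", {
  g <- generate_reference(n_contigs = 1, contig_length = 50000,
                          cpg_density = 0.02, n_genes = 10, n_islands = 5,
                          seed = 1)
  fa <- tempfile(fileext = ".fa")
  write_reference_fasta(g$reference, fa)
  seq <- paste(readLines(fa)[-1], collapse = "")
  n_cpg <- length(gregexpr("(?=CG)", seq, perl = TRUE)[[1]])
  expected <- 0.02 * 50000
  tol <- 3 * sqrt(50000 * 0.02 * 0.98)
  expect_gt(n_cpg, expected - tol)
  expect_lt(n_cpg, expected + tol)
  expect_identical(nrow(g$annotation$genes), 10L)
  expect_identical(nrow(g$annotation$cpg_islands), 5L)
  # stored sites agree with a direct string scan and satisfy the dinucleotide
  # invariant
  scan <- as.integer(gregexpr("(?=CG)", seq, perl = TRUE)[[1]]) - 1L
  expect_identical(g$reference$cpg_sites[["ctg1"]], scan)
  # islands really are locally enriched
  isl <- g$annotation$cpg_islands
  in_isl <- sum(vapply(seq_len(nrow(isl)), function(i) {
    sum(scan >= isl$start[i] & scan < isl$end[i])
  }, 0L))
  isl_area <- sum(isl$end - isl$start)
  expect_gt(in_isl / isl_area, 2 * (n_cpg - in_isl) / (50000 - isl_area))
})

test_that("reference generation rejects bad sizing and zero density", {
  expect_error(generate_reference(cpg_density = 0), "density")
  expect_error(generate_reference(contig_length = 4000), "contig_length")
  expect_error(generate_reference(n_contigs = 1, contig_length = 5000,
                                  n_genes = 50, n_islands = 0), "sizing")
})

test_that("reference generation is byte-identical under a fixed seed", {
  paths <- replicate(2, {
    g <- generate_reference(n_contigs = 1, contig_length = 10000,
                            n_genes = 2, n_islands = 2, seed = 7)
    fa <- tempfile(fileext = ".fa")
    gtf <- tempfile(fileext = ".gtf")
    bed <- tempfile(fileext = ".bed")
    write_reference_fasta(g$reference, fa)
    write_annotation(g$annotation, gtf, bed)
    c(fa, gtf, bed)
  })
  for (k in 1:3) {
    expect_identical(readLines(paths[k, 1]), readLines(paths[k, 2]))
  }
})

test_that("methylomes carry planted fold effects and are null outside them", {
  g <- generate_reference(n_contigs = 1, contig_length = 20000, n_genes = 3,
                          n_islands = 2, seed = 2)
  ref <- g$reference
  p <- ref$cpg_sites[["ctg1"]]
  dmr <- data.frame(contig = "ctg1", start = p[10], end = p[40] + 2, fold = 2)
  mm <- generate_methylomes(ref, n_pairs = 27, dmr_spec = dmr,
                            baseline_beta_params = c(3, 7), seed = 3)
  expect_length(mm$profiles, 54L)
  groups <- vapply(mm$profiles, function(x) x$group, "")
  expect_identical(sum(groups == "primary"), 27L)
  lev <- vapply(mm$profiles, function(x) x$levels[["ctg1"]], numeric(length(p)))
  inside <- p >= dmr$start & p < dmr$end
  m_prim <- rowMeans(lev[, groups == "primary"])
  m_rec <- rowMeans(lev[, groups == "recurrent"])
  # planted interval: recurrent ~ 2x primary (baseline mean 0.3)
  expect_equal(mean(m_rec[inside]) / mean(m_prim[inside]), 2, tolerance = 0.1)
  # outside: groups indistinguishable
  expect_equal(mean(m_rec[!inside]), mean(m_prim[!inside]), tolerance = 0.02)
  expect_true(all(lev >= 0 & lev <= 1))
  expect_error(
    generate_methylomes(ref, 2, data.frame(contig = "ctgZ", start = 0,
                                           end = 10, fold = 2)),
    "annotation error")
  expect_error(
    generate_methylomes(ref, 2, data.frame(contig = "ctg1", start = 0,
                                           end = 10, fold = -1)),
    "fold")
})

test_that("a unit fold effect leaves group means equal everywhere", {
  g <- generate_reference(n_contigs = 1, contig_length = 10000, n_genes = 2,
                          n_islands = 1, seed = 5)
  dmr <- data.frame(contig = "ctg1", start = 0, end = 10000, fold = 1)
  mm <- generate_methylomes(g$reference, n_pairs = 30, dmr_spec = dmr, seed = 6)
  groups <- vapply(mm$profiles, function(x) x$group, "")
  lev <- vapply(mm$profiles, function(x) x$levels[["ctg1"]],
                numeric(length(g$reference$cpg_sites[["ctg1"]])))
  expect_equal(mean(rowMeans(lev[, groups == "recurrent"])),
               mean(rowMeans(lev[, groups == "primary"])), tolerance = 0.01)
})

test_that("simulated reads respect the positional window and Poisson depth", {
  g <- generate_reference(n_contigs = 1, contig_length = 10000, n_genes = 2,
                          n_islands = 1, seed = 8)
  ref <- g$reference
  # fully methylated single-site profile
  m0 <- lapply(ref$cpg_sites, function(p) rep(0, length(p)))
  prof0 <- structure(list(sample_id = "z", group = "primary", levels = m0),
                     class = "methylation_profile")
  empty <- simulate_medseq_reads(prof0, ref, mean_depth = 10,
                                 background_fraction = 0, seed = 9)
  expect_identical(nrow(empty$reads), 0L)

  m1 <- m0
  m1[["ctg1"]][25] <- 1
  prof1 <- structure(list(sample_id = "o", group = "primary", levels = m1),
                     class = "methylation_profile")
  counts <- vapply(1:30, function(s) {
    nrow(simulate_medseq_reads(prof1, ref, mean_depth = 10,
                               background_fraction = 0, seed = s)$reads)
  }, 0L)
  expect_equal(mean(counts), 10, tolerance = 0.2 * 10)
  rs <- simulate_medseq_reads(prof1, ref, mean_depth = 10,
                              background_fraction = 0, seed = 10)
  expect_true(all(vapply(rs$reads$sequence, filter_oracle, TRUE)))

  fq <- replicate(2, {
    path <- tempfile(fileext = ".fastq")
    write_fastq(simulate_medseq_reads(prof1, ref, mean_depth = 10,
                                      seed = 11)$reads, path)
    path
  })
  expect_identical(readLines(fq[1]), readLines(fq[2]))
})

test_that("Ct matrices carry batch offsets, censoring and pairing", {
  sim <- generate_ct_matrix(n_mirnas = 300, n_pairs = 12, n_batches = 3,
                            batch_spec = list(offsets = c(0, 3, 0)),
                            detect_ct_max = Inf, noise_sd = 0.5, seed = 4)
  expect_false(anyNA(sim$ct$ct))
  mean_b <- tapply(colMeans(sim$ct$ct), sim$ct$batch, mean)
  expect_equal(unname(mean_b["b2"] - mean_b["b1"]), 3, tolerance = 0.3)
  # paired samples share a batch by construction (validated in ct_matrix)
  expect_s3_class(sim$ct, "ct_matrix")
  expect_error(generate_ct_matrix(n_mirnas = 10, n_pairs = 2, n_batches = 3),
               "sizing")
  # round-trip through the TSV writer preserves values and metadata
  p <- tempfile(fileext = ".tsv")
  write_ct_matrix(sim$ct, p)
  back <- read_ct_matrix(p)
  expect_equal(back$ct, sim$ct$ct, tolerance = 1e-8)
  expect_identical(unname(back$batch), unname(sim$ct$batch))
})

test_that("clinical tables are internally consistent and deterministic", {
  cl <- generate_clinical(n_pairs = 27, seed = 12)
  expect_identical(nrow(cl), 27L)
  expect_true(all(cl$age_recurrent - cl$age_primary ==
                    round(cl$time_to_recurrence)))
  expect_true(all(cl$margin_primary %in% c("R0", "R1", "R2", "Rx")))
  expect_identical(cl, generate_clinical(n_pairs = 27, seed = 12))
  expect_error(generate_clinical(0), "sizing")
  # same schema as the packaged fixture
  fixture <- read_clinical(clinical_fixture_path())
  expect_true(all(setdiff(names(fixture), "dmr_count") %in% names(cl)))
})
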