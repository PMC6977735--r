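test_that("the 2x2 chi-square matches the textbook oracle and chisq.test", {
  set.seed(41)
  for (rep in 1:50) {
    ta <- sample(100:5000, 1)
    tb <- sample(100:5000, 1)
    a <- sample(0:ta, 1)
    b <- sample(0:tb, 1)
    got <- chi2_counts_test(a, ta, b, tb)
    want <- chi2_table_oracle(a, ta, b, tb)
    expect_equal(got$chi2_stat, want$chi2, tolerance = 1e-10)
    expect_equal(got$p_raw, want$p, tolerance = 1e-10)
    if (a > 0 && b > 0 && a < ta && b < tb) {
      ct <- suppressWarnings(
        chisq.test(matrix(c(a, ta - a, b, tb - b), 2, byrow = TRUE),
                   correct = FALSE))
      expect_equal(got$chi2_stat, unname(ct$statistic), tolerance = 1e-10)
    }
  }
})

test_that("chi-square edge cases: equal proportions, empty margins, errors", {
  r <- chi2_counts_test(10, 1000, 10, 1000)
  expect_equal(r$chi2_stat, 0)
  expect_equal(r$p_raw, 1)
  expect_equal(r$fold_change, 1)
  r0 <- chi2_counts_test(0, 100, 0, 100)
  expect_equal(r0$chi2_stat, 0)
  expect_equal(r0$fold_change, 1)
  expect_error(chi2_counts_test(1, 0, 1, 10), "degenerate")
  expect_error(chi2_counts_test(11, 10, 1, 10), "count")
})

test_that("swapping the groups preserves chi-square and inverts the fold", {
  set.seed(42)
  for (rep in 1:20) {
    t0 <- sample(500:2000, 1)
    a <- sample(0:t0, 1)
    b <- sample(0:t0, 1)
    f <- chi2_counts_test(a, t0, b, t0)
    r <- chi2_counts_test(b, t0, a, t0)
    expect_equal(f$chi2_stat, r$chi2_stat, tolerance = 1e-12)
    expect_equal(f$fold_change, 1 / r$fold_change, tolerance = 1e-12)
  }
})

test_that("p-value adjustment reproduces the hand step-up and scalar cases", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(c(0.3, 0.4), "bonferroni"), c(0.6, 0.8))
  set.seed(43)
  for (rep in 1:10) {
    p <- runif(sample(2:10, 1))
    expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # permutation invariance: adjusting a permuted vector permutes the output
  p <- c(0.001, 0.2, 0.04, 0.7, 0.03)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(adjust_pvalues(p, "BH")[perm], adjust_pvalues(p[perm], "BH"))
})

region_matrix_fixture <- function(effect_region = NULL, fold = 1, seed = 44) {
  set.seed(seed)
  regions <- build_regions(gene_annotation(
    data.frame(gene_id = character(0), contig = character(0),
               strand = character(0), tss = integer(0), tes = integer(0)),
    data.frame(island_id = sprintf("i%d", 1:40), contig = "ctgA",
               start = seq(0L, 3900L, by = 100L),
               end = seq(100L, 4000L, by = 100L))))
  n_s <- 6
  counts <- matrix(rpois(40 * 2 * n_s, 50), nrow = 40)
  colnames(counts) <- sprintf("s%d", 1:(2 * n_s))
  if (!is.null(effect_region)) {
    counts[effect_region, (n_s + 1):(2 * n_s)] <-
      rpois(n_s, 50 * fold)
  }
  structure(list(counts = counts, regions = regions,
                 library_totals = setNames(rep(50 * 40, 2 * n_s),
                                           colnames(counts))),
            class = "region_count_matrix")
}

test_that("region DMR calling recovers a strong planted region and respects min_fc", {
  rm <- region_matrix_fixture(effect_region = 7, fold = 4)
  labels <- rep(c("primary", "recurrent"), each = 6)
  dmrs <- call_region_dmrs(rm, labels, method = "BH", alpha = 0.05,
                           min_fc = 1.5)
  expect_true("CpG-island:i7" %in% dmrs$region_id)
  expect_identical(dmrs$direction[dmrs$region_id == "CpG-island:i7"], "hyper")
  # neutral threshold: min_fc = 1 reduces to significance only
  d1 <- call_region_dmrs(rm, labels, min_fc = 1)
  d0 <- call_region_dmrs(rm, labels, min_fc = 1e9)
  expect_gte(nrow(d1), nrow(dmrs))
  expect_identical(nrow(d0), 0L)
})

test_that("null region matrices rarely yield adjusted discoveries", {
  rm <- region_matrix_fixture()
  labels <- rep(c("primary", "recurrent"), each = 6)
  expect_identical(nrow(call_region_dmrs(rm, labels, min_fc = 1)), 0L)
})

# Hand-built tracks: two groups of 2 samples with per-site counts set so the
# significance pattern is controlled exactly.
two_group_tracks <- function(counts_a, counts_b, pos, total = 1e5) {
  c(lapply(1:2, function(i) make_track(paste0("p", i), "ctgA", pos,
                                       counts_a, total = total)),
    lapply(1:2, function(i) make_track(paste0("r", i), "ctgA", pos,
                                       counts_b, total = total)))
}

test_that("adjacent significant sites with opposite direction are never merged", {
  pos <- c(100L, 110L, 120L, 130L)
  tracks <- two_group_tracks(c(500, 500, 50, 50), c(50, 50, 500, 500), pos)
  labels <- c("primary", "primary", "recurrent", "recurrent")
  dmrs <- sliding_window_dmrs(tracks, labels, min_sites = 1, min_size_bp = 1,
                              min_fc = 1, max_gap = 0)
  expect_identical(nrow(dmrs), 2L)
  expect_setequal(dmrs$direction, c("hyper", "hypo"))
})

test_that("with unit thresholds significant sites are partitioned exactly", {
  set.seed(45)
  pos <- sort(sample(0:20000, 300))
  base <- rpois(300, 40)
  up <- base
  bump <- sample(300, 60)
  up[bump] <- rpois(60, 160)
  tracks <- two_group_tracks(base, up, pos)
  labels <- c("primary", "primary", "recurrent", "recurrent")
  dmrs <- sliding_window_dmrs(tracks, labels, min_sites = 1, min_size_bp = 1,
                              min_fc = 1, max_gap = 0)
  # independent recomputation of the per-site significance set
  res <- chi2_counts_test(2 * base, 2e5, 2 * up, 2e5)
  sig <- adjust_pvalues(res$p_raw, "BH") < 0.05 & res$fold_change != 1
  expect_identical(sum(dmrs$n_sites), sum(sig))
  # every significant site lies in exactly one reported DMR
  hits <- vapply(pos[sig], function(p) {
    sum(p >= dmrs$start & p < dmrs$end)
  }, 0L)
  expect_true(all(hits == 1L))
})

test_that("raising alpha never reduces the number of significant sites", {
  set.seed(46)
  pos <- sort(sample(0:5000, 100))
  a <- rpois(100, 30)
  b <- rpois(100, 45)
  tracks <- two_group_tracks(a, b, pos, total = 2e4)
  labels <- c("primary", "primary", "recurrent", "recurrent")
  n_sig <- vapply(c(0.01, 0.05, 0.2, 0.5), function(alpha) {
    sum(sliding_window_dmrs(tracks, labels, alpha = alpha, min_sites = 1,
                            min_size_bp = 1, min_fc = 1)$n_sites)
  }, 0)
  expect_true(all(diff(n_sig) >= 0))
})

test_that("empty tracks give an empty DMR table, not an error", {
  expect_identical(nrow(sliding_window_dmrs(list(), c("primary", "recurrent"))), 0L)
})

test_that("DMR annotation equals the double-loop interval intersection", {
  regions <- build_regions(gene_annotation(
    data.frame(gene_id = c("g1", "g2"), contig = "ctgA", strand = c("+", "-"),
               tss = c(2000L, 7000L), tes = c(5000L, 3500L)),
    data.frame(island_id = "i1", contig = "ctgA", start = 1500L, end = 2500L)))
  # containment and exact-boundary cases
  dmr_in <- data.frame(contig = "ctgA", start = 1200L, end = 1400L)
  ann <- annotate_dmrs(dmr_in, regions)  # inside TSS:g1 ([1000, 3000))
  expect_true(grepl("TSS:g1", ann$overlaps))
  touch <- annotate_dmrs(data.frame(contig = "ctgA", start = 2500L,
                                    end = 2600L), regions)
  expect_false(grepl("CpG-island:i1", touch$overlaps))  # [1500,2500) excludes 2500
  set.seed(47)
  for (rep in 1:5) {
    dmrs <- data.frame(contig = "ctgA",
                       start = sample(0:9000, 20))
    dmrs$end <- dmrs$start + sample(50:2000, 20)
    got <- annotate_dmrs(dmrs, regions)
    for (k in seq_len(nrow(dmrs))) {
      want <- regions$region_id[regions$contig == "ctgA" &
                                  regions$start < dmrs$end[k] &
                                  dmrs$start[k] < regions$end]
      got_ids <- if (nzchar(got$overlaps[k])) {
        strsplit(got$overlaps[k], ";", fixed = TRUE)[[1]]
      } else character(0)
      expect_setequal(got_ids, want)
    }
  }
})
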