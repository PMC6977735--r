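ct_fixture <- function(ct, batch = NULL, detect_max = 35) {
  n <- ncol(ct)
  stopifnot(n %% 2 == 0)
  colnames(ct) <- as.vector(t(cbind(sprintf("P%02d.1", 1:(n / 2)),
                                    sprintf("P%02d.2", 1:(n / 2)))))
  if (is.null(batch)) batch <- rep("b1", n)
  ct_matrix(ct, batch = batch,
            pair = rep(sprintf("P%02d", 1:(n / 2)), each = 2),
            role = rep(c("primary", "recurrent"), n / 2))
}

test_that("median-Ct normalization matches the hand examples and is idempotent", {
  ct <- matrix(c(28, 30, 34, 30, 30, 30), nrow = 3,
               dimnames = list(c("mA", "mB", "mC"), NULL))
  x <- ct_fixture(ct)
  ex <- normalize_ct(x)
  expect_equal(unname(ex$expr[, 1]), c(2, 0, -4))
  expect_equal(unname(ex$expr[, 2]), c(0, 0, 0))
  # per-sample median of detectable values is 0 by construction
  expect_equal(unname(apply(ex$expr, 2, median, na.rm = TRUE)), c(0, 0))
  # renormalizing the normalized values (as pseudo-Ct) is a no-op
  renorm <- normalize_ct(ct_fixture(-ex$expr, detect_max = 35))
  expect_equal(renorm$expr, ex$expr)
})

test_that("censoring above the detection cutoff and empty samples error", {
  ct <- matrix(c(30, 36, 30, 30), nrow = 2,
               dimnames = list(c("mA", "mB"), NULL))
  ex <- normalize_ct(ct_fixture(ct), detect_ct_max = 35)
  expect_true(is.na(ex$expr["mB", 1]))
  all_high <- matrix(40, 2, 2, dimnames = list(c("mA", "mB"), NULL))
  expect_error(normalize_ct(ct_fixture(all_high)), "sample-quality")
})

test_that("detection filtering is boundary-inclusive over all samples", {
  m <- matrix(rnorm(3 * 26), nrow = 3,
              dimnames = list(c("m13", "m12", "m26"), NULL))
  m["m13", 1:13] <- NA   # detected in 13/26
  m["m12", 1:14] <- NA   # detected in 12/26
  ex <- ct_fixture(matrix(30, 3, 26, dimnames = dimnames(m)))
  ex <- normalize_ct(ex)
  ex$expr <- m
  kept <- detection_filter(ex, 0.5)
  expect_setequal(rownames(kept$expr), c("m13", "m26"))
  strict <- detection_filter(ex, 1)
  expect_identical(rownames(strict$expr), "m26")
})

test_that("location-scale batch adjustment equalizes planted batch means", {
  sim <- generate_ct_matrix(n_mirnas = 120, n_pairs = 12, n_batches = 3,
                            batch_spec = list(offsets = c(0, 3, 0)),
                            detect_ct_max = Inf, noise_sd = 0.5, seed = 51)
  ex <- suppressWarnings(batch_adjust(normalize_ct(sim$ct, detect_ct_max = Inf)))
  for (i in sample(nrow(ex$expr), 20)) {
    means <- tapply(ex$expr[i, ], ex$batch, mean)
    expect_lt(max(means) - min(means), 1e-6)
  }
})

test_that("batch adjustment is a near no-op without batch structure", {
  sim <- generate_ct_matrix(n_mirnas = 60, n_pairs = 10, n_batches = 2,
                            batch_spec = list(offsets = c(0, 0)),
                            detect_ct_max = Inf, seed = 52)
  ex <- normalize_ct(sim$ct, detect_ct_max = Inf)
  adj <- suppressWarnings(batch_adjust(ex))
  expect_equal(adj$expr, ex$expr, tolerance = 0.5)
  # a single batch returns the input unchanged
  one <- ex
  one$batch[] <- "b1"
  expect_identical(batch_adjust(one)$expr, one$expr)
})

test_that("the paired t-test matches the explicit formula oracle", {
  d <- c(0.8, 1.2, 1.0, 0.9, 1.1)
  expr <- matrix(0, nrow = 1, ncol = 10,
                 dimnames = list("mX", NULL))
  expr[1, seq(2, 10, by = 2)] <- d  # recurrent minus primary = d
  x <- ct_fixture(matrix(30, 1, 10, dimnames = dimnames(expr)))
  ex <- normalize_ct(x)
  colnames(expr) <- colnames(ex$expr)
  ex$expr <- expr
  res <- paired_de(ex, min_pairs = 2)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$t_stat, 14.1421356, tolerance = 1e-6)
  expect_equal(res$p_two_sided, 2 * pt(-t_hand, df = 4), tolerance = 1e-12)
  expect_equal(res$mean_diff, 1.0)
  expect_equal(res$n_pairs_used, 5)
})

test_that("degenerate paired differences are flagged as specified", {
  expr <- matrix(0, nrow = 2, ncol = 12, dimnames = list(c("one", "zero"), NULL))
  expr["one", seq(2, 12, by = 2)] <- 1  # d = (1,1,1,1,1,1)
  x <- ct_fixture(matrix(30, 2, 12, dimnames = dimnames(expr)))
  ex <- normalize_ct(x)
  colnames(expr) <- colnames(ex$expr)
  ex$expr <- expr
  res <- paired_de(ex, min_pairs = 2)
  expect_equal(res$p_two_sided[res$mirna == "one"], 0)
  expect_identical(res$flag[res$mirna == "one"], "zero_variance")
  expect_equal(res$p_two_sided[res$mirna == "zero"], 1)
  expect_identical(res$flag[res$mirna == "zero"], "constant")
})

test_that("paired testing is invariant to sample column order", {
  sim <- generate_ct_matrix(n_mirnas = 50, n_pairs = 8, n_batches = 2, seed = 53)
  ex <- normalize_ct(sim$ct)
  set.seed(55)
  perm <- sample(ncol(ex$expr))
  ex2 <- ex
  ex2$expr <- ex$expr[, perm]
  ex2$batch <- ex$batch[perm]
  ex2$pair <- ex$pair[perm]
  ex2$role <- ex$role[perm]
  r1 <- paired_de(ex)
  r2 <- paired_de(ex2)
  expect_equal(r1$t_stat, r2$t_stat)
  expect_equal(r1$q_BH, r2$q_BH)
})

test_that("miRNAs below the pair minimum are reported untested", {
  expr <- matrix(NA_real_, nrow = 1, ncol = 12, dimnames = list("sparse", NULL))
  expr[1, 1:4] <- c(1, 2, 1, 2)  # two complete pairs only
  x <- ct_fixture(matrix(30, 1, 12, dimnames = dimnames(expr)))
  ex <- normalize_ct(x)
  colnames(expr) <- colnames(ex$expr)
  ex$expr <- expr
  res <- paired_de(ex, min_pairs = 5)
  expect_true(is.na(res$p_two_sided))
  expect_false(res$significant)
})

test_that("planted paired shifts are recovered at the dual threshold", {
  # mixed-direction shifts: same-direction planting would bias the median
  # normalizer; observed FDR is the mean FDP over replicates
  sens <- fdp <- numeric(20)
  for (r in 1:20) {
    sim <- generate_ct_matrix(n_mirnas = 700, n_pairs = 26, n_batches = 3,
                              de_spec = data.frame(mirna = 1:30,
                                                   delta = rep(c(1.5, -1.5), 15)),
                              noise_sd = 1, seed = 530 + r)
    ex <- suppressWarnings(batch_adjust(detection_filter(normalize_ct(sim$ct))))
    de <- paired_de(ex)
    truth <- de$mirna %in% sim$truth$planted_de_mirnas$mirna
    sens[r] <- sum(de$significant & truth) / 30
    fdp[r] <- sum(de$significant & !truth) / max(1, sum(de$significant))
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdp), 0.25)
})

test_that("excluding a sample removes its pair mate too", {
  sim <- generate_ct_matrix(n_mirnas = 20, n_pairs = 5, n_batches = 2, seed = 54)
  ex <- normalize_ct(sim$ct)
  trimmed <- exclude_samples(ex, "P02.1")
  expect_false(any(c("P02.1", "P02.2") %in% colnames(trimmed$expr)))
  expect_identical(ncol(trimmed$expr), 8L)
})
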