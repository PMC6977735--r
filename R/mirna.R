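#' Normalize a Ct matrix to per-sample median Ct
#'
#' Entries above `detect_ct_max` (or already missing) become undetected.
#' Every remaining entry is expressed relative to the median Ct of all
#' detectable miRNAs in that sample: `value = -(Ct - median)`, which is
#' already log2 relative expression under qPCR doubling chemistry. By
#' construction the per-sample median of the normalized detectable values
#' is 0, and renormalizing is a no-op.
#'
#' @param x A [ct_matrix()].
#' @param detect_ct_max Detectability cutoff (default Ct <= 35, the TLDA
#'   convention).
#' @return An object of class `expression_matrix`: list(expr, batch, pair,
#'   role) with missing entries preserved as `NA`.
#' @export
normalize_ct <- function(x, detect_ct_max = 35) {
  ct <- x$ct
  ct[!is.na(ct) & ct > detect_ct_max] <- NA
  n_det <- colSums(!is.na(ct))
  if (any(n_det == 0L)) {
    stop(sprintf("sample-quality error: no detectable miRNAs in sample(s) %s",
                 paste(colnames(ct)[n_det == 0L], collapse = ", ")),
         call. = FALSE)
  }
  med <- apply(ct, 2L, stats::median, na.rm = TRUE)
  expr <- -sweep(ct, 2L, med, `-`)
  structure(list(expr = expr, batch = x$batch, pair = x$pair, role = x$role),
            class = "expression_matrix")
}

#' Filter miRNAs by detection fraction
#'
#' Retains miRNAs detected (non-missing) in at least `min_fraction` of all
#' samples (boundary inclusive; the conventional cutoff is 50%).
#'
#' @param expr An `expression_matrix`.
#' @param min_fraction Fraction in (0, 1].
#' @export
detection_filter <- function(expr, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must lie in (0, 1]", call. = FALSE)
  }
  keep <- rowMeans(!is.na(expr$expr)) >= min_fraction
  expr$expr <- expr$expr[keep, , drop = FALSE]
  expr
}

#' Adjust expression for batch effects
#'
#' Default `"location-scale"` mode: per miRNA and batch, available values
#' are centered and scaled to the batch mean/sd, then restored to the
#' miRNA's overall mean and sd — a deterministic, dependency-free
#' location-scale harmonization after which per-batch means of every miRNA
#' agree. Batches contributing fewer than two available values (or with zero
#' sd) for a miRNA are left unadjusted with a warning. `"combat"` mode
#' applies the empirical-Bayes ComBat model (via the sva package) to the
#' complete-case rows and falls back to location-scale for rows with missing
#' values. Missing entries are never imputed.
#'
#' @param expr An `expression_matrix`.
#' @param batch_labels Optional override of the stored batch labels.
#' @param method `"location-scale"` (default) or `"combat"`.
#' @export
batch_adjust <- function(expr, batch_labels = NULL,
                         method = c("location-scale", "combat")) {
  method <- match.arg(method)
  batch <- batch_labels %||% expr$batch
  m <- expr$expr
  if (length(unique(batch)) < 2L) return(expr)

  if (method == "combat") {
    if (!requireNamespace("sva", quietly = TRUE)) {
      stop("method 'combat' needs the sva package", call. = FALSE)
    }
    complete <- rowSums(is.na(m)) == 0L
    if (sum(complete) >= 2L) {
      m[complete, ] <- sva::ComBat(dat = m[complete, , drop = FALSE],
                                   batch = factor(batch))
    }
    rest <- location_scale_adjust(m[!complete, , drop = FALSE], batch)
    m[!complete, ] <- rest$m
    expr$expr <- m
    return(expr)
  }
  res <- location_scale_adjust(m, batch)
  if (res$n_skipped > 0L) {
    warning(sprintf("%d miRNA-batch cell(s) left unadjusted (fewer than 2 values or zero sd)",
                    res$n_skipped), call. = FALSE)
  }
  expr$expr <- res$m
  expr
}

location_scale_adjust <- function(m, batch) {
  n_skipped <- 0L
  if (!nrow(m)) return(list(m = m, n_skipped = 0L))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    out <- x
    for (b in unique(batch)) {
      idx <- which(batch == b & !is.na(x))
      if (length(idx) < 2L) {
        n_skipped <- n_skipped + (length(idx) > 0L)
        next
      }
      mb <- mean(x[idx])
      sb <- stats::sd(x[idx])
      if (sb == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      out[idx] <- mu + s * (x[idx] - mb) / sb
    }
    m[i, ] <- out
  }
  list(m = m, n_skipped = n_skipped)
}

#' Paired differential expression between primary and recurrent samples
#'
#' Per miRNA, paired differences d = recurrent - primary (log2 units) are
#' taken over the pairs where both values are present; `t = mean(d) /
#' (sd(d) / sqrt(n))` with a two-sided p from Student's t on n - 1 df.
#' miRNAs with fewer than `min_pairs` complete pairs are reported untested
#' (missing p). BH q-values are computed over the tested miRNAs, and a
#' miRNA is significant under the dual threshold p < alpha and q < fdr.
#' Degenerate cases: zero variance with nonzero mean gives p = 0 (flagged
#' `zero_variance`); all differences zero gives p = 1 (flagged `constant`).
#'
#' @param expr An `expression_matrix` (column metadata supplies the pairing
#'   unless `pair_map` is given).
#' @param pair_map Optional data.frame(pair_id, primary, recurrent) of
#'   sample column names.
#' @param alpha Two-sided p threshold (default 0.05).
#' @param fdr BH q threshold (default 0.25).
#' @param min_pairs Minimum complete pairs per miRNA (default 5).
#' @return data.frame(mirna, n_pairs_used, mean_diff, t_stat, p_two_sided,
#'   q_BH, significant, flag).
#' @export
paired_de <- function(expr, pair_map = NULL, alpha = 0.05, fdr = 0.25,
                      min_pairs = 5L) {
  if (is.null(pair_map)) {
    ids <- unique(expr$pair)
    pair_map <- data.frame(
      pair_id = ids,
      primary = vapply(ids, function(p) {
        names(expr$pair)[expr$pair == p & expr$role == "primary"]
      }, ""),
      recurrent = vapply(ids, function(p) {
        names(expr$pair)[expr$pair == p & expr$role == "recurrent"]
      }, ""))
  }
  m <- expr$expr
  d <- m[, pair_map$recurrent, drop = FALSE] - m[, pair_map$primary, drop = FALSE]
  n <- rowSums(!is.na(d))
  mean_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1L, stats::sd, na.rm = TRUE)
  t_stat <- mean_d / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  flag <- rep("", nrow(d))
  zero_var <- !is.na(sd_d) & sd_d == 0 & n >= 2L
  flag[zero_var & mean_d != 0] <- "zero_variance"
  p[zero_var & mean_d != 0] <- 0
  t_stat[zero_var & mean_d != 0] <- Inf * sign(mean_d[zero_var & mean_d != 0])
  flag[zero_var & mean_d == 0] <- "constant"
  p[zero_var & mean_d == 0] <- 1
  t_stat[zero_var & mean_d == 0] <- 0
  untested <- n < min_pairs
  p[untested] <- NA
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- adjust_pvalues(p[tested], "BH")
  out <- data.frame(
    mirna = rownames(m), n_pairs_used = unname(n), mean_diff = unname(mean_d),
    t_stat = unname(t_stat), p_two_sided = unname(p), q_BH = unname(q),
    significant = unname(tested & p < alpha & q < fdr), flag = flag)
  rownames(out) <- NULL
  out
}

#' Write paired differential expression results as TSV
#' @param de Result of [paired_de()].
#' @param path Output file.
#' @export
write_de_results <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples (and their pair mates) from an expression matrix
#'
#' Explicit exclusion list for quality-flagged samples; the pair mate of an
#' excluded sample is removed too so the pairing stays complete.
#' @param expr An `expression_matrix`.
#' @param samples Sample column names to exclude.
#' @export
exclude_samples <- function(expr, samples) {
  pairs_hit <- unique(expr$pair[names(expr$pair) %in% samples])
  drop <- names(expr$pair)[expr$pair %in% pairs_hit]
  keep <- setdiff(colnames(expr$expr), drop)
  expr$expr <- expr$expr[, keep, drop = FALSE]
  expr$batch <- expr$batch[keep]
  expr$pair <- expr$pair[keep]
  expr$role <- expr$role[keep]
  expr
}
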