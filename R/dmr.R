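#' Pearson chi-square test on read counts from two libraries
#'
#' Tests a 2x2 table `[[count_a, total_a - count_a], [count_b,
#' total_b - count_b]]` with the Pearson chi-square statistic (1 df, no
#' continuity correction). The fold change carries a +1 pseudocount in the
#' numerator counts so zero-count regions give finite, direction-preserving
#' ratios: `fold = ((count_b + 1) / total_b) / ((count_a + 1) / total_a)`.
#' Tables whose count margin is empty (both counts 0, or both equal their
#' totals) have statistic 0 and p 1. All arguments are vectorized.
#'
#' @param count_a,total_a Read count and library total of the reference
#'   (primary) group.
#' @param count_b,total_b Read count and library total of the comparison
#'   (recurrent) group.
#' @return data.frame(chi2_stat, p_raw, fold_change).
#' @export
chi2_counts_test <- function(count_a, total_a, count_b, total_b) {
  if (any(total_a <= 0) || any(total_b <= 0)) {
    stop("degenerate input: library totals must be > 0", call. = FALSE)
  }
  if (any(count_a < 0) || any(count_b < 0) || any(count_a > total_a) ||
      any(count_b > total_b)) {
    stop("counts must satisfy 0 <= count <= total", call. = FALSE)
  }
  count_a <- as.numeric(count_a); total_a <- as.numeric(total_a)
  count_b <- as.numeric(count_b); total_b <- as.numeric(total_b)
  a <- count_a; b <- total_a - count_a
  c_ <- count_b; d <- total_b - count_b
  n <- total_a + total_b
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fold <- ((count_b + 1) / total_b) / ((count_a + 1) / total_a)
  data.frame(chi2_stat = chi2, p_raw = p, fold_change = fold)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with monotone
#' enforcement; output order matches input order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"` (case-insensitive).
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(tolower(method[1]), c("bh", "bonferroni"))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

# Resolve group labels into a two-level factor with the reference group
# ("primary" when present, else the first label seen) first.
split_two_groups <- function(labels) {
  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  if ("primary" %in% lev) lev <- c("primary", setdiff(lev, "primary"))
  factor(as.character(labels), levels = lev)
}

#' Call DMRs per annotated region
#'
#' Pools read counts by summation within each group, tests every region with
#' [chi2_counts_test()] against the pooled library totals, adjusts p-values
#' across all tested regions, and returns regions passing both the
#' significance and the fold-change threshold (fold >= min_fc or
#' <= 1/min_fc, inclusive). Fold changes are recurrent over primary
#' (the non-reference over the reference group).
#'
#' @param region_matrix A `region_count_matrix` from [count_regions()].
#' @param group_labels One label per sample column (two groups; `"primary"`
#'   is taken as the reference when present).
#' @param method Multiple-testing method, `"BH"` or `"bonferroni"`.
#' @param alpha Adjusted significance level.
#' @param min_fc Fold-change threshold; 1 reduces to significance only.
#' @return data.frame of called DMRs with region metadata, statistics and
#'   adjusted p-values.
#' @export
call_region_dmrs <- function(region_matrix, group_labels, method = "BH",
                             alpha = 0.05, min_fc = 1.5) {
  grp <- split_two_groups(group_labels)
  counts <- region_matrix$counts
  if (length(grp) != ncol(counts)) {
    stop("one group label per sample column is required", call. = FALSE)
  }
  ca <- rowSums(counts[, grp == levels(grp)[1], drop = FALSE])
  cb <- rowSums(counts[, grp == levels(grp)[2], drop = FALSE])
  ta <- sum(region_matrix$library_totals[grp == levels(grp)[1]])
  tb <- sum(region_matrix$library_totals[grp == levels(grp)[2]])
  if (ta <= 0 || tb <= 0) {
    stop("degenerate input: a group has zero pooled library total", call. = FALSE)
  }
  res <- chi2_counts_test(ca, ta, cb, tb)
  p_adj <- adjust_pvalues(res$p_raw, method)
  keep <- p_adj < alpha &
    (res$fold_change >= min_fc | res$fold_change <= 1 / min_fc)
  r <- region_matrix$regions
  out <- data.frame(
    region_id = r$region_id, class = r$class, parent = r$parent,
    contig = r$contig, start = r$start, end = r$end,
    size_bp = r$end - r$start, n_sites = NA_integer_,
    fold_change = res$fold_change, chi2_stat = res$chi2_stat,
    p_raw = res$p_raw, p_adj = p_adj, adjust_method = method,
    direction = ifelse(res$fold_change > 1, "hyper", "hypo"))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide sliding-window DMR calling over LpnPI sites
#'
#' Each CpG/LpnPI site is tested with [chi2_counts_test()] on pooled group
#' counts against the pooled group library totals, site p-values are adjusted
#' by `method`, and neighboring significant sites sharing a direction
#' (hyper/hypo in the recurrent group) are binned into maximal runs allowing
#' at most `max_gap` intervening non-significant sites (an opposite-direction
#' significant site always ends a run). Each bin spans its first to last
#' significant site (plus the CpG dinucleotide), reports the number of
#' significant member sites, the span-pooled fold change and chi-square, and
#' the best member site's raw/adjusted p. Bins failing `min_sites`,
#' `min_size_bp` or `min_fc` are discarded; surviving DMRs are annotated for
#' region overlap when `regions` is supplied.
#'
#' @param tracks List of [site_count_track()] objects on one reference.
#' @param group_labels One label per track (two groups, `"primary"` the
#'   reference when present).
#' @param alpha Adjusted per-site significance level.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @param min_sites Minimum significant sites per DMR.
#' @param min_size_bp Minimum DMR span in bp.
#' @param min_fc Span fold-change threshold (inclusive, either direction).
#' @param max_gap Maximum intervening non-significant sites inside a run.
#' @param regions Optional `region_set` for overlap annotation.
#' @return data.frame of DMRs (possibly empty) with columns contig, start,
#'   end, n_sites, size_bp, fold_change, chi2_stat, p_raw, p_adj,
#'   adjust_method, direction, overlaps.
#' @export
sliding_window_dmrs <- function(tracks, group_labels, alpha = 0.05,
                                method = "BH", min_sites = 4L,
                                min_size_bp = 100L, min_fc = 1.5,
                                max_gap = 0L, regions = NULL) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      size_bp = integer(0), fold_change = numeric(0),
                      chi2_stat = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), adjust_method = character(0),
                      direction = character(0), overlaps = character(0))
  if (!length(tracks)) return(empty)
  grp <- split_two_groups(group_labels)
  sm <- track_site_matrix(tracks)
  if (!nrow(sm$sites)) return(empty)
  ca <- rowSums(sm$counts[, grp == levels(grp)[1], drop = FALSE])
  cb <- rowSums(sm$counts[, grp == levels(grp)[2], drop = FALSE])
  ta <- sum(sm$library_totals[grp == levels(grp)[1]])
  tb <- sum(sm$library_totals[grp == levels(grp)[2]])
  if (ta <= 0 || tb <= 0) {
    stop("degenerate input: a group has zero pooled library total", call. = FALSE)
  }
  res <- chi2_counts_test(ca, ta, cb, tb)
  p_adj <- adjust_pvalues(res$p_raw, method)
  sig <- p_adj < alpha & res$fold_change != 1
  dir <- ifelse(res$fold_change > 1, "hyper", "hypo")

  out <- list()
  for (ctg in unique(sm$sites$contig)) {
    rows <- which(sm$sites$contig == ctg)
    sidx <- rows[sig[rows]]
    if (!length(sidx)) next
    runs <- list()
    cur <- sidx[1]
    for (i in sidx[-1]) {
      prev <- cur[length(cur)]
      if (dir[i] == dir[cur[1]] && (i - prev - 1L) <= max_gap) {
        cur <- c(cur, i)
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- i
      }
    }
    runs[[length(runs) + 1L]] <- cur
    for (run in runs) {
      span <- run[1]:run[length(run)]          # member + intervening sites
      start <- sm$sites$pos[run[1]]
      end <- sm$sites$pos[run[length(run)]] + 2L
      pooled <- chi2_counts_test(sum(ca[span]), ta, sum(cb[span]), tb)
      best <- run[which.min(res$p_raw[run])]
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = start, end = end, n_sites = length(run),
        size_bp = end - start, fold_change = pooled$fold_change,
        chi2_stat = pooled$chi2_stat, p_raw = res$p_raw[best],
        p_adj = p_adj[best], adjust_method = method,
        direction = dir[run[1]], overlaps = "")
    }
  }
  dmrs <- do.call(rbind, out) %||% empty
  keep <- dmrs$n_sites >= min_sites & dmrs$size_bp >= min_size_bp &
    (dmrs$fold_change >= min_fc | dmrs$fold_change <= 1 / min_fc)
  dmrs <- dmrs[keep, , drop = FALSE]
  rownames(dmrs) <- NULL
  if (!is.null(regions) && nrow(dmrs)) dmrs <- annotate_dmrs(dmrs, regions)
  dmrs
}

#' Annotate DMRs with overlapping region classes
#'
#' Fills the `overlaps` column with every region (as `class:parent`) sharing
#' at least 1 bp with the DMR under the half-open convention, joined by ";".
#'
#' @param dmrs DMR data.frame with contig, start, end columns.
#' @param regions A `region_set`.
#' @export
annotate_dmrs <- function(dmrs, regions) {
  dmrs$overlaps <- ""
  for (ctg in unique(dmrs$contig)) {
    di <- which(dmrs$contig == ctg)
    ri <- which(regions$contig == ctg)
    if (!length(ri)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = dmrs$start[di] + 1L, end = dmrs$end[di]),
      IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri]))
    if (!length(ov)) next
    hits <- split(regions$region_id[ri[S4Vectors::to(ov)]],
                  S4Vectors::from(ov))
    for (k in names(hits)) {
      dmrs$overlaps[di[as.integer(k)]] <- paste(hits[[k]], collapse = ";")
    }
  }
  dmrs
}

#' Write DMRs as a BED-compatible TSV
#'
#' First six columns are BED6 (id `dmr_<i>`, score `-log10(p_adj)`, strand
#' "."), followed by n_sites, fold_change, chi2_stat, p_raw, p_adj, overlaps.
#' @param dmrs DMR data.frame.
#' @param path Output file.
#' @export
write_dmrs <- function(dmrs, path) {
  score <- round(-log10(pmax(dmrs$p_adj, .Machine$double.xmin)), 4)
  lines <- sprintf("%s\t%d\t%d\tdmr_%d\t%g\t.\t%d\t%.6g\t%.6g\t%.6g\t%.6g\t%s",
                   dmrs$contig, dmrs$start, dmrs$end, seq_len(nrow(dmrs)),
                   score, dmrs$n_sites, dmrs$fold_change, dmrs$chi2_stat,
                   dmrs$p_raw, dmrs$p_adj, dmrs$overlaps)
  writeLines(c(paste("#contig", "start", "end", "id", "score", "strand",
                     "n_sites", "fold_change", "chi2_stat", "p_raw", "p_adj",
                     "overlaps", sep = "\t"), lines), path)
  invisible(path)
}
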