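# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately re-derive each quantity from first
# principles so they share no code with the implementation under test.

# Textbook Pearson chi-square on a 2x2 table: sum over cells of (O - E)^2 / E
# with expectations from the margins.
chi2_table_oracle <- function(a, ta, b, tb) {
  O <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) return(list(chi2 = 0, p = 1))
  chi2 <- sum((O - E)^2 / E)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by its definition: p * m / rank, cumulative
# minimum from the largest p down, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# (n + 1)-rank quantile with linear interpolation, straight from the formula.
quantile6_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- q * (n + 1)
  h <- min(max(h, 1), n)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Double loop over sites x regions under the half-open convention.
region_count_oracle <- function(sites, counts, regions) {
  out <- matrix(0, nrow = nrow(regions), ncol = ncol(counts),
                dimnames = list(regions$region_id, colnames(counts)))
  for (r in seq_len(nrow(regions))) {
    for (s in seq_len(nrow(sites))) {
      if (sites$contig[s] == regions$contig[r] &&
          sites$pos[s] >= regions$start[r] && sites$pos[s] < regions$end[r]) {
        out[r, ] <- out[r, ] + counts[s, ]
      }
    }
  }
  out
}

# Per-read positional filter by exhaustive scan of every motif occurrence.
filter_oracle <- function(seq, motif = "CG", wmin = 13, wmax = 17) {
  L <- nchar(seq)
  if (L < wmax + nchar(motif)) return(FALSE)
  for (s in seq_len(L - nchar(motif) + 1)) {
    if (substr(seq, s, s + nchar(motif) - 1) == motif) {
      d3 <- L - (s + nchar(motif) - 1) + 1
      if ((s >= wmin && s <= wmax) || (d3 >= wmin && d3 <= wmax)) return(TRUE)
    }
  }
  FALSE
}

# A read of length L that is motif-free except for a CG planted at 1-based
# offset `at` (NA for none); the filler alternates A/T so no CG can arise.
read_with_cg_at <- function(at, L = 50) {
  filler <- rep(c("A", "T"), length.out = L)
  if (!is.na(at)) {
    filler[at] <- "C"
    filler[at + 1] <- "G"
  }
  paste(filler, collapse = "")
}

# Hand-built track over explicit sites.
make_track <- function(sample_id, contig, pos, count, total = sum(count)) {
  site_count_track(sample_id,
                   stats::setNames(list(list(pos = pos, count = count)), contig),
                   library_total = total)
}

# Small deterministic reference shared by region and annotation tests.
tiny_reference <- function() {
  set.seed(42)
  chars <- sample(c("A", "T"), 12000, replace = TRUE)
  ref <- reference_genome(c(ctgA = paste(chars, collapse = "")))
  ref
}
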