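#' Read set container
#'
#' @param read_id Character vector of unique read names.
#' @param sequence A/C/G/T/N sequences.
#' @param quality Optional quality strings (defaults to constant "I").
#' @return data.frame of class `read_set` with columns read_id, sequence,
#'   quality.
#' @export
read_set <- function(read_id, sequence, quality = NULL) {
  if (anyDuplicated(read_id)) stop("read ids must be unique", call. = FALSE)
  if (length(sequence) && any(grepl("[^ACGTN]", sequence))) {
    stop("sequences must be over A/C/G/T/N", call. = FALSE)
  }
  quality <- quality %||% vapply(nchar(sequence), function(n) {
    paste(rep("I", n), collapse = "")
  }, "")
  structure(data.frame(read_id = as.character(read_id),
                       sequence = as.character(sequence),
                       quality = as.character(quality)),
            class = c("read_set", "data.frame"))
}

#' Simulate MeD-seq reads from a methylome
#'
#' Per CpG site, Poisson(mean_depth * m) fragments are emitted. Each fragment
#' is a `read_length` subsequence of the reference placed so the recognition
#' site sits in the positional window the read filter expects: the C at a
#' 1-based offset drawn uniformly from `window` from the 5' end, or the G at
#' such an offset from the 3' end. Each read is reported on a random
#' sequencing strand (the CG motif is its own reverse complement, so the
#' in-window property is preserved). A configurable fraction of background
#' reads carrying no correctly positioned site is added. Read names encode
#' the true origin (`frag:<contig>:<site>` or `bg`) for oracle tests.
#' Fragments that would run off a contig edge are skipped and counted.
#'
#' @param profile A `methylation_profile`.
#' @param reference The matching [reference_genome()].
#' @param mean_depth Expected reads at a fully methylated site.
#' @param read_length Read length in bp (default 50, single-end).
#' @param background_fraction Fraction of the final read set that is
#'   off-motif background (default 0.05).
#' @param window Inclusive 1-based offset window, default c(13, 17).
#' @param seed Integer seed.
#' @return list(reads = [read_set()], stats = list(n_site_reads,
#'   n_background, n_skipped_edge)).
#' @export
simulate_medseq_reads <- function(profile, reference, mean_depth = 20,
                                  read_length = 50L,
                                  background_fraction = 0.05,
                                  window = c(13L, 17L), seed = 1L) {
  L <- as.integer(read_length)
  with_seed(seed, {
    ids <- seqs <- list()
    n_skip <- 0L
    for (ctg in names(reference$cpg_sites)) {
      p <- reference$cpg_sites[[ctg]]
      if (!length(p)) next
      n <- stats::rpois(length(p), mean_depth * profile$levels[[ctg]])
      if (!sum(n)) next
      site <- rep(p, n)
      d <- sample(window[1]:window[2], length(site), replace = TRUE)
      from5 <- sample(c(TRUE, FALSE), length(site), replace = TRUE)
      a0 <- ifelse(from5, site - (d - 1L), site + d + 1L - L)
      ok <- a0 >= 0L & a0 + L <= nchar(reference$contigs[[ctg]])
      n_skip <- n_skip + sum(!ok)
      if (!any(ok)) next
      a0 <- a0[ok]
      site <- site[ok]
      s <- substring(reference$contigs[[ctg]], a0 + 1L, a0 + L)
      flip <- sample(c(TRUE, FALSE), length(s), replace = TRUE)
      if (any(flip)) s[flip] <- revcomp(s[flip])
      ids[[ctg]] <- sprintf("frag:%s:%d:%d", ctg, site, seq_along(site))
      seqs[[ctg]] <- s
    }
    ids <- unlist(ids, use.names = FALSE) %||% character(0)
    seqs <- unlist(seqs, use.names = FALSE) %||% character(0)
    n_true <- length(ids)

    n_bg <- round(background_fraction / (1 - background_fraction) * n_true)
    if (n_bg > 0) {
      ctg_len <- nchar(reference$contigs)
      bg <- character(0)
      while (length(bg) < n_bg) {
        need <- n_bg - length(bg)
        ctg <- sample(names(ctg_len), need, replace = TRUE,
                      prob = ctg_len / sum(ctg_len))
        a0 <- vapply(ctg, function(cc) {
          sample.int(ctg_len[[cc]] - L + 1L, 1L) - 1L
        }, 0L)
        s <- substring(reference$contigs[ctg], a0 + 1L, a0 + L)
        s <- s[!passes_position_filter(s, "CG", window[1], window[2])]
        bg <- c(bg, s)
      }
      ids <- c(ids, sprintf("bg:%d", seq_len(n_bg)))
      seqs <- c(seqs, bg[seq_len(n_bg)])
    }
    list(reads = read_set(ids, seqs),
         stats = list(n_site_reads = n_true, n_background = n_bg,
                      n_skipped_edge = n_skip))
  })
}

#' Write reads as FASTQ
#' @param reads A [read_set()].
#' @param path Output file (".gz" suffix writes gzip).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file, optionally gzip-compressed.
#' @export
read_fastq <- function(path) {
  lines <- readLines(gzfile(path))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  }
  if (!length(lines)) return(read_set(character(0), character(0)))
  i <- seq(1L, length(lines), by = 4L)
  read_set(sub("^@", "", sub("\\s.*$", "", lines[i])),
           toupper(lines[i + 1L]), lines[i + 3L])
}
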