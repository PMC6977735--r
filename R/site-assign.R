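#' Assign filtered reads to genomic CpG sites by exact matching
#'
#' Each read is matched exactly (forward and reverse complement, no
#' mismatches) against the reference. Uniquely matching reads increment the
#' count of the CpG site at the read's in-window motif offset; multi-mapping
#' and unmatched reads are dropped and counted in the stats, as are reads
#' whose sequence carries more than one window-positioned motif (the true
#' restriction site cannot be told from the decoy). Designed for desk-scale
#' synthetic references, standing in for a genome aligner.
#'
#' @param reads A [read_set()], already position-filtered.
#' @param reference A [reference_genome()].
#' @param sample_id Sample id stored on the returned track.
#' @param motif Recognition motif (default "CG").
#' @param window Inclusive positional window, default c(13, 17).
#' @return list(track = [site_count_track()] over every reference CpG site,
#'   stats = list(n_input, n_assigned, n_multi, n_unmatched, n_ambiguous,
#'   n_no_site)).
#' @export
assign_sites <- function(reads, reference, sample_id = "sample",
                         motif = "CG", window = c(13L, 17L)) {
  if (!length(reference$contigs)) stop("empty reference", call. = FALSE)
  n <- nrow(reads)
  counts <- lapply(reference$cpg_sites, function(p) rep(0, length(p)))
  stats <- list(n_input = n, n_assigned = 0L, n_multi = 0L,
                n_unmatched = 0L, n_ambiguous = 0L, n_no_site = 0L)
  if (n == 0L) {
    track <- site_count_track(sample_id, mapply(function(p, cnt) {
      list(pos = p, count = cnt)
    }, reference$cpg_sites, counts, SIMPLIFY = FALSE), library_total = 0)
    return(list(track = track, stats = stats))
  }

  n_match <- integer(n)                  # total match count per read
  hit <- data.frame(read = integer(0), contig = character(0),
                    rc = logical(0), start1 = integer(0))
  subjects <- lapply(reference$contigs, Biostrings::DNAString)
  for (w in unique(nchar(reads$sequence))) {
    idx <- which(nchar(reads$sequence) == w)
    fwd <- Biostrings::DNAStringSet(reads$sequence[idx])
    for (rc in c(FALSE, TRUE)) {
      pd <- Biostrings::PDict(if (rc) Biostrings::reverseComplement(fwd) else fwd)
      for (ctg in names(subjects)) {
        m <- Biostrings::matchPDict(pd, subjects[[ctg]])
        starts <- Biostrings::startIndex(m)
        k <- lengths(starts)
        k[vapply(starts, is.null, TRUE)] <- 0L
        n_match[idx] <- n_match[idx] + k
        has <- which(k > 0L)
        if (length(has)) {
          hit <- rbind(hit, data.frame(
            read = rep(idx[has], k[has]), contig = ctg,
            rc = rc, start1 = unlist(starts[has])))
        }
      }
    }
  }
  stats$n_unmatched <- sum(n_match == 0L)
  stats$n_multi <- sum(n_match > 1L)
  uniq <- hit[n_match[hit$read] == 1L, , drop = FALSE]
  if (nrow(uniq)) {
    L <- nchar(reads$sequence[uniq$read])
    j <- in_window_offset(reads$sequence[uniq$read], motif, window[1], window[2])
    keep <- !is.na(j)
    stats$n_ambiguous <- sum(!keep)
    uniq <- uniq[keep, , drop = FALSE]
    L <- L[keep]
    j <- j[keep]
    site0 <- ifelse(uniq$rc,
                    (uniq$start1 - 1L) + L - j - 1L,
                    (uniq$start1 - 1L) + (j - 1L))
    for (ctg in unique(uniq$contig)) {
      rows <- uniq$contig == ctg
      pos_idx <- match(site0[rows], reference$cpg_sites[[ctg]])
      miss <- is.na(pos_idx)
      stats$n_no_site <- stats$n_no_site + sum(miss)
      tab <- table(pos_idx[!miss])
      counts[[ctg]][as.integer(names(tab))] <-
        counts[[ctg]][as.integer(names(tab))] + as.integer(tab)
      stats$n_assigned <- stats$n_assigned + sum(!miss)
    }
  }
  track <- site_count_track(sample_id, mapply(function(p, cnt) {
    list(pos = p, count = cnt)
  }, reference$cpg_sites, counts, SIMPLIFY = FALSE),
  library_total = stats$n_assigned)
  list(track = track, stats = stats)
}

#' Load a site count track from externally aligned reads (SAM or BED)
#'
#' SAM: header lines are skipped; unmapped (0x4), secondary (0x100) and
#' supplementary (0x800) records are skipped; each remaining record is
#' assigned to the site at its aligned start plus the in-read motif offset
#' (records with no in-window motif are skipped and counted). BED (3+
#' columns): each record contributes one read at the site given by its
#' 0-based start. Malformed records raise an error naming the line number.
#'
#' @param path Input file.
#' @param format `"SAM"` or `"BED"`.
#' @param sample_id Sample id for the track.
#' @param motif,window Positional-filter settings used for SAM offset lookup.
#' @return A [site_count_track()] over the observed sites.
#' @export
load_alignments <- function(path, format = c("SAM", "BED"),
                            sample_id = "sample", motif = "CG",
                            window = c(13L, 17L)) {
  format <- match.arg(format)
  lines <- readLines(path)
  site <- data.frame(contig = character(0), pos = integer(0))
  if (format == "BED") {
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i])) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (length(f) < 3L || is.na(start) || is.na(end) || start >= end) {
        stop(sprintf("malformed BED record at line %d of %s", i, path),
             call. = FALSE)
      }
      site <- rbind(site, data.frame(contig = f[1], pos = start))
    }
  } else {
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i]) || startsWith(lines[i], "@")) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      flag <- suppressWarnings(as.integer(f[2]))
      pos <- suppressWarnings(as.integer(f[4]))
      if (length(f) < 11L || is.na(flag) || is.na(pos)) {
        stop(sprintf("malformed SAM record at line %d of %s", i, path),
             call. = FALSE)
      }
      if (bitwAnd(flag, 0x4L) || bitwAnd(flag, 0x100L) || bitwAnd(flag, 0x800L)) next
      j <- in_window_offset(toupper(f[10]), motif, window[1], window[2])
      if (is.na(j)) next
      site <- rbind(site, data.frame(contig = f[3], pos = (pos - 1L) + (j - 1L)))
    }
  }
  contigs <- lapply(split(site$pos, site$contig), function(p) {
    tab <- table(p)
    list(pos = as.integer(names(tab)), count = as.integer(tab))
  })
  site_count_track(sample_id, contigs)
}
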