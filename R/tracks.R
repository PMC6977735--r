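#' Per-site read count track
#'
#' Read counts at LpnPI/CpG sites for one sample: per contig a sorted vector
#' of 0-based site positions with non-negative counts, plus the library total
#' (number of retained reads the track was built from).
#'
#' @param sample_id Sample identifier.
#' @param contigs Named list; each element a list with integer vectors `pos`
#'   (strictly increasing, 0-based) and `count` (same length, >= 0).
#' @param library_total Defaults to the sum of all counts.
#' @return An object of class `site_count_track`.
#' @export
site_count_track <- function(sample_id, contigs, library_total = NULL) {
  for (ctg in names(contigs)) {
    el <- contigs[[ctg]]
    if (length(el$pos) != length(el$count) ||
        (length(el$pos) > 1 && is.unsorted(el$pos, strictly = TRUE)) ||
        any(el$count < 0)) {
      stop(sprintf("contig %s: positions must be strictly increasing with counts >= 0", ctg),
           call. = FALSE)
    }
    contigs[[ctg]] <- list(pos = as.integer(el$pos), count = as.numeric(el$count))
  }
  structure(list(sample_id = sample_id, contigs = contigs,
                 library_total = library_total %||% sum(vapply(contigs, function(e) sum(e$count), 0))),
            class = "site_count_track")
}

#' @export
print.site_count_track <- function(x, ...) {
  cat(sprintf("site_count_track %s: %d site(s) on %d contig(s), library total %g\n",
              x$sample_id, sum(vapply(x$contigs, function(e) length(e$pos), 0L)),
              length(x$contigs), x$library_total))
  invisible(x)
}

# Zero-count track over every CpG site of a reference.
empty_track <- function(sample_id, reference) {
  site_count_track(sample_id, lapply(reference$cpg_sites, function(p) {
    list(pos = p, count = rep(0, length(p)))
  }), library_total = 0)
}

#' Site-by-sample count matrix over the union of track sites
#'
#' Aligns a list of tracks on the union of their site positions (absent sites
#' count 0) and returns one long table, one row per (contig, site).
#'
#' @param tracks List of [site_count_track()] objects.
#' @return list(sites = data.frame(contig, pos), counts = numeric matrix with
#'   one column per track, library_totals = named numeric vector).
#' @export
track_site_matrix <- function(tracks) {
  if (!length(tracks)) stop("no tracks given", call. = FALSE)
  ids <- vapply(tracks, function(t) t$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids across tracks", call. = FALSE)
  ctgs <- unique(unlist(lapply(tracks, function(t) names(t$contigs))))
  sites <- do.call(rbind, lapply(ctgs, function(ctg) {
    pos <- sort(unique(unlist(lapply(tracks, function(t) t$contigs[[ctg]]$pos))))
    if (!length(pos)) return(NULL)
    data.frame(contig = ctg, pos = pos)
  }))
  if (is.null(sites)) sites <- data.frame(contig = character(0), pos = integer(0))
  counts <- matrix(0, nrow = nrow(sites), ncol = length(tracks),
                   dimnames = list(NULL, ids))
  for (j in seq_along(tracks)) {
    for (ctg in names(tracks[[j]]$contigs)) {
      el <- tracks[[j]]$contigs[[ctg]]
      if (!length(el$pos)) next
      rows <- which(sites$contig == ctg)
      idx <- rows[match(el$pos, sites$pos[rows])]
      counts[idx, j] <- el$count
    }
  }
  list(sites = sites, counts = counts,
       library_totals = stats::setNames(vapply(tracks, function(t) t$library_total, 0), ids))
}

#' Write a track as a bedGraph-style TSV
#'
#' One line per site: contig, 0-based start, end (site + 2, covering the CpG
#' dinucleotide), read count.
#' @param track A [site_count_track()].
#' @param path Output file.
#' @param drop_zero Omit zero-count sites (default TRUE).
#' @export
write_track <- function(track, path, drop_zero = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$contigs)) {
    el <- track$contigs[[ctg]]
    keep <- if (drop_zero) el$count > 0 else rep(TRUE, length(el$pos))
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", ctg, el$pos[keep], el$pos[keep] + 2L,
                         el$count[keep]), con)
    }
  }
  invisible(path)
}

#' Write a track read-by-read as BED
#'
#' Emits one BED record per counted read at the site's dinucleotide interval,
#' so reloading with [load_alignments()] reproduces the track.
#' @param track A [site_count_track()].
#' @param path Output file.
#' @export
track_to_bed <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  k <- 0L
  for (ctg in names(track$contigs)) {
    el <- track$contigs[[ctg]]
    for (i in which(el$count > 0)) {
      n <- el$count[i]
      writeLines(sprintf("%s\t%d\t%d\tread%d", ctg, el$pos[i], el$pos[i] + 2L,
                         k + seq_len(n)), con)
      k <- k + n
    }
  }
  invisible(path)
}
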