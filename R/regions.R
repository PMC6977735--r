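#' Build the three scored region classes from a gene annotation
#'
#' Per gene: a TSS region from 1 kb before to 1 kb after the transcription
#' start (half-open, 2 kb unless clipped at a contig edge) and a gene-body
#' region from 1 kb after the TSS — in the strand-aware direction of
#' transcription — to the TES. Genes whose TES lies within 1 kb of the TSS
#' yield no gene-body region. Each CpG island becomes one region.
#'
#' @param annotation A [gene_annotation()].
#' @param reference Optional [reference_genome()]; when given, regions are
#'   clipped (not dropped) at contig edges.
#' @param tss_flank,body_offset Flank sizes in bp (default 1000).
#' @return A `region_set` data.frame with columns region_id, class
#'   (`TSS`, `CpG-island`, `gene-body`), contig, start, end, strand, parent.
#' @export
build_regions <- function(annotation, reference = NULL, tss_flank = 1000L,
                          body_offset = 1000L) {
  g <- annotation$genes
  if (!is.null(reference)) {
    len <- nchar(reference$contigs)
    if (any(g$tss < 0 | g$tss >= len[g$contig])) {
      stop("annotation error: tss outside contig bounds", call. = FALSE)
    }
  }
  rows <- list()
  for (i in seq_len(NROW(g))) {
    tss <- g$tss[i]; tes <- g$tes[i]; plus <- g$strand[i] == "+"
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = paste0("TSS:", g$gene_id[i]), class = "TSS",
      contig = g$contig[i], start = tss - tss_flank, end = tss + tss_flank,
      strand = g$strand[i], parent = g$gene_id[i])
    body <- if (plus) c(tss + body_offset, tes) else c(tes, tss - body_offset)
    if (body[2] > body[1]) {
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = paste0("gene-body:", g$gene_id[i]), class = "gene-body",
        contig = g$contig[i], start = body[1], end = body[2],
        strand = g$strand[i], parent = g$gene_id[i])
    }
  }
  isl <- annotation$cpg_islands
  for (i in seq_len(NROW(isl))) {
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = paste0("CpG-island:", isl$island_id[i]), class = "CpG-island",
      contig = isl$contig[i], start = isl$start[i], end = isl$end[i],
      strand = ".", parent = isl$island_id[i])
  }
  out <- do.call(rbind, rows) %||%
    data.frame(region_id = character(0), class = character(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), parent = character(0))
  if (!is.null(reference)) {
    len <- nchar(reference$contigs)
    out$start <- pmax(out$start, 0L)
    out$end <- pmin(out$end, len[out$contig])
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' Aggregate site count tracks into a region-by-sample count matrix
#'
#' `counts[r, s]` is the sum of sample s site counts at positions p with
#' `start <= p < end` of region r. Overlapping regions each receive the full
#' site count (the three region classes are scored independently, so no
#' apportioning).
#'
#' @param tracks List of [site_count_track()] objects on one reference.
#' @param regions A `region_set` from [build_regions()].
#' @return An object of class `region_count_matrix`: list(counts = region x
#'   sample matrix, regions, library_totals).
#' @export
count_regions <- function(tracks, regions) {
  sm <- track_site_matrix(tracks)
  extra <- setdiff(unique(sm$sites$contig[rowSums(sm$counts) > 0]),
                   unique(regions$contig))
  if (length(extra)) {
    stop(sprintf("input error: track contig(s) %s absent from the region set",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  counts <- matrix(0, nrow = nrow(regions), ncol = ncol(sm$counts),
                   dimnames = list(regions$region_id, colnames(sm$counts)))
  for (ctg in unique(regions$contig)) {
    srows <- which(sm$sites$contig == ctg)
    rrows <- which(regions$contig == ctg)
    if (!length(srows) || !length(rrows)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = sm$sites$pos[srows] + 1L, width = 1L),
      IRanges::IRanges(start = regions$start[rrows] + 1L, end = regions$end[rrows]))
    if (!length(ov)) next
    si <- srows[S4Vectors::from(ov)]
    ri <- rrows[S4Vectors::to(ov)]
    for (j in seq_len(ncol(counts))) {
      agg <- rowsum(sm$counts[si, j], ri)
      counts[as.integer(rownames(agg)), j] <-
        counts[as.integer(rownames(agg)), j] + agg[, 1]
    }
  }
  structure(list(counts = counts, regions = regions,
                 library_totals = sm$library_totals),
            class = "region_count_matrix")
}

#' Write a region set as BED6
#'
#' The name field packs `class:parent` (the region id); score is 0.
#' @param regions A `region_set`.
#' @param path Output file.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", regions$contig, regions$start,
                     regions$end, regions$region_id, regions$strand), path)
  invisible(path)
}

#' Read a region set from BED6 written by [write_regions_bed()]
#' @param path Input file.
#' @export
read_regions_bed <- function(path) {
  f <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "start", "end", "region_id",
                                       "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character"))
  parts <- strsplit(f$region_id, ":", fixed = TRUE)
  out <- data.frame(region_id = f$region_id,
                    class = vapply(parts, `[`, "", 1L),
                    contig = f$contig, start = f$start, end = f$end,
                    strand = f$strand,
                    parent = vapply(parts, `[`, "", 2L))
  class(out) <- c("region_set", "data.frame")
  out
}

#' Write a region count matrix as TSV
#' @param x A `region_count_matrix`.
#' @param path Output file.
#' @export
write_region_counts <- function(x, path) {
  df <- data.frame(region_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
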