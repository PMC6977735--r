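#' Reference genome container
#'
#' A small in-memory reference: named contig sequences plus, per contig, the
#' sorted 0-based positions of every CpG dinucleotide (position of the C).
#' These positions are the potential LpnPI sites of the simulator and of the
#' site-count tracks. If `cpg_sites` is omitted it is computed by scanning
#' the sequences, which guarantees the invariant sequence[p] == "C",
#' sequence[p + 1] == "G" for every listed site.
#'
#' @param contigs Named character vector of A/C/G/T sequences.
#' @param cpg_sites Optional named list of 0-based integer vectors.
#' @return An object of class `reference_genome`.
#' @export
reference_genome <- function(contigs, cpg_sites = NULL) {
  if (length(contigs) == 0 || is.null(names(contigs)) ||
      anyDuplicated(names(contigs)) || any(!nzchar(contigs))) {
    stop("`contigs` must be a non-empty named vector of non-empty sequences, unique names",
         call. = FALSE)
  }
  if (is.null(cpg_sites)) {
    cpg_sites <- lapply(contigs, scan_cpg_sites)
  } else {
    for (ctg in names(contigs)) {
      p <- cpg_sites[[ctg]] %||% integer(0)
      if (is.unsorted(p, strictly = TRUE) && length(p) > 1) {
        stop("cpg_sites must be strictly increasing per contig", call. = FALSE)
      }
      if (length(p)) {
        dinuc <- substring(contigs[[ctg]], p + 1, p + 2)
        if (any(dinuc != "CG")) {
          stop(sprintf("contig %s: listed CpG site without a CG dinucleotide", ctg),
               call. = FALSE)
        }
      }
    }
  }
  structure(list(contigs = contigs, cpg_sites = cpg_sites[names(contigs)]),
            class = "reference_genome")
}

# 0-based positions of the C of every CG dinucleotide in `seq`.
scan_cpg_sites <- function(seq) {
  hits <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
  if (length(hits) == 1 && hits == -1) return(integer(0))
  as.integer(hits) - 1L
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("reference_genome: %d contig(s), %d bp, %d CpG site(s)\n",
              length(x$contigs), sum(nchar(x$contigs)),
              sum(lengths(x$cpg_sites))))
  invisible(x)
}

#' Gene and CpG-island annotation
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `strand`
#'   (`+`/`-`), `tss`, `tes` (0-based positions; for `-` strand genes
#'   `tss > tes`).
#' @param cpg_islands data.frame with columns `island_id`, `contig`,
#'   `start`, `end` (0-based, half-open).
#' @param reference Optional [reference_genome()] used to bounds-check
#'   coordinates.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, cpg_islands, reference = NULL) {
  need_g <- c("gene_id", "contig", "strand", "tss", "tes")
  need_i <- c("island_id", "contig", "start", "end")
  if (!all(need_g %in% names(genes)) || !all(need_i %in% names(cpg_islands))) {
    stop("annotation tables are missing required columns", call. = FALSE)
  }
  if (any(genes$tss == genes$tes)) stop("gene with tss == tes", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (any(cpg_islands$start >= cpg_islands$end)) {
    stop("cpg_islands must be half-open with start < end", call. = FALSE)
  }
  if (!is.null(reference)) {
    len <- nchar(reference$contigs)
    for (i in seq_len(nrow(genes))) {
      L <- len[[genes$contig[i]]]
      if (is.na(L) || genes$tss[i] < 0 || genes$tss[i] >= L ||
          genes$tes[i] < 0 || genes$tes[i] > L) {
        stop(sprintf("gene %s outside contig bounds", genes$gene_id[i]), call. = FALSE)
      }
    }
    for (i in seq_len(nrow(cpg_islands))) {
      L <- len[[cpg_islands$contig[i]]]
      if (is.na(L) || cpg_islands$start[i] < 0 || cpg_islands$end[i] > L) {
        stop(sprintf("island %s outside contig bounds", cpg_islands$island_id[i]),
             call. = FALSE)
      }
    }
  }
  structure(list(genes = genes, cpg_islands = cpg_islands),
            class = "gene_annotation")
}

#' Generate a synthetic reference genome with genes and CpG islands
#'
#' Emits random contigs in which every CpG dinucleotide is planted explicitly:
#' a per-position CpG rate equal to `cpg_density` outside islands and
#' `island_density` inside them, with non-planted positions filled so that no
#' accidental CG arises. Genes are placed non-overlapping with random strand;
#' CpG islands are the locally CpG-enriched stretches used during planting.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (>= 5000).
#' @param cpg_density Per-position CpG start rate outside islands, in (0, 0.2].
#' @param n_genes,n_islands Total counts across contigs.
#' @param island_length Island width in bp.
#' @param island_density CpG start rate inside islands (capped at 0.2).
#' @param gene_length_range Range the gene lengths are drawn from.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return list(reference = [reference_genome()], annotation = [gene_annotation()]).
#' @export
generate_reference <- function(n_contigs = 2L, contig_length = 100000L,
                               cpg_density = 0.02, n_genes = 20L,
                               n_islands = 10L, island_length = 600L,
                               island_density = min(5 * cpg_density, 0.2),
                               gene_length_range = c(1500L, 4000L),
                               seed = 1L) {
  stopifnot_scalar_number(contig_length, "contig_length", min = 5000)
  if (!is.numeric(cpg_density) || cpg_density <= 0 || cpg_density > 0.2) {
    stop("`cpg_density` must lie in (0, 0.2]", call. = FALSE)
  }
  margin <- 1200L  # keeps TSS windows and fragments clear of contig edges
  per_ctg_genes <- ceiling(n_genes / n_contigs)
  per_ctg_islands <- ceiling(n_islands / n_contigs)
  if (per_ctg_genes * min(gene_length_range) > contig_length - 2L * margin) {
    stop("sizing error: too many genes for the requested contig length", call. = FALSE)
  }
  if (per_ctg_islands * island_length > contig_length - 2L * margin) {
    stop("sizing error: too many islands for the requested contig length", call. = FALSE)
  }

  with_seed(seed, {
    ctg_names <- sprintf("ctg%d", seq_len(n_contigs))
    # spread features across contigs as evenly as counts allow
    gene_ctg <- ctg_names[(seq_len(n_genes) - 1L) %% n_contigs + 1L]
    isl_ctg <- ctg_names[(seq_len(n_islands) - 1L) %% n_contigs + 1L]

    contigs <- character(0)
    islands <- list()
    genes <- list()
    gid <- iid <- 0L
    for (ctg in ctg_names) {
      n_isl <- sum(isl_ctg == ctg)
      isl_start <- place_intervals(contig_length, rep(island_length, n_isl), margin)
      # compensate the outside-island rate so the contig-wide expected CpG
      # count stays at cpg_density * contig_length despite island enrichment
      isl_area <- n_isl * island_length
      base_d <- (cpg_density * contig_length - island_density * isl_area) /
        (contig_length - isl_area)
      if (base_d <= 0) {
        stop("sizing error: island enrichment exceeds the contig-wide CpG budget",
             call. = FALSE)
      }
      dens <- rep(base_d, contig_length)
      for (s in isl_start) dens[(s + 1):(s + island_length)] <- island_density

      seq_chars <- plant_cpg_sequence(contig_length, dens)
      contigs[[ctg]] <- paste(seq_chars, collapse = "")

      if (n_isl) {
        islands[[ctg]] <- data.frame(
          island_id = sprintf("isl%d", iid + seq_len(n_isl)),
          contig = ctg, start = as.integer(isl_start),
          end = as.integer(isl_start + island_length))
        iid <- iid + n_isl
      }
      n_g <- sum(gene_ctg == ctg)
      if (n_g) {
        glen <- sample(seq(gene_length_range[1], gene_length_range[2]), n_g,
                       replace = TRUE)
        gstart <- place_intervals(contig_length, glen, margin)
        strand <- sample(c("+", "-"), n_g, replace = TRUE)
        genes[[ctg]] <- data.frame(
          gene_id = sprintf("g%d", gid + seq_len(n_g)),
          contig = ctg, strand = strand,
          tss = as.integer(ifelse(strand == "+", gstart, gstart + glen - 1L)),
          tes = as.integer(ifelse(strand == "+", gstart + glen, gstart - 1L)))
        gid <- gid + n_g
      }
    }
    ref <- reference_genome(contigs)
    ann <- gene_annotation(
      genes = do.call(rbind, unname(genes)) %||%
        data.frame(gene_id = character(0), contig = character(0),
                   strand = character(0), tss = integer(0), tes = integer(0)),
      cpg_islands = do.call(rbind, unname(islands)) %||%
        data.frame(island_id = character(0), contig = character(0),
                   start = integer(0), end = integer(0)))
    list(reference = ref, annotation = ann)
  })
}

# Non-overlapping interval starts (0-based): the free space between the
# intervals is split by random stick-breaking, so placement always succeeds
# when the total width fits.
place_intervals <- function(contig_length, widths, margin) {
  if (!length(widths)) return(integer(0))
  n <- length(widths)
  free <- contig_length - 2L * margin - sum(widths)
  if (free < 0) {
    stop("sizing error: could not place non-overlapping intervals", call. = FALSE)
  }
  g <- stats::rexp(n + 1L)
  gaps <- floor(g / sum(g) * free)
  as.integer(margin + cumsum(gaps[seq_len(n)]) + cumsum(c(0L, widths[-n])))
}

# A/C/G/T character vector of length n with CG dinucleotides planted at rate
# dens[p] (0-based start p-1) and nowhere else.
plant_cpg_sequence <- function(n, dens) {
  cand <- which(stats::runif(n - 1L) < dens[-n]) # 1-based C positions
  keep <- integer(0)
  last <- -2L
  for (p in cand) {
    if (p > last + 1L) {
      keep <- c(keep, p)
      last <- p
    }
  }
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  chars[keep] <- "C"
  chars[keep + 1L] <- "G"
  planted <- keep
  repeat {
    s <- paste(chars, collapse = "")
    all_cg <- scan_cpg_sites(s) + 1L # to 1-based
    bad <- setdiff(all_cg, planted)
    if (!length(bad)) break
    chars[bad + 1L] <- sample(c("A", "C", "T"), length(bad), replace = TRUE)
  }
  chars
}

#' Write a reference as FASTA
#' @param reference A [reference_genome()].
#' @param path Output file.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference$contigs), path)
  invisible(path)
}

#' Read a reference from FASTA, rescanning CpG sites
#' @param path FASTA file.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  reference_genome(seqs)
}

#' Write an annotation as GTF (genes) and BED (CpG islands)
#'
#' Genes are written 1-based inclusive in the GTF dialect; islands 0-based
#' half-open in BED3+1.
#' @param annotation A [gene_annotation()].
#' @param gtf_path,bed_path Output files.
#' @export
write_annotation <- function(annotation, gtf_path, bed_path) {
  g <- annotation$genes
  start0 <- pmin(g$tss, g$tes - ifelse(g$strand == "+", 1L, -1L))
  end0 <- pmax(g$tss + 1L, g$tes + ifelse(g$strand == "+", 0L, 1L))
  lines <- sprintf("%s\tmedmir\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; tss \"%d\"; tes \"%d\";",
                   g$contig, start0 + 1L, end0, g$strand, g$gene_id, g$tss, g$tes)
  writeLines(lines, gtf_path)
  i <- annotation$cpg_islands
  writeLines(sprintf("%s\t%d\t%d\t%s", i$contig, i$start, i$end, i$island_id),
             bed_path)
  invisible(c(gtf_path, bed_path))
}
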