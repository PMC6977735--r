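#' Generate paired methylomes with planted DMRs
#'
#' Draws one baseline methylation level per CpG site from a Beta distribution
#' (shared by all samples), multiplies it by the planted fold effect inside
#' each DMR interval for the recurrent group (clipped to \[0, 1\]), and adds
#' per-sample per-site Beta noise around the expected level. Outside planted
#' DMRs the two groups have identical expected levels.
#'
#' @param reference A [reference_genome()].
#' @param n_pairs Number of primary/recurrent pairs (one profile each).
#' @param dmr_spec NULL, or data.frame(contig, start, end, fold) of planted
#'   DMR intervals (0-based half-open) with fold effects > 0 applied to the
#'   recurrent group.
#' @param baseline_beta_params Shape parameters (a, b) of the baseline Beta;
#'   the default mean a/(a+b) = 0.3 leaves room for hypermethylation folds.
#' @param noise_concentration Concentration k of the per-sample Beta noise
#'   (level ~ Beta(m k, (1 - m) k)); larger is quieter. The default 200
#'   models technical-scale variation (sd about 0.03 at m = 0.3).
#' @param seed Integer seed.
#' @return list(profiles = list of `methylation_profile` (primary then
#'   recurrent per pair, ids "P<i>.1"/"P<i>.2"), truth = truth record with
#'   `planted_dmrs` and `seed`).
#' @export
generate_methylomes <- function(reference, n_pairs, dmr_spec = NULL,
                                baseline_beta_params = c(1.2, 2.8),
                                noise_concentration = 200, seed = 1L) {
  stopifnot_scalar_number(n_pairs, "n_pairs", min = 1)
  if (!is.null(dmr_spec) && nrow(dmr_spec)) {
    if (any(dmr_spec$fold <= 0)) stop("fold effects must be > 0", call. = FALSE)
    len <- nchar(reference$contigs)
    bad <- !(dmr_spec$contig %in% names(len)) | dmr_spec$start < 0 |
      dmr_spec$end > len[dmr_spec$contig] | dmr_spec$start >= dmr_spec$end
    if (any(bad)) stop("annotation error: planted DMR interval off-contig", call. = FALSE)
  }
  with_seed(seed, {
    baseline <- lapply(reference$cpg_sites, function(p) {
      stats::rbeta(length(p), baseline_beta_params[1], baseline_beta_params[2])
    })
    recurrent_mean <- baseline
    if (!is.null(dmr_spec)) {
      for (i in seq_len(NROW(dmr_spec))) {
        ctg <- dmr_spec$contig[i]
        inside <- reference$cpg_sites[[ctg]] >= dmr_spec$start[i] &
          reference$cpg_sites[[ctg]] < dmr_spec$end[i]
        recurrent_mean[[ctg]][inside] <-
          pmin(1, recurrent_mean[[ctg]][inside] * dmr_spec$fold[i])
      }
    }
    noisy <- function(means) {
      lapply(means, function(m) {
        m <- pmin(pmax(m, 1e-4), 1 - 1e-4)
        stats::rbeta(length(m), m * noise_concentration,
                     (1 - m) * noise_concentration)
      })
    }
    profiles <- vector("list", 2L * n_pairs)
    for (i in seq_len(n_pairs)) {
      profiles[[2L * i - 1L]] <- structure(
        list(sample_id = sprintf("P%02d.1", i), group = "primary",
             levels = noisy(baseline)), class = "methylation_profile")
      profiles[[2L * i]] <- structure(
        list(sample_id = sprintf("P%02d.2", i), group = "recurrent",
             levels = noisy(recurrent_mean)), class = "methylation_profile")
    }
    truth <- list(planted_dmrs = dmr_spec %||%
                    data.frame(contig = character(0), start = integer(0),
                               end = integer(0), fold = numeric(0)),
                  planted_de_mirnas = NULL, batch_offsets = NULL, seed = seed)
    list(profiles = profiles, truth = truth)
  })
}

#' Choose planted DMR intervals over runs of consecutive CpG sites
#'
#' DMRs occur where CpG sites exist, so planted intervals are defined as runs
#' of `n_sites` consecutive reference CpG sites; the interval spans the first
#' site to the last site's G (half-open). Runs are chosen disjoint.
#'
#' @param reference A [reference_genome()].
#' @param n_dmrs Number of intervals.
#' @param n_sites CpG sites per interval.
#' @param fold Fold effect recorded in the spec.
#' @param seed Integer seed.
#' @return data.frame(contig, start, end, fold, n_sites) usable as `dmr_spec`.
#' @export
plant_dmr_windows <- function(reference, n_dmrs, n_sites = 20L, fold = 4,
                              seed = 1L) {
  with_seed(seed, {
    out <- list()
    taken <- lapply(reference$cpg_sites, function(p) rep(FALSE, length(p)))
    ctgs <- names(reference$cpg_sites)
    for (d in seq_len(n_dmrs)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        ctg <- sample(ctgs, 1L)
        p <- reference$cpg_sites[[ctg]]
        if (length(p) < n_sites) next
        i <- sample.int(length(p) - n_sites + 1L, 1L)
        idx <- i:(i + n_sites - 1L)
        if (any(taken[[ctg]][idx])) next
        taken[[ctg]][idx] <- TRUE
        out[[d]] <- data.frame(contig = ctg, start = p[i],
                               end = p[i + n_sites - 1L] + 2L, fold = fold,
                               n_sites = n_sites)
        placed <- TRUE
        break
      }
      if (!placed) stop("sizing error: could not place disjoint DMR windows",
                        call. = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate a site count track directly from a methylome
#'
#' Per CpG site the number of retained MeD-seq fragments is
#' Poisson(mean_depth * m); this is the count the read-level route
#' ([simulate_medseq_reads()] then [filter_reads()] and [assign_sites()])
#' converges to, without materializing reads. Used for simulation studies
#' where only counts matter.
#'
#' @param profile A `methylation_profile`.
#' @param reference The matching [reference_genome()].
#' @param mean_depth Expected reads at a fully methylated site.
#' @param seed Integer seed.
#' @return A [site_count_track()].
#' @export
simulate_site_counts <- function(profile, reference, mean_depth = 20, seed = 1L) {
  with_seed(seed, {
    contigs <- lapply(names(reference$cpg_sites), function(ctg) {
      p <- reference$cpg_sites[[ctg]]
      list(pos = p, count = stats::rpois(length(p), mean_depth * profile$levels[[ctg]]))
    })
    names(contigs) <- names(reference$cpg_sites)
    site_count_track(profile$sample_id, contigs)
  })
}
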