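#!/usr/bin/env Rscript
# Build the synthetic MeD-seq study: a reference genome with genes and CpG
# islands, 27 paired methylomes with ten planted DMRs (fold 4, 20 CpG sites
# each), and reads for one sample pushed through the positional filter and
# the exact-matching site assigner to demonstrate the read-level route.
# Site count tracks for all 54 samples are produced by the count-level
# generator and saved with the truth record for the next stage.

library(medmir)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 20260922L

g <- generate_reference(n_contigs = 2, contig_length = 100000,
                        cpg_density = 0.02, n_genes = 20, n_islands = 10,
                        seed = seed)
write_reference_fasta(g$reference, "results/reference.fa")
write_annotation(g$annotation, "results/genes.gtf", "results/islands.bed")
cat(sprintf("reference: %d CpG sites on %d contigs\n",
            sum(lengths(g$reference$cpg_sites)), length(g$reference$contigs)))

spec <- plant_dmr_windows(g$reference, n_dmrs = 10, n_sites = 20, fold = 4,
                          seed = seed + 1L)
write.table(spec, "results/planted_dmrs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
mm <- generate_methylomes(g$reference, n_pairs = 27, dmr_spec = spec,
                          seed = seed + 2L)

# read-level demonstration on the first sample
rs <- simulate_medseq_reads(mm$profiles[[1]], g$reference, mean_depth = 5,
                            seed = seed + 3L)
flt <- filter_reads(rs$reads)
asg <- assign_sites(flt$retained, g$reference,
                    sample_id = mm$profiles[[1]]$sample_id)
cat(sprintf("reads: %d simulated (%d background), %d retained by the 13-17 bp filter, %d uniquely assigned\n",
            nrow(rs$reads), rs$stats$n_background, flt$stats$n_retained,
            asg$stats$n_assigned))
write_track(asg$track, "results/track_P01.1.tsv")

# count-level tracks for the full cohort
tracks <- lapply(seq_along(mm$profiles), function(i) {
  simulate_site_counts(mm$profiles[[i]], g$reference, mean_depth = 30,
                       seed = seed + 10L + i)
})
saveRDS(list(tracks = tracks, spec = spec, annotation = g$annotation,
             reference_sites = g$reference$cpg_sites,
             groups = vapply(mm$profiles, function(p) p$group, "")),
        "scratch/medseq_state.rds")
cat("cohort tracks saved for stage 03\n")
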