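#' Filter reads by recognition-site position
#'
#' MeD-seq fragments carry the LpnPI recognition site a fixed distance from
#' the fragment end; reads are therefore retained only when the motif occurs
#' within an inclusive positional window (default 13-17 bp) from either end.
#' Offsets are 1-based from the respective end; from the 5' side the motif's
#' first base is measured, from the 3' side its last base (the symmetric
#' reading of a window from "either end"). Reads shorter than
#' `window_max + nchar(motif)` are discarded (and counted), as are reads with
#' no motif in window. `N` never matches the motif.
#'
#' @param reads A [read_set()] (or data.frame with columns read_id, sequence).
#' @param motif Recognition motif; default the methylation-dependent CpG core
#'   `"CG"`.
#' @param window_min,window_max Inclusive window bounds.
#' @return list(retained = [read_set()], stats = list(n_input, n_retained,
#'   n_discarded)).
#' @export
filter_reads <- function(reads, motif = "CG", window_min = 13L,
                         window_max = 17L) {
  if (!nzchar(motif)) stop("`motif` must be non-empty", call. = FALSE)
  if (window_min > window_max) stop("window_min must be <= window_max", call. = FALSE)
  keep <- passes_position_filter(reads$sequence, motif, window_min, window_max)
  out <- reads[keep, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  rownames(out) <- NULL
  list(retained = out,
       stats = list(n_input = nrow(reads), n_retained = sum(keep),
                    n_discarded = sum(!keep)))
}

# Vectorized positional predicate shared by the filter, the simulator's
# background rejection and the SAM loader.
passes_position_filter <- function(seqs, motif, wmin, wmax) {
  if (!length(seqs)) return(logical(0))
  mlen <- nchar(motif)
  L <- nchar(seqs)
  hits <- gregexpr(motif, seqs, fixed = TRUE)
  ok <- mapply(function(h, l) {
    if (l < wmax + mlen) return(FALSE)
    s <- as.integer(h)
    if (length(s) == 1 && s == -1L) return(FALSE)
    any((s >= wmin & s <= wmax) |
          (l - (s + mlen - 1L) + 1L >= wmin & l - (s + mlen - 1L) + 1L <= wmax))
  }, hits, L)
  as.logical(ok)
}

# 1-based read offset of the motif occurrence used for site assignment. A
# read can carry a second, decoy motif inside the window at the other end;
# since the true restriction site cannot be told from the decoy, such reads
# are ambiguous (NA), analogous to multi-mapping reads. NA also when no
# occurrence is in window.
in_window_offset <- function(seqs, motif, wmin, wmax) {
  if (!length(seqs)) return(integer(0))
  mlen <- nchar(motif)
  L <- nchar(seqs)
  hits <- gregexpr(motif, seqs, fixed = TRUE)
  off <- mapply(function(h, l) {
    if (l < wmax + mlen) return(NA_integer_)
    s <- as.integer(h)
    if (length(s) == 1 && s == -1L) return(NA_integer_)
    d3 <- l - (s + mlen - 1L) + 1L
    cand <- s[(s >= wmin & s <= wmax) | (d3 >= wmin & d3 <= wmax)]
    if (length(cand) == 1L) cand else NA_integer_
  }, hits, L)
  as.integer(off)
}
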