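#' Ct matrix container
#'
#' Raw TLDA-style Ct values (miRNA x sample) with per-sample batch labels and
#' pair structure. Missing entries (`NA`) are undetected measurements. Every
#' pair id must have exactly one primary and one recurrent sample and both
#' must share a batch (paired samples are run on the same card batch).
#'
#' @param ct Numeric matrix, rows miRNAs, columns samples (named).
#' @param batch,pair,role Character vectors named by (or aligned to) the
#'   sample columns; `role` in `{"primary", "recurrent"}`.
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, batch, pair, role) {
  smp <- colnames(ct)
  if (is.null(smp)) stop("`ct` needs sample column names", call. = FALSE)
  batch <- stats::setNames(as.character(batch), names(batch) %||% smp)[smp]
  pair <- stats::setNames(as.character(pair), names(pair) %||% smp)[smp]
  role <- stats::setNames(as.character(role), names(role) %||% smp)[smp]
  if (!all(role %in% c("primary", "recurrent"))) {
    stop("role must be 'primary' or 'recurrent'", call. = FALSE)
  }
  for (p in unique(pair)) {
    r <- role[pair == p]
    if (sum(r == "primary") != 1L || sum(r == "recurrent") != 1L) {
      stop(sprintf("pair %s must have exactly one primary and one recurrent sample", p),
           call. = FALSE)
    }
    if (length(unique(batch[pair == p])) != 1L) {
      stop(sprintf("pair %s spans batches; paired samples must share a batch", p),
           call. = FALSE)
    }
  }
  if (any(is.infinite(ct), na.rm = TRUE)) stop("Ct values must be finite", call. = FALSE)
  structure(list(ct = ct, batch = batch, pair = pair, role = role),
            class = "ct_matrix")
}

#' Generate a batched Ct matrix with planted paired expression shifts
#'
#' Per-miRNA baseline Ct ~ Uniform(20, 34); a per-pair per-miRNA random
#' effect (sd `pair_sd`) models inter-individual variation shared by the two
#' samples of a pair; planted miRNAs get a paired log2-expression shift
#' `delta` in the recurrent sample (positive delta = up in recurrent, i.e.
#' Ct lowered by delta); a per-batch additive offset and scale are applied;
#' Gaussian measurement noise (sd `noise_sd`) is added; values above
#' `detect_ct_max` are censored as undetected. Pairs are assigned to batches
#' evenly, both samples of a pair in the same batch.
#'
#' @param n_mirnas Number of miRNAs (TLDA A+B cards measure ~754).
#' @param n_pairs Number of primary/recurrent pairs.
#' @param n_batches Number of processing batches (must be <= n_pairs).
#' @param de_spec NULL, or data.frame(mirna, delta) of planted shifts; mirna
#'   may be an index or an id `miR-<i>`.
#' @param batch_spec NULL, or list(offsets, scales) of length n_batches;
#'   defaults to offsets ~ N(0, 1) and scales 1.
#' @param detect_ct_max Censoring threshold (Inf disables censoring).
#' @param noise_sd Measurement noise sd in Ct units.
#' @param pair_sd Sd of the shared per-pair effect in Ct units.
#' @param seed Integer seed.
#' @return list(ct = [ct_matrix()], truth = truth record with
#'   `planted_de_mirnas`, `batch_offsets`, `seed`).
#' @export
generate_ct_matrix <- function(n_mirnas = 754L, n_pairs = 27L,
                               n_batches = 3L, de_spec = NULL,
                               batch_spec = NULL, detect_ct_max = 35,
                               noise_sd = 1, pair_sd = 1, seed = 1L) {
  if (n_batches > n_pairs) {
    stop("sizing error: more batches than pairs", call. = FALSE)
  }
  with_seed(seed, {
    mirnas <- sprintf("miR-%04d", seq_len(n_mirnas))
    samples <- as.vector(t(cbind(sprintf("P%02d.1", seq_len(n_pairs)),
                                 sprintf("P%02d.2", seq_len(n_pairs)))))
    pair <- rep(sprintf("P%02d", seq_len(n_pairs)), each = 2L)
    role <- rep(c("primary", "recurrent"), n_pairs)
    pair_batch <- rep(sprintf("b%d", seq_len(n_batches)), length.out = n_pairs)
    batch <- pair_batch[rep(seq_len(n_pairs), each = 2L)]

    offsets <- if (is.null(batch_spec)) stats::rnorm(n_batches) else batch_spec$offsets
    scales <- if (is.null(batch_spec)) rep(1, n_batches) else
      (batch_spec$scales %||% rep(1, n_batches))
    names(offsets) <- names(scales) <- sprintf("b%d", seq_len(n_batches))

    delta <- stats::setNames(rep(0, n_mirnas), mirnas)
    if (!is.null(de_spec) && nrow(de_spec)) {
      ids <- if (is.numeric(de_spec$mirna)) mirnas[de_spec$mirna] else de_spec$mirna
      if (any(!ids %in% mirnas)) stop("de_spec names unknown miRNAs", call. = FALSE)
      delta[ids] <- de_spec$delta
      de_spec <- data.frame(mirna = ids, delta = de_spec$delta)
    } else {
      de_spec <- data.frame(mirna = character(0), delta = numeric(0))
    }

    base <- stats::runif(n_mirnas, 20, 34)
    pair_eff <- matrix(stats::rnorm(n_mirnas * n_pairs, sd = pair_sd),
                       n_mirnas, n_pairs)
    ct <- base + pair_eff[, match(pair, sprintf("P%02d", seq_len(n_pairs)))]
    ct <- ct - outer(delta, as.numeric(role == "recurrent"))
    ct <- sweep(ct, 2L, scales[batch], `*`)
    ct <- sweep(ct, 2L, offsets[batch], `+`)
    ct <- ct + matrix(stats::rnorm(length(ct), sd = noise_sd), nrow(ct))
    ct[ct > detect_ct_max] <- NA
    dimnames(ct) <- list(mirnas, samples)
    list(ct = ct_matrix(ct, batch, pair, role),
         truth = list(planted_dmrs = NULL, planted_de_mirnas = de_spec,
                      batch_offsets = offsets, batch_scales = scales,
                      seed = seed))
  })
}

#' Write a Ct matrix as TSV with metadata header lines
#'
#' Lines `#batch`, `#pair`, `#role` precede the header row and carry the
#' per-sample metadata in column order.
#' @param x A [ct_matrix()].
#' @param path Output file.
#' @export
write_ct_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  smp <- colnames(x$ct)
  writeLines(c(paste(c("#batch", x$batch[smp]), collapse = "\t"),
               paste(c("#pair", x$pair[smp]), collapse = "\t"),
               paste(c("#role", x$role[smp]), collapse = "\t"),
               paste(c("mirna", smp), collapse = "\t")), con)
  body <- cbind(rownames(x$ct),
                matrix(ifelse(is.na(x$ct), "NA", format(x$ct, digits = 10,
                                                        trim = TRUE)),
                       nrow(x$ct)))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a Ct matrix written by [write_ct_matrix()]
#' @param path Input file.
#' @export
read_ct_matrix <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (key in c("#batch", "#pair", "#role")) {
    row <- strsplit(lines[startsWith(lines, paste0(key, "\t"))][1], "\t")[[1]]
    meta[[sub("#", "", key)]] <- row[-1]
  }
  tab_start <- which(startsWith(lines, "mirna\t"))[1]
  df <- utils::read.table(text = lines[tab_start:length(lines)], sep = "\t",
                          header = TRUE, check.names = FALSE)
  ct <- as.matrix(df[, -1, drop = FALSE])
  rownames(ct) <- df[[1]]
  ct_matrix(ct, stats::setNames(meta$batch, colnames(ct)),
            stats::setNames(meta$pair, colnames(ct)),
            stats::setNames(meta$role, colnames(ct)))
}
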