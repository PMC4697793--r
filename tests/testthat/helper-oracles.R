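# Independent oracles and shared fixtures, built in code at test time.

# all-offsets Hamming scorer, the reference implementation the aligner must
# agree with
brute_force_best <- function(read, seqs, max_mm) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rb <- strsplit(read, "")[[1]]
  L <- length(rb)
  rows <- list()
  for (j in seq_along(seqs)) {
    sb <- strsplit(seqs[[j]], "")[[1]]
    if (length(sb) < L) next
    for (off in 0:(length(sb) - L)) {
      mm <- sum(rb != sb[(off + 1):(off + L)] & rb != "N")
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = names(seqs)[j], offset = off, n_mm = mm,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(ref_id = character(),
                                      offset = integer(), n_mm = integer()))
  best <- min(res$n_mm)
  if (best > max_mm) return(res[0, ])
  out <- res[res$n_mm == best, ]
  out[order(out$ref_id, out$offset), ]
}

paired_t_closed_form <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# small shared catalog/reference fixture (deterministic)
toy_refset <- function(seed = 301, n_mature = 5) {
  catalog <- simulate_gene_catalog(n_mature = n_mature, copies = 1,
                                   intron_frac = 0.4, seed = seed)
  build_reference_set(catalog)
}

# minimal hand-built mature reference record for profiler tests
hand_ref <- function(ref_id, sequence, labels = as.character(seq_len(nchar(sequence)))) {
  list(ref_id = ref_id, sequence = sequence,
       member_gene_ids = ref_id, labels = labels, numbered = TRUE,
       g26_present = NA, a34_present = NA, variable_loop_length = NA_integer_)
}

hand_refset <- function(mature, precursor = NULL) {
  if (is.null(precursor))
    precursor <- lapply(mature, function(r) {
      r$mature_sequence <- r$sequence
      r$site_map <- seq_len(nchar(r$sequence))
      r
    })
  structure(list(mature = mature, precursor = precursor,
                 provenance = list(cca = FALSE)),
            class = "reference_set")
}
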