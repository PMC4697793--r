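#' Read a fragment FASTQ
#'
#' @param path FASTQ, optionally gzipped.
#' @return named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write reads as FASTQ
#'
#' @param reads named character vector.
#' @param path output path (`.gz` for gzip).
#' @param quality_char constant per-base quality character (default `I`,
#'   i.e. Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ss <- Biostrings::DNAStringSet(reads)
  names(ss) <- names(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality_char, n), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

hit_mismatches <- function(read, ref_seq, offset) {
  rb <- strsplit(read, "")[[1]]
  sb <- strsplit(substr(ref_seq, offset + 1L, offset + nchar(read)), "")[[1]]
  mm <- which(rb != sb & rb != "N")
  data.frame(ref_linear_index = offset + mm, ref_base = sb[mm],
             read_base = rb[mm], stringsAsFactors = FALSE)
}

#' Ungapped best placements of one read on a reference tier
#'
#' Scores every offset of every reference by mismatch count (substitutions
#' only, sense strand only; `N` in the read never counts as mismatch) and
#' returns all placements achieving the minimum, provided it does not
#' exceed `max_mm`. Ordering is deterministic: reference order, then
#' offset. Ties are reported, never broken: `n_equal_best` carries the
#' number of equally good placements.
#'
#' @param read a single read sequence.
#' @param refs reference records (each with `ref_id`, `sequence`) or a
#'   named character vector of sequences.
#' @param max_mm maximum tolerated mismatches (default 3: one RT
#'   misincorporation plus sequencing error on a <=35 nt fragment).
#' @return data.frame with `ref_id`, `offset` (0-based), `n_mm`,
#'   `n_equal_best`, and list-column `mismatches` of per-hit mismatch
#'   detail (`ref_linear_index` 1-based, `ref_base`, `read_base`).
#' @export
align_ungapped <- function(read, refs, max_mm = 3) {
  seqs <- ref_seqs(refs)
  h <- align_scan(read, unname(seqs), as.integer(max_mm))
  n <- nrow(h)
  out <- data.frame(ref_id = names(seqs)[h$ref], offset = h$offset,
                    n_mm = h$n_mm, n_equal_best = rep(n, n),
                    stringsAsFactors = FALSE)
  out$mismatches <- lapply(seq_len(n), function(i)
    hit_mismatches(read, seqs[[h$ref[i]]], h$offset[i]))
  out
}

ref_seqs <- function(refs) {
  if (is.character(refs)) return(refs)
  setNames(vapply(refs, `[[`, "", "sequence"),
           vapply(refs, `[[`, "", "ref_id"))
}

#' Hierarchical two-tier mapping of fragment reads
#'
#' Each read inside the length window is first aligned to the mature tier;
#' only reads with no qualifying mature placement proceed to the precursor
#' tier (so a read matching both tiers is mature by construction — mature
#' bodies are substrings of their precursors). Reads outside the window are
#' rejected and counted. Dispositions (`mature`, `precursor`, `unmapped`,
#' `length_rejected`) partition the input exactly.
#'
#' @param reads named character vector of read sequences.
#' @param reference_set a `reference_set`.
#' @param max_mm maximum mismatches per placement (default 3).
#' @param min_len,max_len fragment length window (defaults 19 and 35, the
#'   gel-selection window of the protocol).
#' @return object of class `mapping_result`: list with
#'   * `hits`: data.frame `read_id`, `ref_id`, `tier`, `offset`, `n_mm`,
#'     `n_equal_best` (all equally best placements of each mapped read),
#'   * `disposition`: data.frame `read_id`, `disposition`,
#'   * `reads`: the input reads,
#'   * `summary`: named tally over dispositions.
#' @export
map_hierarchical <- function(reads, reference_set, max_mm = 3,
                             min_len = 19, max_len = 35) {
  if (length(reference_set$mature) == 0L ||
      length(reference_set$precursor) == 0L)
    stop("reference_set has an empty tier; build references first")
  if (is.null(names(reads)) && length(reads))
    names(reads) <- paste0("read", seq_along(reads))

  len <- nchar(reads)
  in_window <- len >= min_len & len <= max_len
  disposition <- rep("length_rejected", length(reads))
  names(disposition) <- names(reads)

  tier_hits <- function(idx, refs, tier) {
    if (length(idx) == 0L)
      return(data.frame(read_id = character(), ref_id = character(),
                        tier = character(), offset = integer(),
                        n_mm = integer(), n_equal_best = integer(),
                        stringsAsFactors = FALSE))
    seqs <- ref_seqs(refs)
    h <- align_scan(unname(reads[idx]), unname(seqs), as.integer(max_mm))
    neb <- as.integer(table(factor(h$read, levels = seq_along(idx))))
    data.frame(read_id = names(reads)[idx][h$read], ref_id = names(seqs)[h$ref],
               tier = rep(tier, nrow(h)), offset = h$offset, n_mm = h$n_mm,
               n_equal_best = neb[h$read], stringsAsFactors = FALSE)
  }

  idx1 <- which(in_window)
  hm <- tier_hits(idx1, reference_set$mature, "mature")
  mature_reads <- unique(hm$read_id)
  disposition[mature_reads] <- "mature"

  idx2 <- idx1[!names(reads)[idx1] %in% mature_reads]
  hp <- tier_hits(idx2, reference_set$precursor, "precursor")
  precursor_reads <- unique(hp$read_id)
  disposition[precursor_reads] <- "precursor"
  disposition[names(reads)[idx1][!names(reads)[idx1] %in%
                                 c(mature_reads, precursor_reads)]] <- "unmapped"

  hits <- rbind(hm, hp)
  structure(list(
    hits = hits,
    disposition = data.frame(read_id = names(reads),
                             disposition = unname(disposition),
                             stringsAsFactors = FALSE),
    reads = reads,
    summary = c(input = length(reads),
                mature = length(mature_reads),
                precursor = length(precursor_reads),
                unmapped = sum(disposition == "unmapped"),
                length_rejected = sum(disposition == "length_rejected"))),
    class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("mapping_result:\n")
  print(x$summary)
  invisible(x)
}

#' Uniquely placed hits
#'
#' The unique subset (exactly one equally best placement across the tier)
#' feeds per-position misincorporation profiling; multi-mapped reads would
#' smear signal between near-identical tRNA family members.
#'
#' @param mapping_result a `mapping_result` (or its `hits` data.frame).
#' @return hits data.frame restricted to `n_equal_best == 1`.
#' @export
select_unique <- function(mapping_result) {
  h <- if (inherits(mapping_result, "mapping_result")) mapping_result$hits
       else mapping_result
  h[h$n_equal_best == 1L, , drop = FALSE]
}

#' Fractional per-reference read weights
#'
#' Each mapped read contributes `1/n_equal_best` to every reference tied
#' for its best placement; weights therefore conserve the mapped read
#' count. Used for abundance counting (profiling uses [select_unique()]
#' instead).
#'
#' @param mapping_result a `mapping_result` (or its `hits` data.frame).
#' @return data.frame `read_id`, `ref_id`, `tier`, `weight`.
#' @export
fractional_weights <- function(mapping_result) {
  h <- if (inherits(mapping_result, "mapping_result")) mapping_result$hits
       else mapping_result
  # a read tied at several offsets of the SAME ref still counts once there
  key <- !duplicated(paste(h$read_id, h$ref_id))
  hu <- h[key, , drop = FALSE]
  nref <- table(hu$read_id)
  data.frame(read_id = hu$read_id, ref_id = hu$ref_id, tier = hu$tier,
             weight = 1 / as.numeric(nref[hu$read_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}
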