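BASES <- c("A", "C", "G", "T", "N")

#' Per-position base-count pileup from uniquely mapped reads
#'
#' Every aligned base of every uniquely placed read contributes once to the
#' base counts of its reference position. Coverage is `A+C+G+T` (an `N`
#' counts neither as coverage nor as mismatch), and the mismatch fraction at
#' a position is `(coverage - count of the reference base) / coverage`,
#' `NA` where coverage is zero (absence of evidence, never 0).
#'
#' @param mapping_result a `mapping_result`; only its unique-hit subset for
#'   the requested tier is used.
#' @param reference_set the `reference_set` mapped against.
#' @param tier `"mature"` (default) or `"precursor"`.
#' @return data.frame, all positions of every reference with at least one
#'   unique read: `ref_id`, `linear_pos` (1-based), `ref_base`, `A`, `C`,
#'   `G`, `T`, `N`, `coverage`, `fraction`.
#' @export
pileup <- function(mapping_result, reference_set, tier = "mature") {
  hits <- select_unique(mapping_result)
  hits <- hits[hits$tier == tier, , drop = FALSE]
  refs <- reference_set[[tier]]
  seqs <- ref_seqs(refs)
  if (nrow(hits) && any(!hits$ref_id %in% names(seqs)))
    stop("hit references a ref_id absent from the reference set")
  reads <- mapping_result$reads[hits$read_id]
  lens <- nchar(reads)

  pos <- unlist(lapply(seq_len(nrow(hits)), function(i)
    hits$offset[i] + seq_len(lens[i])), use.names = FALSE)
  base <- unlist(strsplit(unname(reads), ""), use.names = FALSE)
  refv <- rep(hits$ref_id, lens)

  out <- lapply(unique(hits$ref_id), function(rid) {
    L <- nchar(seqs[[rid]])
    sel <- refv == rid
    tab <- table(factor(pos[sel], levels = seq_len(L)),
                 factor(base[sel], levels = BASES))
    cnt <- matrix(as.integer(tab), nrow = L, ncol = 5,
                  dimnames = list(NULL, BASES))
    refb <- strsplit(seqs[[rid]], "")[[1]]
    cov <- as.integer(rowSums(cnt[, c("A", "C", "G", "T"), drop = FALSE]))
    refcnt <- cnt[cbind(seq_len(L), match(refb, BASES))]
    frac <- ifelse(cov > 0, (cov - refcnt) / cov, NA_real_)
    data.frame(ref_id = rid, linear_pos = seq_len(L), ref_base = refb,
               cnt, coverage = cov, fraction = frac,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  if (length(out) == 0L)
    return(data.frame(ref_id = character(), linear_pos = integer(),
                      ref_base = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), N = integer(),
                      coverage = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Tabulate misincorporation fractions on canonical coordinates
#'
#' Re-indexes a pileup to canonical position labels and applies the
#' coverage floor: positions with coverage below `min_coverage` keep their
#' coverage but get a `NA` fraction, so thin data can never masquerade as
#' a modification signal. Unnumbered references are emitted with their
#' linear index as label and flagged.
#'
#' @param profiles a pileup data.frame from [pileup()].
#' @param reference_set the matching `reference_set`.
#' @param sample sample label stored in the output rows.
#' @param min_coverage coverage floor (default 50).
#' @return data.frame (a misincorporation table): `sample`, `ref_id`,
#'   `canonical_pos`, `linear_pos`, `ref_base`, base counts, `coverage`,
#'   `fraction`, `numbered`.
#' @export
mismatch_fractions <- function(profiles, reference_set, sample = "sample1",
                               min_coverage = 50) {
  refs <- reference_set$mature
  names(refs) <- vapply(refs, `[[`, "", "ref_id")
  lab <- character(nrow(profiles))
  numbered <- logical(nrow(profiles))
  for (rid in unique(profiles$ref_id)) {
    sel <- profiles$ref_id == rid
    r <- refs[[rid]]
    if (!is.null(r) && isTRUE(r$numbered)) {
      lab[sel] <- r$labels[profiles$linear_pos[sel]]
      numbered[sel] <- TRUE
    } else {
      lab[sel] <- as.character(profiles$linear_pos[sel])
      numbered[sel] <- FALSE
    }
  }
  if (any(!numbered))
    warning("some references are unnumbered; their rows carry linear indices")
  frac <- ifelse(profiles$coverage >= min_coverage, profiles$fraction,
                 NA_real_)
  data.frame(sample = sample, ref_id = profiles$ref_id, canonical_pos = lab,
             linear_pos = profiles$linear_pos, ref_base = profiles$ref_base,
             profiles[BASES], coverage = profiles$coverage, fraction = frac,
             numbered = numbered, stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicate mean and standard deviation of misincorporation fractions
#'
#' @param tables_by_replicate list of misincorporation tables built against
#'   the same reference set.
#' @param policy `"complete"` (default): a cell is `NA` if any replicate is
#'   `NA`; `"available"`: summarize over non-`NA` replicates.
#' @return data.frame `ref_id`, `canonical_pos`, `ref_base`, `n_replicates`,
#'   `mean`, `sd` (sample sd, n-1), `mean_coverage`.
#' @export
replicate_summary <- function(tables_by_replicate, policy = c("complete",
                                                              "available")) {
  policy <- match.arg(policy)
  stopifnot(length(tables_by_replicate) >= 1L)
  key0 <- function(t) paste(t$ref_id, t$canonical_pos)
  k1 <- key0(tables_by_replicate[[1]])
  for (t in tables_by_replicate[-1])
    if (!identical(sort(key0(t)), sort(k1)))
      stop("replicates were built against different references")

  all <- do.call(rbind, tables_by_replicate)
  key <- paste(all$ref_id, all$canonical_pos)
  sp <- split(seq_len(nrow(all)), key)
  rows <- lapply(sp, function(ix) {
    f <- all$fraction[ix]
    use <- if (policy == "complete" && anyNA(f)) rep(FALSE, length(f))
           else !is.na(f)
    data.frame(ref_id = all$ref_id[ix[1]],
               canonical_pos = all$canonical_pos[ix[1]],
               ref_base = all$ref_base[ix[1]],
               n_replicates = length(ix),
               mean = if (any(use)) mean(f[use]) else NA_real_,
               sd = if (sum(use) >= 2L) sd(f[use]) else
                 if (sum(use) == 1L) NA_real_ else NA_real_,
               mean_coverage = mean(all$coverage[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$ref_id, suppressWarnings(as.numeric(out$canonical_pos)),
            out$canonical_pos), , drop = FALSE]
}

#' Base preferences among misincorporated reads at one position
#'
#' Distribution over non-reference bases, normalized over mismatching
#' reads only (`N` excluded). An empty named vector means no mismatches.
#'
#' @param profile pileup data.frame from [pileup()].
#' @param ref_id,linear_pos the position to interrogate.
#' @return named numeric over the mismatching bases, summing to 1 (or
#'   length 0).
#' @export
base_preferences <- function(profile, ref_id, linear_pos) {
  row <- profile[profile$ref_id == ref_id & profile$linear_pos == linear_pos, ]
  if (nrow(row) != 1L) stop("position not found in profile")
  cnt <- unlist(row[c("A", "C", "G", "T")])
  cnt <- cnt[names(cnt) != row$ref_base]
  cnt <- cnt[cnt > 0]
  if (length(cnt) == 0L) return(setNames(numeric(0), character(0)))
  cnt / sum(cnt)
}

#' Genome-browser display flag for a misincorporation fraction
#'
#' Mirrors the convention of coloring a position when at least 15% of
#' covering reads mismatch the reference.
#'
#' @param fraction numeric fraction(s) in `[0,1]` (`NA` passes through).
#' @param threshold display threshold (default 0.15).
#' @return logical of the same length.
#' @export
igv_flag <- function(fraction, threshold = 0.15) {
  fraction >= threshold
}

#' Write a misincorporation table as TSV
#' @param table misincorporation table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_misinc_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-reference bedGraph of misincorporation fractions
#'
#' One bedGraph track over reference-local coordinates, suitable for
#' browser display next to the reference FASTA.
#'
#' @param profile pileup data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  ok <- !is.na(profile$fraction)
  df <- data.frame(profile$ref_id[ok], profile$linear_pos[ok] - 1L,
                   profile$linear_pos[ok], signif(profile$fraction[ok], 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=misincorporation", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
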