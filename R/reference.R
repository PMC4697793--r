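#' Canonical (Sprinzl-style) position labels for a mature tRNA sequence
#'
#' Assigns the standard tRNA position labels (1-76, anticodon fixed at
#' 34-36, CCA at 74-76) to each linear index of a mature sequence. The
#' numbering is anchored on the anticodon and the invariant arm lengths of
#' the cloverleaf: acceptor stem + positions 8/9 are the first 9 nt; the
#' 25 nt preceding the 3' CCA (or 3' end) carry labels 49-73 (T arm,
#' acceptor 3' side and discriminator), which pins conserved T-loop
#' positions such as 58 regardless of variable-loop length; the anticodon
#' stem-loop spans labels 27-43 around the anticodon; whatever lies between
#' labels 43 and 49 is the variable loop (labels 44-48, long arms receive
#' `e`-suffixed insertions); the remainder between position 9 and 26 is the
#' D arm (labels 10-25, insertions suffixed after 17).
#'
#' The anticodon is located by exact search for the annotated anticodon
#' triplet within the window of cloverleaf-consistent placements; when a
#' secondary-structure string is supplied, only occurrences unpaired in the
#' structure are considered. If no consistent placement exists the sequence
#' is flagged unnumbered.
#'
#' @param sequence mature sequence, 5'->3', without CCA unless `has_cca`.
#' @param anticodon 3-nt DNA anticodon as encoded in the gene.
#' @param structure_string optional dot-bracket (`.><` or `.()`) string
#'   aligned to the pre-CCA mature sequence.
#' @param has_cca does `sequence` already end in the 3' CCA?
#' @return a list with `labels` (character vector, one label per linear
#'   index), `anticodon_index` (1-based index of position 34),
#'   `variable_loop_length` (nt), and `numbered` (logical; when `FALSE` the
#'   other fields are `NA`).
#' @export
assign_canonical_positions <- function(sequence, anticodon,
                                       structure_string = NULL,
                                       has_cca = TRUE) {
  seq_full <- toupper(sequence)
  body <- if (has_cca) substr(seq_full, 1L, nchar(seq_full) - 3L) else seq_full
  L <- nchar(body)
  fail <- list(labels = NA_character_, anticodon_index = NA_integer_,
               variable_loop_length = NA_integer_, numbered = FALSE)
  if (is.na(anticodon) || nchar(anticodon) != 3L || L < 60L) return(fail)

  # candidate 0-based indices of the first anticodon base (overlapping
  # occurrences included: gregexpr would miss e.g. CTC inside CTCTC)
  cand <- which(vapply(0:(L - 3L), function(i)
    substr(body, i + 1L, i + 3L) == anticodon, TRUE)) - 1L
  if (length(cand) == 0L) return(fail)

  paired <- NULL
  if (!is.null(structure_string) && !is.na(structure_string) &&
      nchar(structure_string) == L) {
    ch <- strsplit(structure_string, "")[[1]]
    paired <- ch %in% c(">", "<", "(", ")")
  }

  ok <- logical(length(cand))
  for (i in seq_along(cand)) {
    a <- cand[i]
    d <- a - 17L                  # D-region length (canonical 16)
    vl <- L - a - 35L             # variable-loop length
    ok[i] <- d >= 8L && d <= 24L && vl >= 3L && vl <= 24L
    if (ok[i] && !is.null(paired))
      ok[i] <- !any(paired[(a + 1L):(a + 3L)])
  }
  cand <- cand[ok]
  if (length(cand) == 0L) return(fail)
  a34 <- cand[which.min(abs(cand - 33L))]   # canonical layout puts 34 at index 33

  d <- a34 - 17L
  vl <- L - a34 - 35L

  d_mid <- d - 8L                 # between fixed 10-13 and 22-25
  mid_labels <- if (d_mid <= 8L) {
    as.character(13L + seq_len(d_mid))
  } else {
    c("14", "15", "16", "17", paste0("17", letters[seq_len(d_mid - 8L)]),
      "18", "19", "20", "21")
  }
  var_labels <- if (vl <= 5L) {
    as.character(43L + seq_len(vl))
  } else {
    c("44", "45", "46", "47", paste0("e", seq_len(vl - 5L)), "48")
  }

  labels <- c(as.character(1:9),
              as.character(10:13), mid_labels, as.character(22:25),
              "26",
              as.character(27:33),
              as.character(34:36),
              as.character(37:38),
              as.character(39:43),
              var_labels,
              as.character(49:73))
  if (has_cca) labels <- c(labels, "74", "75", "76")
  stopifnot(length(labels) == nchar(seq_full))
  list(labels = labels, anticodon_index = a34 + 1L,
       variable_loop_length = vl, numbered = TRUE)
}

#' Deduplicate mature tRNA sequences into the mature reference tier
#'
#' Genes whose intron-spliced bodies are byte-identical collapse into one
#' reference; members partition the input genes. A 3' CCA is appended by
#' default (sequenced fragments derive from CCA-bearing mature tRNA).
#' Reference ids are `isotype-anticodon-serial` with deterministic ordering
#' (isotype, anticodon, then lexicographic sequence).
#'
#' @param catalog a `trna_catalog`.
#' @param cca append 3' CCA (default `TRUE`).
#' @return list of mature reference records: `ref_id`, `sequence`,
#'   `member_gene_ids`, `labels` (canonical map), `numbered`,
#'   `g26_present`, `a34_present`, `variable_loop_length`.
#' @export
build_mature_refs <- function(catalog, cca = TRUE) {
  if (length(catalog) == 0L) return(list())
  mat <- vapply(catalog, mature_sequence, "")
  if (cca) mat <- paste0(mat, "CCA")
  ids <- vapply(catalog, `[[`, "", "gene_id")
  iso <- vapply(catalog, `[[`, "", "isotype")
  ac <- vapply(catalog, `[[`, "", "anticodon")
  st <- vapply(catalog, `[[`, "", "structure_string")

  first <- !duplicated(mat)
  uniq <- mat[first]
  ord <- order(iso[first], ac[first], uniq, method = "radix")
  uniq <- uniq[ord]
  ui <- which(first)[ord]

  serial <- stats::ave(seq_along(ui), paste(iso[ui], ac[ui]),
                       FUN = seq_along)
  refs <- vector("list", length(ui))
  for (k in seq_along(ui)) {
    i <- ui[k]
    members <- ids[mat == uniq[k]]
    num <- assign_canonical_positions(uniq[k], ac[i],
                                      structure_string = st[i],
                                      has_cca = cca)
    if (!num$numbered)
      warning(sprintf("reference %s-%s-%d could not be numbered; excluded from position-indexed output",
                      iso[i], ac[i], serial[k]))
    lab <- num$labels
    g26 <- a34p <- NA
    if (num$numbered) {
      g26 <- substr(uniq[k], match("26", lab), match("26", lab)) == "G"
      a34p <- substr(uniq[k], match("34", lab), match("34", lab)) == "A"
    }
    refs[[k]] <- list(ref_id = sprintf("%s-%s-%d", iso[i], ac[i], serial[k]),
                      sequence = uniq[k], member_gene_ids = members,
                      labels = lab, numbered = num$numbered,
                      g26_present = g26, a34_present = a34p,
                      variable_loop_length = num$variable_loop_length)
  }
  refs
}

#' Deduplicate precursor gene sequences into the precursor reference tier
#'
#' A precursor reference is upstream flank + gene body (introns retained) +
#' downstream flank; genes identical over that whole stretch collapse into
#' one reference named after the first member gene id (input order).
#'
#' @param catalog a `trna_catalog`.
#' @return list of precursor records: `ref_id`, `sequence`,
#'   `member_gene_ids`, `mature_sequence` (spliced body, no CCA), and
#'   `site_map` (integer vector mapping each mature index to its position
#'   on the precursor, used to place modifications on precursor molecules).
#' @export
build_precursor_refs <- function(catalog) {
  if (length(catalog) == 0L) return(list())
  pre <- vapply(catalog, function(g)
    paste0(g$upstream_flank, g$body_sequence, g$downstream_flank), "")
  ids <- vapply(catalog, `[[`, "", "gene_id")
  uniq <- pre[!duplicated(pre)]
  lapply(uniq, function(s) {
    g <- catalog[[match(s, pre)]]
    keep <- rep(TRUE, nchar(g$body_sequence))
    for (iv in g$intron_intervals) keep[(iv[1] + 1L):iv[2]] <- FALSE
    list(ref_id = g$gene_id, sequence = s,
         member_gene_ids = ids[pre == s],
         mature_sequence = mature_sequence(g),
         site_map = nchar(g$upstream_flank) + which(keep))
  })
}

#' Build the two-tier reference set
#'
#' @inheritParams build_mature_refs
#' @return object of class `reference_set` with elements `mature`,
#'   `precursor`, `provenance`.
#' @export
build_reference_set <- function(catalog, cca = TRUE) {
  structure(list(mature = build_mature_refs(catalog, cca = cca),
                 precursor = build_precursor_refs(catalog),
                 provenance = c(attr(catalog, "provenance"),
                                list(cca = cca, n_genes = length(catalog)))),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d mature ref(s), %d precursor ref(s), from %d gene(s)\n",
              length(x$mature), length(x$precursor),
              x$provenance$n_genes %||% NA_integer_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structural features relevant to Trm1 substrate prediction
#'
#' Trm1 installs m2,2G at position 26; its substrate preference depends on
#' features including variable-loop length, and G26 tRNAs with variable
#' loops shorter than 5 nt show essentially no modification. The predicted
#' target flag is therefore `g26_present & variable_loop_length >= varloop_min`.
#'
#' @param ref one mature reference record.
#' @param varloop_min minimum variable-loop length (nt) for a predicted
#'   Trm1 target (default 5).
#' @return list with `g26_present`, `a34_present`, `variable_loop_length`,
#'   `predicted_trm1_target` (all `NA` for unnumbered refs).
#' @export
structural_features <- function(ref, varloop_min = 5) {
  if (!isTRUE(ref$numbered))
    return(list(g26_present = NA, a34_present = NA,
                variable_loop_length = NA_integer_,
                predicted_trm1_target = NA))
  list(g26_present = ref$g26_present, a34_present = ref$a34_present,
       variable_loop_length = ref$variable_loop_length,
       predicted_trm1_target = isTRUE(ref$g26_present) &&
         ref$variable_loop_length >= varloop_min)
}

#' Feature table over all mature references
#'
#' @param reference_set a `reference_set`.
#' @param varloop_min passed to [structural_features()].
#' @return data.frame, one row per mature ref: `ref_id`, `g26`, `a34`,
#'   `varloop_len`, `predicted_trm1_target`, `n_members`, `length`,
#'   `numbered`.
#' @export
ref_features <- function(reference_set, varloop_min = 5) {
  refs <- reference_set$mature
  do.call(rbind, lapply(refs, function(r) {
    f <- structural_features(r, varloop_min)
    data.frame(ref_id = r$ref_id, g26 = f$g26_present, a34 = f$a34_present,
               varloop_len = f$variable_loop_length,
               predicted_trm1_target = f$predicted_trm1_target,
               n_members = length(r$member_gene_ids),
               length = nchar(r$sequence), numbered = r$numbered,
               stringsAsFactors = FALSE)
  }))
}

#' Reference base at a canonical position
#' @param ref mature reference record.
#' @param label canonical position label, e.g. `"26"`.
#' @return single base, or `NA` if the ref is unnumbered or lacks the label.
#' @export
base_at <- function(ref, label) {
  if (!isTRUE(ref$numbered)) return(NA_character_)
  i <- match(label, ref$labels)
  if (is.na(i)) return(NA_character_)
  substr(ref$sequence, i, i)
}

#' Write a reference set to disk
#'
#' Emits one FASTA per tier (headers carry the ref id and member gene ids)
#' and a TSV feature table for the mature tier.
#'
#' @param reference_set a `reference_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference_set <- function(reference_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mature = file.path(dir, "mature.fa"),
             precursor = file.path(dir, "precursor.fa"),
             features = file.path(dir, "mature_features.tsv"))
  for (tier in c("mature", "precursor")) {
    refs <- reference_set[[tier]]
    ss <- Biostrings::DNAStringSet(vapply(refs, `[[`, "", "sequence"))
    names(ss) <- vapply(refs, function(r)
      paste0(r$ref_id, " members=",
             paste(r$member_gene_ids, collapse = ",")), "")
    Biostrings::writeXStringSet(ss, paths[[tier]])
  }
  write.table(ref_features(reference_set), paths[["features"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
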