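#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet
#'   reverseComplement subseq
NULL

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a tRNA gene catalog from genome FASTA + GFF3 annotation
#'
#' Reads one record per annotated tRNA gene. Gene bodies are normalized to
#' gene orientation (minus-strand genes reverse-complemented so
#' `body_sequence` reads 5'->3'), introns are converted to gene-relative
#' 0-based half-open intervals, and up/downstream flanks of `flank_len` nt
#' are extracted in gene orientation (truncated with a warning at contig
#' edges).
#'
#' The annotation is GFF3 with feature type `tRNA` (attributes `ID`,
#' `isotype`, `anticodon`, optional `structure` - a dot/bracket string
#' aligned to the gene body) and intron features of type `tRNA_intron` with a
#' `Parent` attribute. Mitochondrial and pseudogene records are excluded by
#' default (the nuclear gene set is the usual analysis unit).
#'
#' @param fasta_path genome FASTA.
#' @param annotation_path GFF3 annotation (see Details).
#' @param flank_len nt of genomic flank to attach on each side (default 40);
#'   flanks become part of the precursor references.
#' @param exclude_mito,exclude_pseudo drop genes on mitochondrial contigs
#'   (seqid matching `MT`/`mito`/`chrM`) or with isotype `Pseudo`/`Und`.
#' @return an object of class `trna_catalog`: a list of gene records with
#'   fields `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `body_sequence`, `intron_intervals` (gene-relative 0-based
#'   half-open), `upstream_flank`, `downstream_flank`, `isotype`,
#'   `anticodon`, `structure_string`.
#' @export
parse_gene_catalog <- function(fasta_path, annotation_path, flank_len = 40,
                               exclude_mito = TRUE, exclude_pseudo = TRUE) {
  stopifnot(flank_len >= 0)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  gff <- rtracklayer::import(annotation_path)
  type <- as.character(gff$type)
  genes_gr <- gff[type == "tRNA"]
  introns_gr <- gff[type == "tRNA_intron"]

  if (length(genes_gr) == 0L) {
    warning("annotation contains no tRNA records; returning empty catalog")
    return(structure(list(), class = "trna_catalog",
                     provenance = list(fasta = fasta_path,
                                       annotation = annotation_path,
                                       flank_len = flank_len)))
  }

  meta <- S4Vectors::mcols(genes_gr)
  ids <- as.character(meta$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("every tRNA record needs an ID attribute")
  isotype <- if ("isotype" %in% names(meta)) as.character(meta$isotype)
             else rep(NA_character_, length(genes_gr))
  anticodon <- if ("anticodon" %in% names(meta)) as.character(meta$anticodon)
               else rep(NA_character_, length(genes_gr))
  structure_s <- if ("structure" %in% names(meta)) as.character(meta$structure)
                 else rep(NA_character_, length(genes_gr))

  keep <- rep(TRUE, length(genes_gr))
  if (exclude_mito)
    keep <- keep & !grepl("^(MT|chrM|mito)", as.character(GenomicRanges::seqnames(genes_gr)),
                          ignore.case = TRUE)
  if (exclude_pseudo)
    keep <- keep & !(isotype %in% c("Pseudo", "pseudo", "Und", "Undet"))

  intron_parent <- if (length(introns_gr))
    sub("^.*:", "", as.character(unlist(introns_gr$Parent))) else character()

  out <- vector("list", sum(keep))
  oi <- 0L
  for (i in which(keep)) {
    chrom <- as.character(GenomicRanges::seqnames(genes_gr)[i])
    if (!chrom %in% names(genome))
      stop(sprintf("gene %s: chromosome '%s' absent from FASTA", ids[i], chrom))
    clen <- length(genome[[chrom]])
    g1 <- GenomicRanges::start(genes_gr)[i]   # 1-based inclusive (GFF)
    g2 <- GenomicRanges::end(genes_gr)[i]
    strand <- as.character(GenomicRanges::strand(genes_gr)[i])
    if (!strand %in% c("+", "-"))
      stop(sprintf("gene %s: strand must be + or -", ids[i]))
    s0 <- g1 - 1L; e0 <- g2                   # internal 0-based half-open
    body <- as.character(Biostrings::subseq(genome[[chrom]], g1, g2))

    # flanks in genomic orientation first
    up1 <- max(1L, g1 - flank_len); up2 <- g1 - 1L
    dn1 <- g2 + 1L; dn2 <- min(clen, g2 + flank_len)
    up <- if (up2 >= up1) as.character(Biostrings::subseq(genome[[chrom]], up1, up2)) else ""
    dn <- if (dn2 >= dn1) as.character(Biostrings::subseq(genome[[chrom]], dn1, dn2)) else ""
    if (flank_len > 0 && (nchar(up) < flank_len || nchar(dn) < flank_len))
      warning(sprintf("gene %s: flank truncated at contig edge", ids[i]))

    if (strand == "-") {
      body <- revcomp_chr(body)
      tmp <- up
      up <- revcomp_chr(dn)
      dn <- revcomp_chr(tmp)
    }

    # introns -> gene-relative half-open intervals in gene orientation
    iv <- list()
    sel <- which(intron_parent == ids[i])
    for (k in sel) {
      i1 <- GenomicRanges::start(introns_gr)[k] - 1L
      i2 <- GenomicRanges::end(introns_gr)[k]
      rel <- if (strand == "+") c(i1 - s0, i2 - s0) else c(e0 - i2, e0 - i1)
      if (rel[1] < 0 || rel[2] > nchar(body) || rel[1] >= rel[2] ||
          rel[1] == 0 || rel[2] == nchar(body))
        stop(sprintf("gene %s: intron not strictly inside gene body", ids[i]))
      iv[[length(iv) + 1L]] <- rel
    }
    if (length(iv) > 1L) {
      ord <- order(vapply(iv, `[`, 0, 1L))
      iv <- iv[ord]
      for (k in seq_len(length(iv) - 1L))
        if (iv[[k]][2] > iv[[k + 1L]][1])
          stop(sprintf("gene %s: overlapping introns", ids[i]))
    }

    oi <- oi + 1L
    out[[oi]] <- list(gene_id = ids[i], chrom = chrom, start = s0, end = e0,
                      strand = strand, body_sequence = body,
                      intron_intervals = iv,
                      upstream_flank = up, downstream_flank = dn,
                      isotype = isotype[i], anticodon = anticodon[i],
                      structure_string = structure_s[i])
  }
  structure(out, class = "trna_catalog",
            provenance = list(fasta = fasta_path, annotation = annotation_path,
                              flank_len = flank_len))
}

#' Mature (intron-spliced) sequence of one gene record
#'
#' Joins the exonic segments of `body_sequence`; no CCA is added here.
#' @param gene one element of a `trna_catalog`.
#' @return character scalar.
#' @export
mature_sequence <- function(gene) {
  body <- gene$body_sequence
  if (length(gene$intron_intervals) == 0L) return(body)
  keep <- rep(TRUE, nchar(body))
  for (iv in gene$intron_intervals) keep[(iv[1] + 1L):iv[2]] <- FALSE
  paste(strsplit(body, "")[[1]][keep], collapse = "")
}

#' @export
print.trna_catalog <- function(x, ...) {
  cat(sprintf("trna_catalog: %d gene(s)\n", length(x)))
  if (length(x)) {
    n_int <- sum(vapply(x, function(g) length(g$intron_intervals) > 0, TRUE))
    cat(sprintf("  intron-containing: %d; strands: %s\n", n_int,
                paste(names(table(vapply(x, `[[`, "", "strand"))),
                      collapse = "/")))
  }
  invisible(x)
}

#' @export
as.data.frame.trna_catalog <- function(x, ...) {
  data.frame(
    gene_id = vapply(x, `[[`, "", "gene_id"),
    chrom = vapply(x, `[[`, "", "chrom"),
    strand = vapply(x, `[[`, "", "strand"),
    isotype = vapply(x, `[[`, "", "isotype"),
    anticodon = vapply(x, `[[`, "", "anticodon"),
    body_len = vapply(x, function(g) nchar(g$body_sequence), 0L),
    n_introns = vapply(x, function(g) length(g$intron_intervals), 0L),
    stringsAsFactors = FALSE
  )
}
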