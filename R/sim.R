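AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Cloverleaf-layout mature body (no CCA): acceptor 7 + pos8/9 + D region +
# G/N26 + AC stem-loop (anticodon fixed at the canonical slot) + variable
# loop + 25-nt T-arm/acceptor-3' block with the conserved T54/T55/C56 and
# A58.
random_mature_body <- function(anticodon, g26 = TRUE, varloop_len = 5,
                               d_len = 16) {
  t_block <- strsplit(rand_dna(25), "")[[1]]
  t_block[6:8] <- c("T", "T", "C")   # labels 54-56
  t_block[10] <- "A"                 # label 58
  paste0(rand_dna(7), "T", "G",                        # 1-7, 8, 9
         rand_dna(d_len),                              # 10-25 region
         if (g26) "G" else sample(c("A", "C", "T"), 1),# 26
         rand_dna(5), "C", "T",                        # 27-31, 32, 33
         anticodon,                                    # 34-36
         "A", rand_dna(1), rand_dna(5),                # 37, 38, 39-43
         rand_dna(varloop_len),                        # variable loop
         paste(t_block, collapse = ""))                # 49-73
}

make_gene <- function(gene_id, mature_body, isotype, anticodon,
                      intron_len = 0, flank_len = 40, a34 = NULL) {
  if (intron_len > 0) {
    # canonical tRNA intron site: immediately 3' of position 37
    if (is.null(a34)) a34 <- 33L  # 0-based index of first anticodon base
    cut <- a34 + 4L               # after label 37
    body <- paste0(substr(mature_body, 1, cut), rand_dna(intron_len),
                   substr(mature_body, cut + 1, nchar(mature_body)))
    introns <- list(c(cut, cut + intron_len))
  } else {
    body <- mature_body
    introns <- list()
  }
  list(gene_id = gene_id, chrom = NA_character_, start = NA_integer_,
       end = NA_integer_, strand = sample(c("+", "-"), 1),
       body_sequence = body, intron_intervals = introns,
       upstream_flank = rand_dna(flank_len),
       downstream_flank = rand_dna(flank_len),
       isotype = isotype, anticodon = anticodon,
       structure_string = NA_character_)
}

#' Simulate a toy tRNA gene catalog
#'
#' Generates cloverleaf-layout tRNA genes with realistic part lengths
#' (acceptor stem, D arm, anticodon stem-loop with the annotated anticodon
#' at canonical 34-36, variable loop, 25-nt T-arm block with conserved
#' A58), optional canonical-site introns, random genomic flanks, and mixed
#' strands. Useful as test input and as the substrate for
#' [simulate_library()].
#'
#' @param n_mature number of distinct mature sequences.
#' @param copies integer vector of gene copies per mature (recycled;
#'   default 1 each).
#' @param g26_frac,a34_frac fraction of matures with G at 26 / anticodons
#'   starting with A (inosine-34 candidates).
#' @param short_varloop_frac fraction of G26 matures given a <5 nt variable
#'   loop (Trm1 non-target architecture).
#' @param intron_frac fraction of gene copies carrying an intron (8-20 nt).
#' @param flank_len genomic flank length per side.
#' @param seed optional RNG seed for reproducibility.
#' @return a `trna_catalog` (genes carry placeholder genomic coordinates
#'   until written with [write_gene_catalog()]).
#' @export
simulate_gene_catalog <- function(n_mature = 8, copies = 1, g26_frac = 0.6,
                                  a34_frac = 0.2, short_varloop_frac = 0.2,
                                  intron_frac = 0.25, flank_len = 40,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  copies <- rep_len(copies, n_mature)
  g26 <- runif(n_mature) < g26_frac
  n_short <- round(sum(g26) * short_varloop_frac)
  short <- rep(FALSE, n_mature)
  short[sample(which(g26), n_short)] <- TRUE

  genes <- list()
  seen <- character()
  for (i in seq_len(n_mature)) {
    first <- if (runif(1) < a34_frac) "A" else sample(c("C", "G", "T"), 1)
    ac <- paste0(first, rand_dna(2))
    iso <- sample(AA3, 1)
    vl <- if (short[i]) 4L else sample(5:13, 1)
    repeat {
      body <- random_mature_body(ac, g26 = g26[i], varloop_len = vl)
      if (!body %in% seen) break
    }
    seen <- c(seen, body)
    for (k in seq_len(copies[i])) {
      ilen <- if (runif(1) < intron_frac) sample(8:20, 1) else 0L
      genes[[length(genes) + 1L]] <-
        make_gene(sprintf("t%02d.%d", i, k), body, iso, ac,
                  intron_len = ilen, flank_len = flank_len)
    }
  }
  structure(genes, class = "trna_catalog",
            provenance = list(source = "simulate_gene_catalog",
                              flank_len = flank_len, seed = seed))
}

#' Synthetic catalog with fission-yeast-like uniqueness accounting
#'
#' A SYNTHETIC stand-in (not real genomic data) for a nuclear tRNA gene
#' catalog: 171 genes collapsing to 61 unique mature sequences with 45
#' distinct anticodons, 150 unique precursor gene sequences (21 gene copies
#' are exact precursor-level duplicates of a sibling), 36 matures with G at
#' position 26 (9 of them with a <5 nt variable loop, the Trm1 non-target
#' architecture) and 11 matures with encoded A34. The sequences themselves
#' are random within the cloverleaf layout; only the uniqueness/feature
#' accounting is engineered. Intended for exercising the reference builder
#' and mapper at genome-catalog scale.
#'
#' @param flank_len genomic flank per side (default 40).
#' @param seed RNG seed (default 2026).
#' @return a `trna_catalog` of 171 genes.
#' @export
synthetic_pombe_catalog <- function(flank_len = 40, seed = 2026) {
  set.seed(seed)
  n_mature <- 61L
  # 45 distinct anticodons; 16 are carried by two matures each.
  # A-start anticodons: 9 distinct, 2 of them reused -> 11 A34 matures.
  repeat {
    ac_a <- unique(paste0("A", replicate(30, rand_dna(2))))[1:9]
    ac_o <- unique(vapply(1:200, function(i)
      paste0(sample(c("C", "G", "T"), 1), rand_dna(2)), ""))[1:36]
    if (!anyNA(ac_a) && !anyNA(ac_o) && !any(ac_a %in% ac_o)) break
  }
  anticodons <- c(ac_a, ac_o, ac_a[1:2], ac_o[1:14])  # 61 slots
  iso_pool <- rep_len(AA3, 45)
  isotypes <- c(iso_pool, iso_pool[c(1:2, 10:23)])

  # 36 G26 matures; 9 of those get a short (<5 nt) variable loop.
  g26 <- sample(c(rep(TRUE, 36), rep(FALSE, 25)))
  short <- rep(FALSE, n_mature)
  short[sample(which(g26), 9)] <- TRUE

  copies <- c(rep(5L, 15), rep(4L, 10), rep(3L, 8), rep(2L, 4), rep(1L, 24))
  stopifnot(sum(copies) == 171L, length(copies) == n_mature)

  genes <- list()
  seen <- character()
  for (i in seq_len(n_mature)) {
    vl <- if (short[i]) 4L else sample(5:13, 1)
    repeat {
      body <- random_mature_body(anticodons[i], g26 = g26[i],
                                 varloop_len = vl)
      if (!body %in% seen) break
    }
    seen <- c(seen, body)
    ilen <- if (runif(1) < 0.2) sample(8:16, 1) else 0L
    for (k in seq_len(copies[i]))
      genes[[length(genes) + 1L]] <-
        make_gene(sprintf("t%03d.%d", i, k), body, isotypes[i],
                  anticodons[i], intron_len = ilen, flank_len = flank_len)
  }
  # 21 precursor-level duplicates: second copy of the first 21 multi-copy
  # matures becomes byte-identical (flanks included) to the first copy.
  ids <- vapply(genes, `[[`, "", "gene_id")
  multi <- which(copies >= 2L)[1:21]
  for (i in multi) {
    a <- which(ids == sprintf("t%03d.1", i))
    b <- which(ids == sprintf("t%03d.2", i))
    dup <- genes[[a]]
    dup$gene_id <- genes[[b]]$gene_id
    genes[[b]] <- dup
  }
  structure(genes, class = "trna_catalog",
            provenance = list(source = "synthetic_pombe_catalog (synthetic)",
                              flank_len = flank_len, seed = seed))
}

#' Write a simulated catalog as genome FASTA + GFF3
#'
#' Lays the genes out on three chromosomes separated by random spacers,
#' reverse-complementing minus-strand genes into genomic orientation, and
#' writes a GFF3 with `tRNA` records (attributes `ID`, `isotype`,
#' `anticodon`) and `tRNA_intron` child records. Round-trips through
#' [parse_gene_catalog()].
#'
#' @param catalog a `trna_catalog` from [simulate_gene_catalog()] or
#'   [synthetic_pombe_catalog()].
#' @param dir output directory.
#' @param spacer nt of random sequence between gene neighborhoods.
#' @return named character vector with paths `fasta` and `gff`.
#' @export
write_gene_catalog <- function(catalog, dir, spacer = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_chr <- min(3L, max(1L, length(catalog)))
  chr_of <- rep(seq_len(n_chr), length.out = length(catalog))
  chr_seq <- setNames(rep("", n_chr), paste0("chr", seq_len(n_chr)))

  rows <- list()
  for (i in seq_along(catalog)) {
    g <- catalog[[i]]
    chrom <- paste0("chr", chr_of[i])
    seg <- paste0(g$upstream_flank, g$body_sequence, g$downstream_flank)
    if (g$strand == "-") seg <- revcomp_chr(seg)
    base <- nchar(chr_seq[[chrom]]) + spacer   # 0-based start of segment
    chr_seq[[chrom]] <- paste0(chr_seq[[chrom]], rand_dna(spacer), seg)
    flank_up <- nchar(g$upstream_flank)
    flank_dn <- nchar(g$downstream_flank)
    blen <- nchar(g$body_sequence)
    gs0 <- base + (if (g$strand == "+") flank_up else flank_dn)
    ge0 <- gs0 + blen
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = chrom, type = "tRNA", start = gs0 + 1L, end = ge0,
      strand = g$strand, id = g$gene_id, parent = NA_character_,
      isotype = g$isotype, anticodon = g$anticodon,
      stringsAsFactors = FALSE)
    for (k in seq_along(g$intron_intervals)) {
      iv <- g$intron_intervals[[k]]
      gcoord <- if (g$strand == "+") c(gs0 + iv[1], gs0 + iv[2])
                else c(ge0 - iv[2], ge0 - iv[1])
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = chrom, type = "tRNA_intron", start = gcoord[1] + 1L,
        end = gcoord[2], strand = g$strand,
        id = paste0(g$gene_id, ".intron", k), parent = g$gene_id,
        isotype = NA_character_, anticodon = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqid,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$parent), NA, df$parent)
  S4Vectors::mcols(gr)$isotype <- df$isotype
  S4Vectors::mcols(gr)$anticodon <- df$anticodon

  fasta <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chr_seq), fasta)
  rtracklayer::export(gr, gff, format = "gff3")
  c(fasta = fasta, gff = gff)
}

#' Simulation configuration
#'
#' Bundles and validates everything [simulate_library()] needs. Relative
#' abundances default to the number of member genes per mature reference
#' (tRNA abundance roughly tracks gene copy number). The modification spec
#' gives, per (mature ref, canonical position): the modification efficiency
#' `m` (the mole fraction of molecules carrying the modification), the
#' misread-given-modified probability `q` (how often the RT inserts a wrong
#' base over a modified site), and optionally a substitution preference
#' distribution over non-reference bases (uniform if omitted).
#'
#' @param reference_set a `reference_set`.
#' @param n_fragments fragments to emit.
#' @param mods data.frame with columns `ref_id`, `canonical_pos`, `m`, `q`
#'   and optionally a list-column `prefs` of named numeric vectors.
#' @param abundance optional named numeric over mature ref ids.
#' @param error_rate uniform per-base sequencing error (default 0.003).
#' @param len_min,len_max fragment window (defaults 19, 35 - the gel
#'   selection of the protocol).
#' @param precursor_frac fraction of fragments drawn from precursor
#'   molecules (leader + body with introns + trailer); default 0.05.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(reference_set, n_fragments = 10000, mods = NULL,
                       abundance = NULL, error_rate = 0.003,
                       len_min = 19, len_max = 35, precursor_frac = 0.05,
                       seed = NULL) {
  stopifnot(inherits(reference_set, "reference_set"),
            len_min <= len_max, n_fragments >= 1,
            error_rate >= 0, error_rate <= 1,
            precursor_frac >= 0, precursor_frac <= 1)
  mature_ids <- vapply(reference_set$mature, `[[`, "", "ref_id")
  if (is.null(abundance)) {
    abundance <- vapply(reference_set$mature, function(r)
      length(r$member_gene_ids), 0)
    names(abundance) <- mature_ids
  }
  stopifnot(all(names(abundance) %in% mature_ids), all(abundance >= 0),
            sum(abundance) > 0)
  abundance <- abundance / sum(abundance)
  if (is.null(mods))
    mods <- data.frame(ref_id = character(), canonical_pos = character(),
                       m = numeric(), q = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("ref_id", "canonical_pos", "m", "q") %in% names(mods)),
            all(mods$m >= 0 & mods$m <= 1), all(mods$q >= 0 & mods$q <= 1),
            all(mods$ref_id %in% mature_ids))
  min_len_all <- min(vapply(reference_set$mature, function(r)
    nchar(r$sequence), 0L))
  if (min_len_all < len_min)
    stop("fragment window infeasible for the shortest reference")
  structure(list(reference_set = reference_set, n_fragments = n_fragments,
                 mods = mods, abundance = abundance,
                 error_rate = error_rate, len_min = len_min,
                 len_max = len_max, precursor_frac = precursor_frac,
                 seed = seed),
            class = "sim_config")
}

# two uniform cut sites per molecule; keep only window-passing fragments
draw_fragments <- function(lens, len_min, len_max) {
  n <- length(lens)
  start <- integer(n); flen <- integer(n)
  todo <- seq_len(n)
  for (it in 1:1000) {
    c1 <- floor(runif(length(todo)) * (lens[todo] + 1))
    c2 <- floor(runif(length(todo)) * (lens[todo] + 1))
    s <- pmin(c1, c2); l <- abs(c2 - c1)
    ok <- l >= len_min & l <= len_max
    start[todo[ok]] <- as.integer(s[ok])
    flen[todo[ok]] <- as.integer(l[ok])
    todo <- todo[!ok]
    if (length(todo) == 0L) break
  }
  if (length(todo)) stop("rejection sampling failed to fill the window")
  list(start = start, len = flen)
}

#' Analytic expected misincorporation fraction
#'
#' The observed mismatch fraction at a site with modification efficiency
#' `m`, misread-given-modified probability `q` and uniform per-base
#' sequencing error `e` is `m*q + (1 - m*q)*e` (error toward any
#' non-reference base counts as a mismatch). The simulator's error model
#' can flip a misread base back to the reference with probability `e/3`,
#' so the formula is exact up to a term of order `m*q*e/3`.
#'
#' @param m,q,e probabilities (vectorized).
#' @return expected observed mismatch fraction.
#' @export
expected_misinc <- function(m, q, e) {
  stopifnot(all(m >= 0 & m <= 1), all(q >= 0 & q <= 1), all(e >= 0 & e <= 1))
  m * q + (1 - m * q) * e
}

#' Simulate a tRNA-HydroSeq fragment library with ground truth
#'
#' Fragments are drawn molecule by molecule: a source molecule (mature
#' reference, or with probability `precursor_frac` a precursor molecule)
#' is chosen by relative abundance, two hydrolysis cut sites fall uniformly
#' on it, and the fragment is kept only if its length lies in the gel
#' window (rejection sampling mimics size selection). Each covered
#' modifiable site then carries the modification with probability `m`
#' (per molecule); a modified site is read as a wrong base with
#' probability `q` using the site's substitution preference; finally every
#' base is flipped to a uniformly chosen different base with probability
#' `error_rate`. Qualities are constant Q40. Same seed, same library,
#' byte for byte.
#'
#' @param config a `sim_config`.
#' @param fastq_path optional path; when given the library is also written
#'   as FASTQ.
#' @return object of class `sim_library`: `reads` (named character),
#'   `truth` (list: `fragments` per-fragment source table, `sites`
#'   per-fragment modification states, `expected` per-site analytic
#'   expectations), and `config`.
#' @export
simulate_library <- function(config, fastq_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rs <- config$reference_set
  mature <- rs$mature
  mature_ids <- vapply(mature, `[[`, "", "ref_id")
  mature_seq <- vapply(mature, `[[`, "", "sequence")
  pre_ids <- vapply(rs$precursor, `[[`, "", "ref_id")
  pre_seq <- vapply(rs$precursor, `[[`, "", "sequence")
  pre_w <- vapply(rs$precursor, function(r) length(r$member_gene_ids), 0)

  n <- config$n_fragments
  is_pre <- runif(n) < config$precursor_frac
  src <- integer(n)
  src[!is_pre] <- sample.int(length(mature), sum(!is_pre), replace = TRUE,
                             prob = config$abundance[mature_ids])
  if (any(is_pre))
    src[is_pre] <- sample.int(length(pre_seq), sum(is_pre), replace = TRUE,
                              prob = pre_w / sum(pre_w))
  mol_seq <- ifelse(is_pre, pre_seq[src], mature_seq[src])
  frag <- draw_fragments(nchar(mol_seq), config$len_min, config$len_max)
  reads <- substr(mol_seq, frag$start + 1L, frag$start + frag$len)

  chars <- strsplit(reads, "")
  site_rows <- list()
  if (nrow(config$mods)) {
    lab_idx <- function(ref_i, pos)
      match(pos, mature[[ref_i]]$labels)
    for (k in seq_len(nrow(config$mods))) {
      ri <- match(config$mods$ref_id[k], mature_ids)
      li <- lab_idx(ri, config$mods$canonical_pos[k])
      if (is.na(li)) next
      refb <- substr(mature_seq[ri], li, li)
      prefs <- NULL
      if (!is.null(config$mods$prefs)) prefs <- config$mods$prefs[[k]]
      if (is.null(prefs)) {
        others <- setdiff(c("A", "C", "G", "T"), refb)
        prefs <- setNames(rep(1 / 3, 3), others)
      }
      # the modification sits on the mature molecules of this reference
      # and, at the homologous position, on the precursor molecules of its
      # member genes (the methyltransferase acts on pre-tRNA as well)
      body <- substr(mature_seq[ri], 1L, nchar(mature_seq[ri]) -
                       if (isTRUE(rs$provenance$cca)) 3L else 0L)
      targets <- list(list(sel = !is_pre & src == ri, idx = li,
                           src_id = mature_ids[ri], tier = "mature"))
      if (li <= nchar(body)) {
        for (p in seq_along(rs$precursor)) {
          pr <- rs$precursor[[p]]
          if (identical(pr$mature_sequence, body))
            targets[[length(targets) + 1L]] <-
              list(sel = is_pre & src == p, idx = pr$site_map[li],
                   src_id = pre_ids[p], tier = "precursor")
        }
      }
      for (tg in targets) {
        covers <- which(tg$sel & frag$start < tg$idx &
                          frag$start + frag$len >= tg$idx)
        if (length(covers) == 0L) next
        modified <- runif(length(covers)) < config$mods$m[k]
        misread <- modified & runif(length(covers)) < config$mods$q[k]
        nb <- sample(names(prefs), sum(misread), replace = TRUE,
                     prob = prefs)
        local <- tg$idx - frag$start[covers]
        wm <- which(misread)
        for (j in seq_along(wm))
          chars[[covers[wm[j]]]][local[wm[j]]] <- nb[j]
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          fragment = covers, ref_id = config$mods$ref_id[k],
          source_ref = tg$src_id, tier = tg$tier,
          canonical_pos = config$mods$canonical_pos[k],
          linear_pos = tg$idx, modified = modified, misread = misread,
          stringsAsFactors = FALSE)
      }
    }
  }

  # uniform sequencing error: flip to a uniformly chosen different base
  if (config$error_rate > 0) {
    lens <- frag$len
    flat <- unlist(chars, use.names = FALSE)
    hit <- which(runif(length(flat)) < config$error_rate)
    if (length(hit)) {
      cur <- flat[hit]
      repl <- vapply(cur, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      flat[hit] <- repl
      chars <- split(flat, rep(seq_along(lens), lens))
    }
  }
  reads <- vapply(chars, paste, "", collapse = "")
  names(reads) <- sprintf("frag%06d", seq_len(n))

  expected <- if (nrow(config$mods)) {
    data.frame(ref_id = config$mods$ref_id,
               canonical_pos = config$mods$canonical_pos,
               m = config$mods$m, q = config$mods$q,
               e = config$error_rate,
               expected_fraction = expected_misinc(config$mods$m,
                                                   config$mods$q,
                                                   config$error_rate),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ref_id = character(), canonical_pos = character(),
               m = numeric(), q = numeric(), e = numeric(),
               expected_fraction = numeric(), stringsAsFactors = FALSE)
  }
  truth <- list(
    fragments = data.frame(
      fragment_id = names(reads),
      tier = ifelse(is_pre, "precursor", "mature"),
      source_ref = ifelse(is_pre, pre_ids[src], mature_ids[src]),
      start = frag$start, length = frag$len, stringsAsFactors = FALSE),
    sites = if (length(site_rows)) do.call(rbind, site_rows)
            else data.frame(),
    expected = expected)
  out <- structure(list(reads = reads, truth = truth, config = config),
                   class = "sim_library")
  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  out
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("sim_library: %d fragments (%d precursor-derived), %d modification site spec(s)\n",
              length(x$reads),
              sum(x$truth$fragments$tier == "precursor"),
              nrow(x$config$mods)))
  invisible(x)
}
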