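REQUIRED_BASE <- c("9" = "G", "26" = "G", "32" = "C", "34" = "A", "58" = "A")

#' Classify Trm1 targets from G26 misincorporation
#'
#' In a wild-type-like reference condition, Trm1 target tRNAs show
#' substantial G26 misincorporation while non-targets sit at background.
#' References without G26 are unassessed; a fraction at or above
#' `target_threshold` calls a target, at or below `background_ceiling` a
#' non-target, and the band in between is reported as ambiguous rather
#' than silently assigned (the two operating thresholds leave a gap).
#'
#' @param misinc_table misincorporation table (possibly several samples;
#'   the `sample` column is the condition label).
#' @param features mature-ref feature table from [ref_features()].
#' @param reference_condition sample label used for classification.
#' @param target_threshold call a target at or above this fraction
#'   (default 0.10).
#' @param background_ceiling call a non-target at or below this fraction
#'   (default 0.01).
#' @return object of class `mod_call_set`: list with `calls` (data.frame
#'   `ref_id`, `g26_fraction`, `target_status`, `reason`), `fractions`
#'   (long data.frame of G26 fractions per condition), and `thresholds`.
#' @export
call_trm1_targets <- function(misinc_table, features, reference_condition,
                              target_threshold = 0.10,
                              background_ceiling = 0.01) {
  stopifnot(target_threshold >= background_ceiling)
  if (!reference_condition %in% misinc_table$sample)
    stop(sprintf("reference condition '%s' absent from table",
                 reference_condition))
  g26 <- misinc_table[misinc_table$canonical_pos == "26", , drop = FALSE]
  calls <- lapply(seq_len(nrow(features)), function(i) {
    rid <- features$ref_id[i]
    row <- g26[g26$ref_id == rid & g26$sample == reference_condition, ]
    f <- if (nrow(row) == 1L) row$fraction else NA_real_
    if (!isTRUE(features$g26[i]))
      return(data.frame(ref_id = rid, g26_fraction = NA_real_,
                        target_status = "unassessed",
                        reason = "no G26", stringsAsFactors = FALSE))
    if (is.na(f))
      return(data.frame(ref_id = rid, g26_fraction = NA_real_,
                        target_status = "unassessed",
                        reason = "insufficient coverage",
                        stringsAsFactors = FALSE))
    status <- if (f >= target_threshold) "target"
              else if (f <= background_ceiling) "non-target"
              else "ambiguous"
    data.frame(ref_id = rid, g26_fraction = f, target_status = status,
               reason = "", stringsAsFactors = FALSE)
  })
  structure(list(calls = do.call(rbind, calls),
                 fractions = g26[, c("sample", "ref_id", "fraction",
                                     "coverage")],
                 thresholds = c(target_threshold = target_threshold,
                                background_ceiling = background_ceiling,
                                reference_condition = reference_condition)),
            class = "mod_call_set")
}

#' @export
print.mod_call_set <- function(x, ...) {
  cat("mod_call_set:\n")
  print(table(x$calls$target_status))
  invisible(x)
}

#' Per-position subset tables at the classic misincorporation positions
#'
#' Restricts a misincorporation table, per canonical position, to the
#' references that carry the modifiable reference base there (G for 9 and
#' 26, C for 32, A for 34 and 58 - the m1G9 / m2,2G26 / m3C32 / inosine-34
#' / m1A58 readouts).
#'
#' @param misinc_table misincorporation table.
#' @param positions canonical labels (default the five above).
#' @return named list of data.frames, one per position.
#' @export
position_subsets <- function(misinc_table,
                             positions = c("9", "26", "32", "34", "58")) {
  setNames(lapply(positions, function(p) {
    t <- misinc_table[misinc_table$canonical_pos == p, , drop = FALSE]
    need <- REQUIRED_BASE[p]
    if (!is.na(need)) t <- t[t$ref_base == need, , drop = FALSE]
    row.names(t) <- NULL
    t
  }), positions)
}

#' Paired comparison of misincorporation between two conditions
#'
#' Two-sided paired t test on per-reference fractions at one canonical
#' position, over references non-missing in both conditions. All-zero
#' differences return `t = 0, p = 1` by convention.
#'
#' @param table_a,table_b misincorporation tables for the two conditions.
#' @param position canonical label, e.g. `"26"`.
#' @param ref_subset optional ref_ids to restrict to (e.g. called Trm1
#'   targets).
#' @return object of class `condition_comparison`: `position`, `n_pairs`,
#'   `mean_difference` (A minus B), `t`, `p_value`, and `pairs`
#'   (data.frame `ref_id`, `fraction_a`, `fraction_b`, `delta`).
#' @export
compare_conditions <- function(table_a, table_b, position,
                               ref_subset = NULL) {
  get <- function(t) {
    t <- t[t$canonical_pos == position, c("ref_id", "fraction")]
    if (!is.null(ref_subset)) t <- t[t$ref_id %in% ref_subset, ]
    t
  }
  a <- get(table_a); b <- get(table_b)
  m <- merge(a, b, by = "ref_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$fraction_a) & !is.na(m$fraction_b), , drop = FALSE]
  if (nrow(m) < 3L) stop("insufficient pairs (need >= 3 complete pairs)")
  delta <- m$fraction_a - m$fraction_b
  if (sd(delta) <= .Machine$double.eps^0.5 * max(1, abs(mean(delta)))) {
    # (near-)constant differences: zero shift is the stated convention,
    # a constant nonzero shift is infinitely strong evidence
    if (isTRUE(all.equal(mean(delta), 0))) { tstat <- 0; p <- 1 }
    else { tstat <- sign(mean(delta)) * Inf; p <- 0 }
  } else {
    tt <- t.test(m$fraction_a, m$fraction_b, paired = TRUE)
    tstat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(position = position, n_pairs = nrow(m),
                 mean_difference = mean(delta), t = tstat, p_value = p,
                 pairs = data.frame(ref_id = m$ref_id,
                                    fraction_a = m$fraction_a,
                                    fraction_b = m$fraction_b,
                                    delta = delta,
                                    stringsAsFactors = FALSE)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "condition_comparison @%s: n=%d, mean diff=%.4g, t=%.3g, p=%.3g\n",
    x$position, x$n_pairs, x$mean_difference, x$t, x$p_value))
  invisible(x)
}
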