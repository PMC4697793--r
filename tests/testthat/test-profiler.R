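make_mapping <- function(reads, rs, max_mm = 3) {
  map_hierarchical(reads, rs, max_mm = max_mm)
}

test_that("a single exact read covers exactly its footprint with zero fractions", {
  set.seed(501)
  rs <- hand_refset(list(hand_ref("r1", random_read(70))))
  read <- substr(rs$mature[[1]]$sequence, 21, 40)
  prof <- pileup(make_mapping(c(a = read), rs), rs)
  expect_identical(sum(prof$coverage), 20L)
  expect_true(all(prof$coverage[21:40] == 1L))
  expect_true(all(prof$fraction[21:40] == 0))
  # uncovered positions are NA, never 0
  expect_true(all(is.na(prof$fraction[prof$coverage == 0])))
})

test_that("pileup counts match the hand-counting oracle at a mutated site", {
  set.seed(502)
  base <- random_read(70)
  rs <- hand_refset(list(hand_ref("r1", base)))
  # 10 reads over positions 11..35; 3 carry a substitution at position 20
  refb <- substr(base, 20, 20)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  reads <- setNames(rep(substr(base, 11, 35), 10), paste0("x", 1:10))
  for (i in 1:3) substr(reads[i], 10, 10) <- alt   # read-local pos 10 = ref 20
  prof <- pileup(make_mapping(reads, rs), rs)
  row <- prof[prof$linear_pos == 20, ]
  expect_identical(row[[refb]], 7L)
  expect_identical(row[[alt]], 3L)
  expect_identical(row$coverage, 10L)
  expect_equal(row$fraction, 0.3)
})

test_that("coverage conserves the summed lengths of unique reads", {
  rs <- toy_refset(seed = 503, n_mature = 4)
  lib <- simulate_library(sim_config(rs, n_fragments = 500, seed = 3))
  mr <- map_hierarchical(lib$reads, rs)
  prof <- pileup(mr, rs, tier = "mature")
  uh <- select_unique(mr)
  uh <- uh[uh$tier == "mature", ]
  expect_identical(sum(prof$coverage) + sum(prof$N),
                   sum(nchar(mr$reads[uh$read_id])))
})

test_that("fractions are invariant under read-order permutation", {
  rs <- toy_refset(seed = 504, n_mature = 3)
  lib <- simulate_library(sim_config(rs, n_fragments = 300, seed = 5))
  mr1 <- map_hierarchical(lib$reads, rs)
  mr2 <- map_hierarchical(rev(lib$reads), rs)
  p1 <- pileup(mr1, rs); p2 <- pileup(mr2, rs)
  key <- function(p) p[order(p$ref_id, p$linear_pos),
                       c("ref_id", "linear_pos", "A", "C", "G", "T", "coverage")]
  expect_equal(key(p1), key(p2), ignore_attr = TRUE)
})

test_that("coverage floor nulls thin positions but keeps their coverage", {
  set.seed(505)
  rs <- toy_refset(seed = 505, n_mature = 2)
  read <- substr(rs$mature[[1]]$sequence, 5, 30)
  mr <- make_mapping(setNames(rep(read, 10), paste0("r", 1:10)), rs)
  tab <- mismatch_fractions(pileup(mr, rs), rs, sample = "s",
                            min_coverage = 50)
  expect_true(all(is.na(tab$fraction[tab$coverage < 50])))
  tab2 <- mismatch_fractions(pileup(mr, rs), rs, sample = "s",
                             min_coverage = 5)
  expect_true(any(!is.na(tab2$fraction)))
  expect_true(all(tab2$coverage[!is.na(tab2$fraction)] >= 5))
})

test_that("canonical re-indexing places fractions on Sprinzl-style labels", {
  rs <- toy_refset(seed = 506, n_mature = 2)
  ref <- rs$mature[[1]]
  i26 <- match("26", ref$labels)
  read <- substr(ref$sequence, i26 - 10, i26 + 10)
  mr <- make_mapping(setNames(rep(read, 60), paste0("r", 1:60)), rs)
  tab <- mismatch_fractions(pileup(mr, rs), rs, sample = "s")
  row <- tab[tab$ref_id == ref$ref_id & tab$canonical_pos == "26", ]
  expect_identical(row$linear_pos, i26)
  expect_identical(row$coverage, 60L)
})

test_that("replicate summary matches the closed-form mean and n-1 sd", {
  t0 <- data.frame(sample = "a", ref_id = "r", canonical_pos = "26",
                   linear_pos = 26L, ref_base = "G", A = 0L, C = 0L, G = 0L,
                   T = 0L, N = 0L, coverage = 100L, fraction = 0.2,
                   numbered = TRUE, stringsAsFactors = FALSE)
  t1 <- t0; t1$sample <- "b"; t1$fraction <- 0.4
  s <- replicate_summary(list(t0, t1))
  expect_equal(s$mean, 0.3)
  expect_equal(s$sd, sd(c(0.2, 0.4)))
  expect_equal(s$sd, 0.1414, tolerance = 1e-3)
  # identical replicates -> sd exactly 0
  s2 <- replicate_summary(list(t0, t0, t0, t0))
  expect_identical(s2$n_replicates, 4L)
  expect_equal(s2$sd, 0)
  # complete policy: any NA replicate nulls the cell
  t2 <- t0; t2$fraction <- NA_real_
  expect_true(is.na(replicate_summary(list(t0, t2))$mean))
  expect_false(is.na(replicate_summary(list(t0, t2),
                                       policy = "available")$mean))
})

test_that("replicate summary refuses mismatched reference builds", {
  t0 <- data.frame(sample = "a", ref_id = "r", canonical_pos = "26",
                   fraction = 0.2, coverage = 10L, ref_base = "G")
  t1 <- t0; t1$ref_id <- "other"
  expect_error(replicate_summary(list(t0, t1)), "different references")
})

test_that("base preferences normalize over mismatching bases only", {
  prof <- data.frame(ref_id = "r", linear_pos = 1L, ref_base = "G",
                     A = 3L, C = 0L, G = 6L, T = 1L, N = 2L,
                     coverage = 10L, fraction = 0.4,
                     stringsAsFactors = FALSE)
  p <- base_preferences(prof, "r", 1L)
  expect_equal(p[["A"]], 0.75)
  expect_equal(p[["T"]], 0.25)
  expect_equal(sum(p), 1)
  prof0 <- prof; prof0$A <- 0L; prof0$T <- 0L
  expect_length(base_preferences(prof0, "r", 1L), 0L)
})

test_that("simulator substitution preferences are recovered at a modified site", {
  rs <- toy_refset(seed = 507, n_mature = 3)
  f <- ref_features(rs)
  rid <- f$ref_id[f$g26][1]
  ref <- rs$mature[[match(rid, vapply(rs$mature, `[[`, "", "ref_id"))]]
  mods <- data.frame(ref_id = rid, canonical_pos = "26", m = 0.6, q = 1)
  mods$prefs <- list(c(A = 0.7, T = 0.2, C = 0.1))
  lib <- simulate_library(sim_config(rs, n_fragments = 20000, mods = mods,
                                     error_rate = 0, precursor_frac = 0,
                                     seed = 17))
  mr <- map_hierarchical(lib$reads, rs)
  prof <- pileup(mr, rs)
  p <- base_preferences(prof, rid, match("26", ref$labels))
  n_mm <- sum(lib$truth$sites$misread)
  se <- sqrt(0.7 * 0.3 / n_mm)
  expect_lt(abs(p[["A"]] - 0.7), 3 * se + 0.02)
  expect_lt(abs(p[["T"]] - 0.2), 3 * sqrt(0.2 * 0.8 / n_mm) + 0.02)
})

test_that("display flag applies the 15% threshold inclusively", {
  expect_true(igv_flag(0.15))
  expect_false(igv_flag(0.1499))
  expect_true(igv_flag(1.0))
  expect_true(is.na(igv_flag(NA_real_)))
})
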