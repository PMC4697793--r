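read_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

require_fields <- function(x, fields, where) {
  miss <- setdiff(fields, names(x))
  if (length(miss))
    stop(sprintf("config schema error in %s: missing field(s) %s", where,
                 paste(miss, collapse = ", ")))
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(character())
  setNames(as.character(tools::md5sum(paths)), basename(paths))
}

#' Run the full fragment-profiling pipeline from one config
#'
#' Orchestrates reference building, (optional) library simulation, mapping,
#' misincorporation profiling, abundance counting and (optional) G26
#' target calling, writing every stage output plus a reproducibility
#' manifest under one directory. Re-running an identical config and seed
#' reproduces identical stage tallies.
#'
#' Config schema (YAML or list): `out_dir`; `catalog: {fasta, gff}`;
#' `samples:` list of `{name, fastq}` or `{name, simulate: {n_fragments,
#' error_rate, mods (TSV path with ref_id/canonical_pos/m/q),
#' precursor_frac}}`; optional scalars `seed`, `flank_len` (40), `cca`
#' (true), `max_mm` (3), `min_len` (19), `max_len` (35), `min_coverage`
#' (50); optional `call: {reference_condition, target_threshold,
#' background_ceiling}`.
#'
#' @param config list or YAML path.
#' @return the run manifest (list), invisibly; outputs under `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  require_fields(config, c("out_dir", "catalog", "samples"), "top level")
  require_fields(config$catalog, c("fasta", "gff"), "catalog")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  catalog <- parse_gene_catalog(config$catalog$fasta, config$catalog$gff,
                                flank_len = config$flank_len %||% 40)
  refset <- build_reference_set(catalog, cca = config$cca %||% TRUE)
  write_reference_set(refset, file.path(out, "reference"))

  max_mm <- config$max_mm %||% 3
  min_len <- config$min_len %||% 19
  max_len <- config$max_len %||% 35
  min_cov <- config$min_coverage %||% 50

  mappings <- list()
  tables <- list()
  tallies <- list()
  input_files <- c(config$catalog$fasta, config$catalog$gff)
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    require_fields(s, "name", sprintf("samples[%d]", i))
    if (!is.null(s$fastq)) {
      reads <- read_fastq(s$fastq)
      input_files <- c(input_files, s$fastq)
    } else if (!is.null(s$simulate)) {
      sim <- s$simulate
      mods <- NULL
      if (!is.null(sim$mods)) {
        mods <- read.table(sim$mods, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
        mods$canonical_pos <- as.character(mods$canonical_pos)
        input_files <- c(input_files, sim$mods)
      }
      cfg <- sim_config(refset,
                        n_fragments = sim$n_fragments %||% 10000,
                        mods = mods,
                        error_rate = sim$error_rate %||% 0.003,
                        precursor_frac = sim$precursor_frac %||% 0.05,
                        seed = seed + i)
      lib <- simulate_library(
        cfg, fastq_path = file.path(out, paste0(s$name, ".fastq")))
      reads <- lib$reads
    } else {
      stop(sprintf("config schema error in samples[%d] ('%s'): need fastq or simulate",
                   i, s$name))
    }
    mr <- map_hierarchical(reads, refset, max_mm = max_mm,
                           min_len = min_len, max_len = max_len)
    mappings[[s$name]] <- mr
    tallies[[s$name]] <- as.list(mr$summary)
    prof <- pileup(mr, refset, tier = "mature")
    tab <- mismatch_fractions(prof, refset, sample = s$name,
                              min_coverage = min_cov)
    tables[[s$name]] <- tab
    write_misinc_tsv(tab, file.path(out, paste0(s$name, "_misinc.tsv")))
    write_bedgraph(prof, file.path(out, paste0(s$name, "_misinc.bedgraph")))
  }

  for (tier in c("mature", "precursor")) {
    cm <- count_reads(mappings, refset, tier = tier)
    write.table(data.frame(ref_id = rownames(cm), cm, check.names = FALSE),
                file.path(out, paste0("counts_", tier, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (tier == "mature" && ncol(cm) >= 2L && all(colSums(cm) > 0)) {
      sf <- tryCatch(size_factors(cm), error = function(e) NULL)
      if (!is.null(sf))
        write.table(data.frame(sample = names(sf), size_factor = sf),
                    file.path(out, "size_factors.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
  }

  calls_summary <- NULL
  if (!is.null(config$call)) {
    require_fields(config$call, "reference_condition", "call")
    all_tab <- do.call(rbind, tables)
    cs <- call_trm1_targets(
      all_tab, ref_features(refset),
      reference_condition = config$call$reference_condition,
      target_threshold = config$call$target_threshold %||% 0.10,
      background_ceiling = config$call$background_ceiling %||% 0.01)
    write.table(cs$calls, file.path(out, "trm1_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    calls_summary <- as.list(table(cs$calls$target_status))
  }

  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  manifest <- list(
    tool = as.character(utils::packageVersion("hydroseq")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_md5 = unname(md5_of(cfg_json)),
    input_md5 = as.list(md5_of(input_files)),
    references = list(n_genes = length(catalog),
                      n_mature = length(refset$mature),
                      n_precursor = length(refset$precursor)),
    samples = tallies,
    calls = calls_summary)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
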