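# End-to-end orchestration: configuration, fixture generation, the staged
# analysis (clean -> collapse -> map -> annotate -> discover -> DE ->
# degradome) and the report bundle.

#' Pipeline configuration
#'
#' Collects every input path and threshold of the pipeline. Thresholds
#' default to the study values (16-30 nt reads, 2 reference mismatches,
#' -18 kcal/mol, 4 duplex mismatches, 2 nt bulges, 24 loci, frequency-10
#' filter, |log2FC| >= 1 at p <= 0.01, target score 4.5, 20 nt tags).
#' Serialises losslessly to YAML via [write_pipeline_config()].
#'
#' @param reads_cl,reads_dt,genome,ncrna,repeats,gff,known_mirnas,transcripts,degradome
#'   input file paths (see [make_fixture()] for the expected formats).
#' @param out_dir output directory for the report bundle.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len,min_qual read filters.
#' @param max_mm,flank,min_stem,mfe_max,max_duplex_mm,max_bulge,max_loci,cluster_gap,min_locus_count,require_star
#'   discovery thresholds (see [discovery_params()]).
#' @param min_count,lfc_min,alpha differential-expression thresholds.
#' @param max_score,pred_max_score,tag_len,cleavage_window degradome
#'   thresholds.
#' @param seed integer seed recorded in the manifest.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(reads_cl = NULL, reads_dt = NULL, genome = NULL,
                            ncrna = NULL, repeats = NULL, gff = NULL,
                            known_mirnas = NULL, transcripts = NULL,
                            degradome = NULL, out_dir = tempfile("srnapipe_"),
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_len = 16L, max_len = 30L, min_qual = 0L,
                            max_mm = 2L, flank = 250L, min_stem = 15L,
                            mfe_max = -18.0, max_duplex_mm = 4L,
                            max_bulge = 2L, max_loci = 24L,
                            cluster_gap = 200L, min_locus_count = 5L,
                            require_star = FALSE, min_count = 10L,
                            lfc_min = 1.0, alpha = 0.01, max_score = 4.5,
                            pred_max_score = 3.0, tag_len = 20L,
                            cleavage_window = 1L, seed = 1L) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$min_len > cfg$max_len)
    stop_input("min_len (%d) exceeds max_len (%d)", cfg$min_len, cfg$max_len)
  if (nchar(cfg$adapter) < 5) stop_input("adapter must be >= 5 nt")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop_input("alpha must be in (0, 1]")
  if (cfg$lfc_min < 0) stop_input("lfc_min must be >= 0")
  if (cfg$mfe_max > 0) stop_input("mfe_max must be <= 0 kcal/mol")
  if (cfg$max_score < 0 || cfg$tag_len < 10)
    stop_input("invalid degradome thresholds")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a complete synthetic input set to disk
#'
#' Generates the synthetic study ([sim_genome()], [sim_srna_libraries()],
#' [sim_degradome()]) and writes every pipeline input plus the ground-truth
#' tables: genome and transcript FASTA, collapsed read FASTA for both
#' libraries and the degradome, ncRNA and reference-mature FASTA, gene
#' models GFF3, repeats BED, truth TSVs and a ready-to-run pipeline config
#' YAML.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the `pipeline_config` pointing at the written files;
#'   the `sim_data` object is attached as attribute `"sim"`.
#' @export
make_fixture <- function(config = sim_config(), dir = tempfile("fixture_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop_input("fixture dir not writable: %s", dir)
  sim <- sim_genome(config)
  libs <- sim_srna_libraries(sim)
  deg <- sim_degradome(sim)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_reads(libs$cl %>% select("seq", "count"), p("reads_cl.fa"))
  write_reads(libs$dt %>% select("seq", "count"), p("reads_dt.fa"))
  write_reads(deg, p("degradome.fa"))
  write_fasta(setNames(sim$refs$ncrna$seq,
                       paste(sim$refs$ncrna$id, sim$refs$ncrna$class)),
              p("ncrna.fa"))
  write_fasta(setNames(sim$refs$known_mirnas$seq,
                       paste(sim$refs$known_mirnas$id,
                             sim$refs$known_mirnas$family)),
              p("known_mirnas.fa"))
  write_fasta(setNames(sim$transcripts$seq, sim$transcripts$transcript_id),
              p("transcripts.fa"))
  write_gff3(sim$annotations$gene_features, p("genes.gff3"))
  write_bed(sim$annotations$repeats, p("repeats.bed"))
  readr::write_tsv(sim$truth$mirna, p("truth_mirna.tsv"))
  readr::write_tsv(sim$truth$targets, p("truth_targets.tsv"))
  readr::write_tsv(sim$truth$decoys %>% select(-"seq"), p("truth_decoys.tsv"))
  readr::write_tsv(sim$truth$sirna, p("truth_sirna.tsv"))
  pcfg <- pipeline_config(
    reads_cl = p("reads_cl.fa"), reads_dt = p("reads_dt.fa"),
    genome = p("genome.fa"), ncrna = p("ncrna.fa"),
    repeats = p("repeats.bed"), gff = p("genes.gff3"),
    known_mirnas = p("known_mirnas.fa"), transcripts = p("transcripts.fa"),
    degradome = p("degradome.fa"), out_dir = file.path(dir, "out"),
    adapter = config$adapter, seed = config$seed)
  write_pipeline_config(pcfg, p("config.yaml"))
  attr(pcfg, "sim") <- sim
  invisible(pcfg)
}

parse_two_token_fasta <- function(path, second = "class") {
  x <- read_fasta(path)
  parts <- strsplit(names(x), "\\s+")
  out <- tibble(id = vapply(parts, `[`, "", 1),
                seq = unname(x))
  out[[second]] <- vapply(parts, function(z) z[2] %||% NA_character_, "")
  out
}

#' Run the full small-RNA + degradome pipeline
#'
#' Executes every stage on the configured inputs and writes the report
#' bundle to `config$out_dir`: overlap table, per-library annotation
#' tables, length histogram, candidate table, DE table, validated and
#' predicted target tables, per-transcript T-plots, a run manifest and a
#' stage log. Re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()] with all input paths set.
#' @return (invisibly) a `pipeline_result` list holding every table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  needed <- c("reads_cl", "reads_dt", "genome")
  for (f in needed) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop_input("missing input file for '%s': %s", f,
                 config[[f]] %||% "<unset>")
  }
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message("[srnapipe] ", line)
  }

  genome <- read_fasta(config$genome)
  ncrna <- if (!is.null(config$ncrna) && file.exists(config$ncrna))
    parse_two_token_fasta(config$ncrna, "class") else NULL
  known_ref <- if (!is.null(config$known_mirnas) &&
                   file.exists(config$known_mirnas))
    parse_two_token_fasta(config$known_mirnas, "family") else NULL
  repeats <- if (!is.null(config$repeats) && file.exists(config$repeats))
    read_bed(config$repeats) else NULL
  gene_models <- if (!is.null(config$gff) && file.exists(config$gff))
    read_gff3(config$gff) else NULL
  transcripts <- if (!is.null(config$transcripts) &&
                     file.exists(config$transcripts)) {
    tx <- read_fasta(config$transcripts)
    tibble(transcript_id = names(tx), seq = unname(tx))
  } else NULL

  params <- discovery_params(
    flank = config$flank, min_stem = config$min_stem,
    mfe_max = config$mfe_max, max_duplex_mm = config$max_duplex_mm,
    max_bulge = config$max_bulge, max_loci = config$max_loci,
    max_mm = config$max_mm, cluster_gap = config$cluster_gap,
    min_locus_count = config$min_locus_count,
    require_star = config$require_star)

  # stage 1: clean + collapse
  libs <- purrr::imap(list(CL = config$reads_cl, DT = config$reads_dt),
                      function(path, lab) {
    raw <- read_reads(path)
    expanded <- raw[rep(seq_len(nrow(raw)), raw$count), c("seq", "qual")[
      c(TRUE, "qual" %in% names(raw))], drop = FALSE]
    clean <- trim_and_filter(expanded, adapter = config$adapter,
                             min_len = config$min_len,
                             max_len = config$max_len,
                             min_qual = config$min_qual)
    say("%s: %d raw reads -> %d clean reads", lab, nrow(expanded),
        nrow(clean))
    lib <- collapse_reads(clean, label = lab)
    if (attr(lib, "total_reads") == 0)
      warning(sprintf("library %s is empty after filtering", lab))
    lib
  })

  hist_cl <- length_distribution(libs$CL)
  hist_dt <- length_distribution(libs$DT)
  overlap <- overlap_stats(libs$CL, libs$DT)
  say("overlap: %.2f%% of total reads shared",
      overlap$total_pct[overlap$type == "shared"])

  # stage 2: map + annotate
  union_lib <- bind_rows(tidy(libs$CL), tidy(libs$DT)) %>%
    distinct(.data$seq)
  locus_map <- map_perfect(union_lib, genome)
  say("mapping: %d of %d unique sequences have perfect loci",
      dplyr::n_distinct(locus_map$seq), nrow(union_lib))
  ann <- purrr::map(libs, function(lib)
    classify_reads(lib, locus_map, ncrna_ref = ncrna,
                   repeat_intervals = repeats, gene_models = gene_models,
                   known_mirnas = known_ref))
  # annotation over the pooled library drives the novel-candidate exclusion
  pooled <- collapse_reads(bind_rows(tidy(libs$CL), tidy(libs$DT)) %>%
                             select("seq", "count"), label = "pooled")
  ann_pooled <- classify_reads(pooled, locus_map, ncrna_ref = ncrna,
                               repeat_intervals = repeats,
                               gene_models = gene_models,
                               known_mirnas = known_ref)

  # stage 3: discovery
  cand <- discover_mirnas(libs$CL, libs$DT, genome, known_ref = known_ref,
                          annotation = ann_pooled,
                          gene_models = gene_models,
                          locus_map = locus_map, params = params)
  passing <- cand[cand$pass %||% logical(0), , drop = FALSE]
  say("discovery: %d candidates evaluated, %d pass (%d known, %d novel)",
      nrow(cand), nrow(passing), sum(passing$status == "known"),
      sum(passing$status == "novel"))

  # stage 4: differential expression
  de <- call_de(
    passing %>% select("mirna_id", "count_cl", "count_dt"),
    total_cl = attr(libs$CL, "total_reads"),
    total_dt = attr(libs$DT, "total_reads"),
    min_count = config$min_count, lfc_min = config$lfc_min,
    alpha = config$alpha)
  say("DE: %d up, %d down, %d ns, %d filtered",
      sum(de$de_call == "up"), sum(de$de_call == "down"),
      sum(de$de_call == "ns"), sum(de$de_call == "filtered"))

  # stage 5: degradome
  targets <- predicted <- NULL
  tplots <- NULL
  if (!is.null(transcripts) && !is.null(config$degradome) &&
      file.exists(config$degradome)) {
    tags <- read_reads(config$degradome)
    tplots <- map_tags(tags, transcripts, tag_len = config$tag_len)
    mir_in <- passing %>% select("mirna_id", "family", "mature")
    targets <- call_targets(mir_in, tplots, transcripts,
                            max_score = config$max_score,
                            window = config$cleavage_window)
    predicted <- predict_targets_insilico(mir_in, transcripts,
                                          max_score = config$pred_max_score)
    say("degradome: %d validated target hits, %d predicted sites",
        nrow(targets), nrow(predicted))
  }

  result <- structure(
    list(libraries = libs, length_hist = list(CL = hist_cl, DT = hist_dt),
         overlap = overlap, annotation = ann, candidates = cand,
         de = de, tplots = tplots, targets = targets,
         predicted_targets = predicted, locus_map = locus_map,
         config = config, log = log),
    class = "pipeline_result")
  write_report_bundle(result, config)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' @describeIn run_pipeline one-row summary of a pipeline run.
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @export
glance.pipeline_result <- function(x, ...) {
  pass <- x$candidates[x$candidates$pass, , drop = FALSE]
  tibble(
    clean_reads_cl = attr(x$libraries$CL, "total_reads"),
    clean_reads_dt = attr(x$libraries$DT, "total_reads"),
    unique_cl = attr(x$libraries$CL, "unique_reads"),
    unique_dt = attr(x$libraries$DT, "unique_reads"),
    n_candidates = nrow(x$candidates),
    n_mirnas = nrow(pass),
    n_known = sum(pass$status == "known"),
    n_novel = sum(pass$status == "novel"),
    n_families = dplyr::n_distinct(pass$family),
    n_de_up = sum(x$de$de_call == "up"),
    n_de_down = sum(x$de$de_call == "down"),
    n_targets = if (is.null(x$targets)) NA_integer_ else nrow(x$targets))
}

format_location <- function(scaffold, start, end, strand) {
  sprintf("%s:%d..%d:%s", scaffold, start, end, strand)
}

write_report_bundle <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(result$overlap, p("table1_overlap.tsv"))
  readr::write_tsv(as_tibble(result$annotation$CL), p("table2_annotation_cl.tsv"))
  readr::write_tsv(as_tibble(result$annotation$DT), p("table2_annotation_dt.tsv"))
  readr::write_tsv(
    bind_rows(CL = result$length_hist$CL, DT = result$length_hist$DT,
              .id = "library"),
    p("length_histogram.tsv"))
  cand <- as_tibble(result$candidates)
  if (nrow(cand)) {
    tab3 <- cand %>%
      filter(.data$pass) %>%
      mutate(location = format_location(.data$scaffold,
                                        .data$precursor_start,
                                        .data$precursor_end, .data$strand),
             mfe = round_half_up(.data$mfe, 1)) %>%
      select("mirna_id", "status", "family", "mature", "arm", "length",
             "star", "location", "context", "mfe", "count_cl", "count_dt")
    readr::write_tsv(tab3, p("candidates.tsv"))
  }
  de <- as_tibble(result$de) %>%
    mutate(tpm_cl = round_half_up(.data$tpm_cl, 1),
           tpm_dt = round_half_up(.data$tpm_dt, 1),
           log2fc = round_half_up(.data$log2fc, 2))
  readr::write_tsv(de, p("de_table.tsv"))
  if (!is.null(result$targets))
    readr::write_tsv(result$targets, p("table4_targets.tsv"))
  if (!is.null(result$predicted_targets))
    readr::write_tsv(result$predicted_targets, p("predicted_targets.tsv"))
  if (!is.null(result$tplots))
    readr::write_tsv(as_tibble(result$tplots), p("tplots.tsv"))
  manifest <- list(
    package = "srnapipe",
    version = as.character(utils::packageVersion("srnapipe")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = as.list(glance(result)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(result$log, p("pipeline.log"))
  invisible(config$out_dir)
}
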