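# Seeded generator of synthetic genomes, reference sets, small-RNA libraries
# and degradome tag sets with known planted truth. The generator emulates the
# statistical structure the analysis assumes: hairpin miRNA loci with
# negative-binomial read counts and planted fold-changes, ncRNA/repeat/gene
# background classes in roughly the proportions seen in real leaf libraries,
# shuffled-precursor decoys, siRNA duplex loci, and degradome tag piles
# peaking at planted cleavage sites.

#' Synthetic study configuration
#'
#' All knobs of the synthetic data generator with defaults that mirror the
#' emulated study design: two libraries (CL control, DT drought), mature
#' miRNAs of 20-22 nt on 61-222 nt hairpin precursors, a 24-nt-dominated
#' background, and a quarter of the planted miRNAs differentially expressed
#' at log2 fold-change 2.
#'
#' @param seed integer seed; every generator stage derives its RNG stream
#'   from it.
#' @param n_scaffolds,scaffold_len genome size (default 5 x 20 kb).
#' @param n_mirna_loci number of planted miRNA hairpin loci.
#' @param precursor_len_range precursor length range in nt (within 50-300).
#' @param n_sirna_loci planted siRNA duplex loci.
#' @param n_ncrna_decoys reference ncRNAs per class (rRNA/tRNA/snRNA/snoRNA).
#' @param n_genes gene models (two exons joined by one intron).
#' @param read_depth target total reads per library.
#' @param dispersion negative-binomial dispersion phi (var = mu + phi mu^2);
#'   0 gives deterministic rounded means.
#' @param de_fraction fraction of planted miRNAs that are differentially
#'   expressed; `de_fraction * n_mirna_loci` must be an integer.
#' @param planted_log2fc log2 fold-change applied to the DT mean of planted
#'   DE miRNAs.
#' @param degradome_depth total degradome tags.
#' @param cleavage_peak_fraction fraction of a target transcript's tags that
#'   start exactly at the planted cleavage site, in (0, 1].
#' @param n_targets planted cleavage targets (one per transcript).
#' @param known_fraction fraction of planted matures included in the
#'   reference mature-miRNA set (the "known" ones).
#' @param star_fraction star read abundance relative to the mature.
#' @param adapter 3' adapter appended to every simulated read.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 42, n_scaffolds = 5, scaffold_len = 20000,
                       n_mirna_loci = 20, precursor_len_range = c(61, 222),
                       n_sirna_loci = 4, n_ncrna_decoys = 3, n_genes = 14,
                       read_depth = 2e6, dispersion = 0.02,
                       de_fraction = 0.25, planted_log2fc = 2,
                       degradome_depth = 5e4, cleavage_peak_fraction = 0.9,
                       n_targets = 10, known_fraction = 0.4,
                       star_fraction = 0.1,
                       adapter = "TGGAATTCTCGGGTGCCAAGG") {
  cfg <- list(seed = as.integer(seed), n_scaffolds = n_scaffolds,
              scaffold_len = scaffold_len, n_mirna_loci = n_mirna_loci,
              precursor_len_range = as.integer(precursor_len_range),
              n_sirna_loci = n_sirna_loci, n_ncrna_decoys = n_ncrna_decoys,
              n_genes = n_genes, read_depth = read_depth,
              dispersion = dispersion, de_fraction = de_fraction,
              planted_log2fc = planted_log2fc,
              degradome_depth = degradome_depth,
              cleavage_peak_fraction = cleavage_peak_fraction,
              n_targets = n_targets, known_fraction = known_fraction,
              star_fraction = star_fraction, adapter = toupper(adapter))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (precursor_len_range[1] < 50 || precursor_len_range[2] > 300 ||
        precursor_len_range[1] > precursor_len_range[2])
      stop_input("precursor_len_range must lie within [50, 300]")
    nde <- de_fraction * n_mirna_loci
    if (abs(nde - round(nde)) > 1e-9)
      stop_input("de_fraction * n_mirna_loci must be an integer")
    if (any(c(n_scaffolds, scaffold_len, n_mirna_loci + 1, read_depth,
              degradome_depth) <= 0))
      stop_input("all sizes must be positive")
    if (dispersion < 0) stop_input("dispersion must be >= 0")
    if (cleavage_peak_fraction <= 0 || cleavage_peak_fraction > 1)
      stop_input("cleavage_peak_fraction must be in (0, 1]")
    if (n_targets > n_genes)
      stop_input("n_targets cannot exceed n_genes")
  })
  invisible(cfg)
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: a random Eulerian walk over the dinucleotide
#' transition multigraph, preserving the exact dinucleotide (and hence
#' mononucleotide) composition while destroying longer-range structure.
#' Used to build negative-control "decoy" hairpin loci.
#'
#' @param seq a single sequence.
#' @return shuffled sequence of identical length and dinucleotide counts.
#' @export
dinuc_shuffle <- function(seq) {
  s <- chars(seq); n <- length(s)
  if (n < 4) return(seq)
  src <- s[-n]; tgt <- s[-1]
  edges <- split(tgt, src)
  last <- s[n]
  verts <- setdiff(names(edges), last)
  # pick a "last exit" edge per vertex forming paths that all reach `last`
  for (attempt in 1:1000) {
    lastedge <- vapply(verts, function(v) sample(edges[[v]], 1), "")
    ok <- TRUE
    for (v in verts) {
      cur <- v; steps <- 0
      while (cur != last && steps <= 5) {
        if (!cur %in% verts) { cur <- NA; break }
        cur <- lastedge[[cur]]; steps <- steps + 1
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(paste(sample(s), collapse = "")) # pathological composition
  avail <- edges
  for (v in verts) {
    idx <- match(lastedge[[v]], avail[[v]])
    rest <- avail[[v]][-idx]
    avail[[v]] <- c(if (length(rest)) sample(rest) else character(0),
                    lastedge[[v]])
  }
  avail[[last]] <- if (!is.null(avail[[last]]) && length(avail[[last]]) > 1)
    sample(avail[[last]]) else avail[[last]]
  out <- character(n); out[1] <- s[1]; cur <- s[1]
  for (i in 2:n) {
    nxt <- avail[[cur]][1]
    avail[[cur]] <- avail[[cur]][-1]
    out[i] <- nxt; cur <- nxt
  }
  paste(out, collapse = "")
}

# -- genome generation --------------------------------------------------------

#' Generate a synthetic genome with planted truth
#'
#' Builds random scaffolds and plants, at non-overlapping loci: miRNA
#' hairpin precursors (mature:star duplex fully complementary, 2-nt 3'
#' overhangs, stem long enough to satisfy the discovery criteria under the
#' package energy model), dinucleotide-shuffled decoy copies of every
#' precursor, siRNA duplex loci, reference ncRNAs of four classes, repeat
#' intervals, and two-exon gene models whose spliced transcripts carry the
#' planted miRNA cleavage sites.
#'
#' @param config a [sim_config()].
#' @return a `sim_data` list: `genome` (named character), `truth` (list of
#'   tibbles: `mirna`, `decoys`, `sirna`, `targets`), `annotations` (list:
#'   `ncrna_loci`, `repeats`, `gene_features`), `refs` (list: `ncrna`,
#'   `known_mirnas`), `transcripts` (tibble `transcript_id`, `gene`, `seq`),
#'   and `config`.
#' @export
sim_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config
  scaf_names <- sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))
  scafs <- lapply(seq_len(cfg$n_scaffolds),
                  function(i) chars(rand_dna(cfg$scaffold_len)))
  names(scafs) <- scaf_names

  cursor <- stats::setNames(rep(150L, cfg$n_scaffolds), scaf_names)
  place <- function(len) {
    # keep planted loci well apart so read clusters stay distinct
    gap <- sample(420:800, 1)
    for (sc in names(sort(cursor))) {
      pos <- cursor[[sc]] + gap
      if (pos + len <= cfg$scaffold_len - 150) {
        cursor[[sc]] <<- pos + len
        return(list(scaffold = sc, start = pos, end = pos + len - 1L))
      }
    }
    stop_input("scaffolds too short to host the requested loci")
  }
  write_seq <- function(sc, start, seq) {
    scafs[[sc]][start:(start + nchar(seq) - 1)] <<- chars(seq)
  }

  # ncRNA references, embedded in the genome
  nc_len <- c(rRNA = 120, tRNA = 75, snRNA = 100, snoRNA = 90)
  ncrna <- purrr::map_dfr(names(nc_len), function(cls) {
    purrr::map_dfr(seq_len(cfg$n_ncrna_decoys), function(i) {
      sq <- rand_dna(nc_len[[cls]])
      at <- place(nchar(sq))
      write_seq(at$scaffold, at$start, sq)
      tibble(id = sprintf("%s_%d", cls, i), class = cls, seq = sq,
             scaffold = at$scaffold, start = at$start, end = at$end)
    })
  })

  # repeat intervals (left as random sequence; membership is positional)
  repeats <- purrr::map_dfr(seq_len(max(2, cfg$n_ncrna_decoys)), function(i) {
    at <- place(300L)
    tibble(repeat_id = sprintf("rep_%d", i), scaffold = at$scaffold,
           start = at$start, end = at$end)
  })

  # gene models: exon1 - intron - exon2; a few genes widened to host
  # intron- or CDS-context miRNA precursors
  n_intron_ctx <- min(2, cfg$n_mirna_loci)
  n_cds_ctx <- if (cfg$n_mirna_loci >= 10) 1L else 0L
  gene_plan <- tibble(
    gene = sprintf("gene_%02d", seq_len(cfg$n_genes)),
    exon1 = 300L, exon2 = 300L, intron = 150L)
  if (cfg$n_genes >= n_intron_ctx + n_cds_ctx && n_intron_ctx > 0) {
    gene_plan$intron[seq_len(n_intron_ctx)] <- 320L
    if (n_cds_ctx > 0) gene_plan$exon2[n_intron_ctx + 1] <- 380L
  }
  gene_features <- purrr::map_dfr(seq_len(nrow(gene_plan)), function(g) {
    gp <- gene_plan[g, ]
    glen <- gp$exon1 + gp$intron + gp$exon2
    at <- place(glen)
    e1 <- c(at$start, at$start + gp$exon1 - 1L)
    ir <- c(e1[2] + 1L, e1[2] + gp$intron)
    e2 <- c(ir[2] + 1L, ir[2] + gp$exon2)
    tibble(gene = gp$gene, scaffold = at$scaffold,
           type = c("exon", "CDS", "intron", "exon", "CDS"),
           start = c(e1[1], e1[1], ir[1], e2[1], e2[1]),
           end = c(e1[2], e1[2], ir[2], e2[2], e2[2]),
           strand = "+")
  })

  # miRNA hairpin loci
  n_de <- round(cfg$de_fraction * cfg$n_mirna_loci)
  de_flags <- rep(c(TRUE, FALSE),
                  c(n_de, cfg$n_mirna_loci - n_de))
  n_known <- round(cfg$known_fraction * cfg$n_mirna_loci)
  contexts <- c(rep("intron", n_intron_ctx), rep("CDS", n_cds_ctx),
                rep("intergenic",
                    cfg$n_mirna_loci - n_intron_ctx - n_cds_ctx))
  mirna <- purrr::map_dfr(seq_len(cfg$n_mirna_loci), function(i) {
    L <- sample(20:22, 1)
    # realistic pre-miRNAs carry long stems and short terminal loops, so
    # extra precursor length goes into the stem extension, not the loop
    min_len <- max(cfg$precursor_len_range[1], 2L * L + 2L * 5L + 8L)
    plen <- sample(min_len:cfg$precursor_len_range[2], 1)
    loop_len <- sample(8:16, 1)
    ext <- (plen - 2L * L - loop_len) %/% 2L
    loop_len <- plen - 2L * L - 2L * ext
    M <- rand_dna(L, gc = 0.55)
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                  collapse = "")
    E5 <- rand_dna(ext)
    prec <- paste0(E5, M, loop, revcomp(M), revcomp(E5))
    arm <- sample(c("5p", "3p"), 1)
    # duplex partner with 2-nt 3' overhangs on both strands
    arm5 <- M
    arm3 <- substring(prec, ext + L + loop_len + 3L, ext + L + loop_len + 2L + L)
    mature <- if (arm == "5p") arm5 else arm3
    star <- if (arm == "5p") arm3 else arm5
    ctx <- contexts[i]
    if (ctx == "intron") {
      gf <- gene_features[gene_features$type == "intron", ][i, ]
      start <- gf$start + 20L
      sc <- gf$scaffold
      if (start + plen - 1L > gf$end) { ctx <- "intergenic" }
    }
    if (ctx == "CDS") {
      gf <- gene_features[gene_features$type == "CDS" &
                            gene_features$end - gene_features$start > 350, ]
      gf <- gf[1, ]
      start <- gf$start + 30L
      sc <- gf$scaffold
      if (is.na(start) || start + plen - 1L > gf$end) ctx <- "intergenic"
    }
    if (ctx == "intergenic") {
      at <- place(plen)
      sc <- at$scaffold; start <- at$start
    }
    write_seq(sc, start, prec)
    m_off <- if (arm == "5p") ext else ext + L + loop_len + 2L
    # expression scales with sequencing depth; the 800-5000 band is the
    # per-2M-read expectation of a well-expressed plant miRNA
    cl_mean <- max(10, round(10^stats::runif(1, log10(800), log10(5000)) *
                               cfg$read_depth / 2e6))
    lfc <- if (de_flags[i]) cfg$planted_log2fc else 0
    tibble(mirna_id = sprintf("syn-miR%02d", i), mature = M_or(mature),
           star = M_or(star), arm = arm, length = nchar(mature),
           scaffold = sc, precursor_start = start,
           precursor_end = start + plen - 1L,
           mature_start = start + m_off,
           mature_end = start + m_off + L - 1L, strand = "+",
           precursor_seq = prec, context = ctx,
           cl_mean = cl_mean, dt_mean = round(cl_mean * 2^lfc),
           true_log2fc = lfc, is_de = de_flags[i],
           known = i <= n_known)
  })

  # decoy loci: dinucleotide-shuffled copies of each precursor
  decoys <- purrr::map_dfr(seq_len(nrow(mirna)), function(i) {
    sq <- dinuc_shuffle(mirna$precursor_seq[i])
    at <- place(nchar(sq))
    write_seq(at$scaffold, at$start, sq)
    core <- substring(sq, nchar(sq) %/% 2 - 10L, nchar(sq) %/% 2 + 10L)
    tibble(decoy_id = sprintf("decoy_%02d", i), scaffold = at$scaffold,
           start = at$start, end = at$end, seq = sq, core_read = core)
  })

  # siRNA duplex loci: opposite-strand read pair, 2-nt 3' overhangs
  sirna <- purrr::map_dfr(seq_len(cfg$n_sirna_loci), function(i) {
    at <- place(60L)
    a <- at$start + 20L
    plus <- paste(scafs[[at$scaffold]][a:(a + 20L)], collapse = "")
    minus <- revcomp(paste(scafs[[at$scaffold]][(a - 2L):(a + 18L)],
                           collapse = ""))
    tibble(sirna_id = sprintf("sirna_%d", i), scaffold = at$scaffold,
           plus_start = a, plus_end = a + 20L, plus_read = plus,
           minus_read = minus)
  })

  genome <- vapply(scafs, paste, "", collapse = "")

  # planted cleavage targets: reverse complement of a mature written into
  # exon2; cleavage position opposite miRNA nucleotide 10
  target_genes <- gene_plan$gene[gene_plan$exon2 == 300L]
  target_genes <- utils::head(target_genes, cfg$n_targets)
  target_mirnas <- mirna[rep_len(seq_len(nrow(mirna)),
                                 length(target_genes)), ]
  targets <- purrr::map_dfr(seq_along(target_genes), function(k) {
    g <- target_genes[k]
    mi <- target_mirnas[k, ]
    L <- nchar(mi$mature)
    feats <- gene_features[gene_features$gene == g &
                             gene_features$type == "exon", ]
    e1 <- feats[1, ]; e2 <- feats[2, ]
    off <- 60L + 7L * k                      # within exon2, clear of ends
    site_g_start <- e2$start + off
    site <- revcomp(mi$mature)
    genome[[e2$scaffold]] <<- `substr<-`(genome[[e2$scaffold]],
                                         site_g_start,
                                         site_g_start + L - 1L, site)
    s <- (e1$end - e1$start + 1L) + off + 1L # 1-based transcript start
    tibble(transcript_id = paste0(g, ".1"), gene = g,
           mirna_id = mi$mirna_id, mature = mi$mature,
           site_start = s, site_end = s + L - 1L,
           cleavage_pos = s + L - 10L)
  })

  transcripts <- purrr::map_dfr(unique(gene_features$gene), function(g) {
    ex <- gene_features[gene_features$gene == g &
                          gene_features$type == "exon", ]
    sq <- paste(vapply(seq_len(nrow(ex)), function(r)
      substring(genome[[ex$scaffold[r]]], ex$start[r], ex$end[r]), ""),
      collapse = "")
    tibble(transcript_id = paste0(g, ".1"), gene = g, seq = sq)
  })

  known <- mirna[mirna$known, ]
  refs <- list(
    ncrna = select(ncrna, "id", "class", "seq"),
    known_mirnas = tibble(id = paste0("ref-", known$mirna_id),
                          family = paste0("miR", 150 + seq_len(nrow(known))),
                          seq = known$mature))

  structure(
    list(genome = genome,
         truth = list(mirna = select(mirna, -"precursor_seq"),
                      precursors = select(mirna, "mirna_id", "precursor_seq"),
                      decoys = decoys, sirna = sirna, targets = targets),
         annotations = list(
           ncrna_loci = select(ncrna, "id", "class", "scaffold",
                               "start", "end"),
           repeats = repeats, gene_features = gene_features),
         refs = refs, transcripts = transcripts, config = cfg),
    class = "sim_data")
}

M_or <- function(x) x # readability no-op for tibble construction

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(paste0("<sim_data> seed %d: %d scaffolds x %d nt, ",
                     "%d miRNA loci (%d DE), %d decoys, %d genes, ",
                     "%d targets\n"),
              x$config$seed, x$config$n_scaffolds, x$config$scaffold_len,
              nrow(x$truth$mirna), sum(x$truth$mirna$is_de),
              nrow(x$truth$decoys), nrow(x$transcripts),
              nrow(x$truth$targets)))
  invisible(x)
}

# -- small-RNA libraries ------------------------------------------------------

# class shares of the background (non-miRNA) depth, loosely following the
# proportions of a real leaf library (rRNA-heavy annotated fraction, a
# dominant unannotated remainder)
bg_shares <- c(rRNA = 0.20, tRNA = 0.02, snRNA = 0.004, snoRNA = 0.004,
               repeat_ = 0.018, exon = 0.004, intron = 0.002,
               decoy = 0.004, sirna = 0.002,
               others_mapped = 0.06, unmapped = 0.674, junk = 0.008)

#' Simulate the two small-RNA read libraries
#'
#' Draws per-sequence counts negative-binomially around the planted means
#' (DT means of DE miRNAs scaled by `2^planted_log2fc`), adds background
#' reads from the ncRNA/repeat/gene/decoy/siRNA loci and from unmappable
#' random sequences, appends the 3' adapter to every read, and sprinkles in
#' a small fraction of junk reads (too short after trimming, or containing
#' N) so the cleaning stage is exercised.
#'
#' @param sim a `sim_data` object from [sim_genome()].
#' @param config optional override of `sim$config`.
#' @return list of two tibbles `cl` and `dt`, each with columns `seq` (raw
#'   read including adapter), `count`, plus attribute `insert` (the clean
#'   insert) for truth checks.
#' @export
sim_srna_libraries <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_data"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  tr <- sim$truth
  phi <- cfg$dispersion

  sub_reads <- function(source_seqs, n_per, mean_count, pool = "shared") {
    # distinct 16-30 nt substrings (24-nt mode) of the source sequences
    purrr::map_dfr(source_seqs, function(sq) {
      L <- nchar(sq)
      lens <- sample(16:30, n_per, replace = TRUE,
                     prob = length_weights())
      starts <- sample(seq_len(max(1, L - 30)), n_per, replace = TRUE)
      tibble(insert = substring(sq, starts, pmin(L, starts + lens - 1)),
             mu = mean_count, pool = pool)
    })
  }

  # planted means were drawn at the genome's configured depth; re-scale if
  # the libraries are drawn at a different depth
  rel <- cfg$read_depth / sim$config$read_depth
  mirna_cl <- tibble(insert = as_dna(c(tr$mirna$mature, tr$mirna$star)),
                     mu = rel * c(tr$mirna$cl_mean,
                                  tr$mirna$cl_mean * cfg$star_fraction),
                     pool = "shared")
  mirna_dt <- tibble(insert = mirna_cl$insert,
                     mu = rel * c(tr$mirna$dt_mean,
                                  tr$mirna$dt_mean * cfg$star_fraction),
                     pool = "shared")

  bg_depth <- max(0, cfg$read_depth - sum(tr$mirna$cl_mean) * 1.1)
  share_mu <- function(class, n_seqs) bg_shares[[class]] * bg_depth /
    max(1, n_seqs)

  nc <- sim$refs$ncrna
  bg <- list()
  for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    src <- nc$seq[nc$class == cls]
    key <- if (cls == "rRNA") "rRNA" else cls
    bg[[cls]] <- sub_reads(src, 20, share_mu(key, length(src) * 20))
  }
  repseqs <- vapply(seq_len(nrow(sim$annotations$repeats)), function(r) {
    rr <- sim$annotations$repeats[r, ]
    substring(sim$genome[[rr$scaffold]], rr$start, rr$end)
  }, "")
  bg$repeats <- sub_reads(repseqs, 15, share_mu("repeat_", length(repseqs) * 15))
  gf <- sim$annotations$gene_features
  exons <- vapply(which(gf$type == "exon"), function(r)
    substring(sim$genome[[gf$scaffold[r]]], gf$start[r], gf$end[r]), "")
  introns <- vapply(which(gf$type == "intron"), function(r)
    substring(sim$genome[[gf$scaffold[r]]], gf$start[r], gf$end[r]), "")
  bg$exon <- sub_reads(utils::head(exons, 6), 4,
                       share_mu("exon", 24))
  bg$intron <- sub_reads(utils::head(introns, 4), 3,
                         share_mu("intron", 12))
  bg$decoy <- tibble(insert = tr$decoys$core_read,
                     mu = share_mu("decoy", nrow(tr$decoys)),
                     pool = "shared")
  if (nrow(tr$sirna)) {
    bg$sirna <- tibble(insert = c(tr$sirna$plus_read, tr$sirna$minus_read),
                       mu = share_mu("sirna", 2 * nrow(tr$sirna)),
                       pool = "shared")
  }
  # unannotated mapped background + unmappable sequences, split into
  # shared / CL-only / DT-only pools for realistic library overlap
  rand_locus_reads <- function(n_loci, pool, reads_per_locus = 5L) {
    # unannotated background arrives in small read piles at scattered loci,
    # like the degradation products it emulates
    n <- n_loci * reads_per_locus
    sc <- rep(sample(names(sim$genome), n_loci, replace = TRUE),
              each = reads_per_locus)
    anchor <- rep(vapply(seq_len(n_loci), function(i)
      sample(seq_len(cfg$scaffold_len - 80L), 1), 1), each = reads_per_locus)
    st <- anchor + sample(0:30, n, replace = TRUE)
    lens <- sample(16:30, n, replace = TRUE, prob = length_weights())
    tibble(insert = substring(unname(sim$genome[sc]), st, st + lens - 1),
           mu = share_mu("others_mapped", 600), pool = pool)
  }
  rand_free_reads <- function(n, pool) {
    lens <- sample(16:30, n, replace = TRUE, prob = length_weights())
    tibble(insert = vapply(lens, rand_dna, ""),
           mu = share_mu("unmapped", 1400), pool = pool)
  }
  bg$om_shared <- rand_locus_reads(60, "shared")
  bg$om_cl <- rand_locus_reads(30, "cl")
  bg$om_dt <- rand_locus_reads(30, "dt")
  bg$un_shared <- rand_free_reads(500, "shared")
  bg$un_cl <- rand_free_reads(450, "cl")
  bg$un_dt <- rand_free_reads(450, "dt")
  # junk: under-length inserts and reads containing N
  bg$junk <- tibble(
    insert = c(vapply(rep(12, 30), rand_dna, ""),
               vapply(rep(24, 30), function(l)
                 sub("^(.{8})(.)", "\\1N", rand_dna(l)), "")),
    mu = share_mu("junk", 60), pool = "shared")

  if (cfg$read_depth <= 0) stop_input("read_depth must be positive")
  background <- bind_rows(bg)
  draw_lib <- function(extra, lab) {
    tab <- bind_rows(extra, background)
    tab <- tab[tab$pool %in% c("shared", lab), ]
    counts <- draw_counts(tab$mu, phi)
    out <- tab[counts > 0, ]
    out$count <- counts[counts > 0]
    out$seq <- paste0(out$insert, cfg$adapter)
    lib <- out %>%
      group_by(.data$seq, .data$insert) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    if (sum(lib$count) == 0) stop_input("empty simulated library")
    lib
  }
  list(cl = draw_lib(mirna_cl, "cl"), dt = draw_lib(mirna_dt, "dt"))
}

length_weights <- function() {
  w <- c(1, 1, 1.5, 2, 2.5, 6, 3, 2.5, 14, 3, 2, 1.5, 1, 1, 1)
  w / sum(w) # lengths 16..30, modes at 21 and a dominant 24
}

# -- degradome ----------------------------------------------------------------

#' Simulate degradome (PARE) tags
#'
#' For every transcript with a planted target, `cleavage_peak_fraction` of
#' its tags start exactly at the planted cleavage position and the
#' remainder start uniformly along the transcript; transcripts without a
#' target receive uniform tags only. Tags are 5'-anchored `tag_len`-nt
#' substrings of their transcript.
#'
#' @param sim a `sim_data` from [sim_genome()].
#' @param config optional override of `sim$config`.
#' @param tag_len tag length (default 20 nt).
#' @return tibble `seq`, `count` of degradome tags.
#' @export
sim_degradome <- function(sim, config = sim$config, tag_len = 20) {
  stopifnot(inherits(sim, "sim_data"))
  cfg <- config
  set.seed(cfg$seed + 2L)
  tx <- sim$transcripts
  tg <- sim$truth$targets
  bad <- !tg$transcript_id %in% tx$transcript_id |
    tg$cleavage_pos > nchar(tx$seq[match(tg$transcript_id,
                                         tx$transcript_id)]) - tag_len + 1
  if (any(bad))
    stop_input("planted cleavage position outside its transcript")
  per_tx <- max(1, round(cfg$degradome_depth / nrow(tx)))
  tags <- purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    sq <- tx$seq[i]; L <- nchar(sq)
    tgt <- tg[tg$transcript_id == tx$transcript_id[i], ]
    npk <- if (nrow(tgt)) round(cfg$cleavage_peak_fraction * per_tx) else 0L
    nuni <- per_tx - npk
    pos <- c(rep(tgt$cleavage_pos[seq_len(min(1, nrow(tgt)))], npk),
             if (nuni > 0) sample(seq_len(L - tag_len + 1), nuni,
                                  replace = TRUE))
    tibble(seq = substring(sq, pos, pos + tag_len - 1))
  })
  tags %>% count(.data$seq, name = "count") %>% arrange(desc(.data$count))
}
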