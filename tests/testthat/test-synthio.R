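# Synthetic study generator: determinism, planted truth, count model,
# degradome tag piles.

tiny_cfg <- function(...) {
  base <- list(seed = 11, n_scaffolds = 3, scaffold_len = 15000,
               n_mirna_loci = 6, n_sirna_loci = 2, n_ncrna_decoys = 2,
               n_genes = 6, read_depth = 3e4, degradome_depth = 6e3,
               de_fraction = 0.5, n_targets = 4)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- sim_genome(tiny_cfg())
  b <- sim_genome(tiny_cfg())
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$mirna, b$truth$mirna)
  c <- sim_genome(tiny_cfg(seed = 12))
  expect_false(identical(a$genome, c$genome))

  la <- sim_srna_libraries(a); lb <- sim_srna_libraries(b)
  expect_identical(la$cl, lb$cl)
  da <- sim_degradome(a); db <- sim_degradome(b)
  expect_identical(da, db)
})

test_that("planted sequences are exact substrings of their sources", {
  sim <- sim_genome(tiny_cfg())
  tr <- sim$truth$mirna
  for (i in seq_len(nrow(tr))) {
    sc <- sim$genome[[tr$scaffold[i]]]
    expect_identical(substring(sc, tr$mature_start[i], tr$mature_end[i]),
                     tr$mature[i])
    # the mature occurs exactly once on the forward strand
    expect_equal(length(gregexpr(tr$mature[i], paste(sim$genome,
                                                     collapse = "N"),
                                 fixed = TRUE)[[1]]), 1)
    prec <- substring(sc, tr$precursor_start[i], tr$precursor_end[i])
    expect_true(grepl(tr$star[i], prec, fixed = TRUE))
  }
  # planted cleavage sites: reverse complement of the mature on the
  # transcript, cleavage opposite miRNA positions 10-11
  tg <- sim$truth$targets
  tx <- sim$transcripts
  for (i in seq_len(nrow(tg))) {
    s <- tx$seq[tx$transcript_id == tg$transcript_id[i]]
    site <- substring(s, tg$site_start[i], tg$site_end[i])
    expect_identical(site, revcomp(tg$mature[i]))
    expect_equal(tg$cleavage_pos[i],
                 tg$site_start[i] + nchar(tg$mature[i]) - 10L)
  }
})

test_that("precursor lengths respect the configured range", {
  cfg <- tiny_cfg()
  sim <- sim_genome(cfg)
  lens <- sim$truth$mirna$precursor_end - sim$truth$mirna$precursor_start + 1
  expect_true(all(lens >= cfg$precursor_len_range[1]))
  expect_true(all(lens <= cfg$precursor_len_range[2]))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(precursor_len_range = c(40, 222)),
               class = "srnapipe_input_error")
  expect_error(sim_config(de_fraction = 0.13, n_mirna_loci = 20),
               class = "srnapipe_input_error")
  expect_error(sim_config(cleavage_peak_fraction = 0),
               class = "srnapipe_input_error")
  expect_error(sim_genome(tiny_cfg(scaffold_len = 600)),
               class = "srnapipe_input_error")
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
             collapse = "")
  sh <- dinuc_shuffle(s)
  dinucs <- function(x) {
    v <- strsplit(x, "")[[1]]
    table(paste0(v[-length(v)], v[-1]))
  }
  expect_equal(nchar(sh), nchar(s))
  expect_equal(as.list(dinucs(sh)), as.list(dinucs(s)))
  expect_false(identical(sh, s))
})

test_that("the count model degenerates to rounded means at zero dispersion", {
  sim <- sim_genome(tiny_cfg(dispersion = 0))
  libs <- sim_srna_libraries(sim)
  tr <- sim$truth$mirna
  cl <- libs$cl
  for (i in seq_len(nrow(tr))) {
    got <- sum(cl$count[cl$insert == tr$mature[i]])
    expect_equal(got, round(tr$cl_mean[i]), info = tr$mirna_id[i])
  }
})

test_that("zero de_fraction plants no fold-changes", {
  sim <- sim_genome(tiny_cfg(de_fraction = 0))
  expect_true(all(sim$truth$mirna$true_log2fc == 0))
  expect_false(any(sim$truth$mirna$is_de))
})

test_that("planted fold-changes are recovered empirically at deep counts", {
  cfg <- tiny_cfg(seed = 21, n_mirna_loci = 10, de_fraction = 0.5,
                  read_depth = 5e5, dispersion = 0.005)
  sim <- sim_genome(cfg)
  libs <- sim_srna_libraries(sim)
  tr <- sim$truth$mirna
  ncl <- sum(libs$cl$count); ndt <- sum(libs$dt$count)
  de <- tr[tr$is_de, ]
  emp <- vapply(seq_len(nrow(de)), function(i) {
    x <- sum(libs$cl$count[libs$cl$insert == de$mature[i]])
    y <- sum(libs$dt$count[libs$dt$insert == de$mature[i]])
    log2((y / ndt) / (x / ncl))
  }, numeric(1))
  expect_gte(mean(abs(emp - cfg$planted_log2fc) <= 0.5), 0.9)
})

test_that("reads carry the adapter and junk reads exercise the filters", {
  cfg <- tiny_cfg()
  sim <- sim_genome(cfg)
  libs <- sim_srna_libraries(sim)
  expect_true(all(endsWith(libs$cl$seq, cfg$adapter)))
  expect_true(any(grepl("N", libs$cl$seq)))
  cfg0 <- cfg; cfg0$read_depth <- 0
  expect_error(sim_srna_libraries(sim, cfg0),
               class = "srnapipe_input_error")
})

test_that("degradome tags pile at the planted cleavage positions", {
  cfg <- tiny_cfg(cleavage_peak_fraction = 1.0)
  sim <- sim_genome(cfg)
  tags <- sim_degradome(sim)
  tg <- sim$truth$targets
  tx <- sim$transcripts
  tp <- map_tags(tags, tx)
  for (i in seq_len(nrow(tg))) {
    p <- tp[tp$transcript_id == tg$transcript_id[i], ]
    # every tag for a targeted transcript starts at the planted site
    expect_equal(p$position[which.max(p$count)], tg$cleavage_pos[i])
    expect_equal(nrow(p[p$count > 1, ]), 1)
  }

  cfg2 <- tiny_cfg(cleavage_peak_fraction = 0.8, degradome_depth = 2e4)
  sim2 <- sim_genome(cfg2)
  tp2 <- map_tags(sim_degradome(sim2), sim2$transcripts)
  tg2 <- sim2$truth$targets
  for (i in seq_len(nrow(tg2))) {
    p <- tp2[tp2$transcript_id == tg2$transcript_id[i], ]
    expect_equal(p$position[which.max(p$count)], tg2$cleavage_pos[i])
  }
  # transcripts without a target have no dominant position
  bare <- setdiff(tx$transcript_id, tg$transcript_id)
  tp3 <- map_tags(sim_degradome(sim2), sim2$transcripts)
  for (id in setdiff(sim2$transcripts$transcript_id,
                     sim2$truth$targets$transcript_id)) {
    p <- tp3[tp3$transcript_id == id, ]
    if (nrow(p)) expect_lt(max(p$count) / sum(p$count), 0.15)
  }
})
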