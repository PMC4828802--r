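# Known/novel miRNA identification: matching, windows, criteria, star
# detection, families and genomic context.

test_that("match_known applies the 2-mismatch equal-length rule", {
  ref <- tibble::tibble(id = c("mir-a", "mir-b"), family = c("famA", "famB"),
                        seq = c("ACGTACGTACGTACGTACGTA",
                                "TTTTGGGGCCCCAAAATTTTG"))
  sub2 <- ref$seq[1]
  substr(sub2, 3, 3) <- "T"; substr(sub2, 10, 10) <- "A"
  sub3 <- sub2; substr(sub3, 15, 15) <- "C"
  hits <- match_known(tibble::tibble(seq = c(ref$seq[1], sub2, sub3)), ref)
  expect_equal(hits$mismatches[hits$seq == ref$seq[1]], 0L)
  expect_equal(hits$mismatches[hits$seq == sub2], 2L)
  expect_false(sub3 %in% hits$seq)
  # best hit wins: equal-distance ties resolved by reference id
  twin <- tibble::tibble(id = c("z-ref", "a-ref"), seq = ref$seq[c(1, 1)])
  h2 <- match_known(tibble::tibble(seq = ref$seq[1]), twin)
  expect_equal(h2$ref_id, "a-ref")
})

test_that("extract_precursors emits clipped windows containing the mature", {
  set.seed(13)
  genome <- c(s = paste(sample(c("A", "C", "G", "T"), 2000,
                               replace = TRUE), collapse = ""))
  mature <- substring(genome[["s"]], 1000, 1021)
  locus <- tibble::tibble(scaffold = "s", start = 1000, end = 1021,
                          strand = "+")
  w <- extract_precursors(genome, locus)
  expect_equal(nrow(w), 3)
  expect_true(all(vapply(w$seq, grepl, logical(1), pattern = mature,
                         fixed = TRUE)))
  # near the scaffold start the windows clip at 1
  locus2 <- tibble::tibble(scaffold = "s", start = 11, end = 32,
                           strand = "+")
  w2 <- extract_precursors(genome, locus2)
  expect_true(all(w2$window_start >= 1))
  expect_error(extract_precursors(genome, tibble::tibble(
    scaffold = "s", start = 1999, end = 2030, strand = "+")),
    class = "srnapipe_input_error")
})

test_that("apply_criteria enforces every threshold at its boundary", {
  prec <- planted_hairpin()
  st <- fold_mfe(prec)
  dup <- duplex_stats("GGCAGCTGCAGTACGATCGGA",
                      revcomp("GGCAGCTGCAGTACGATCGGA"), st)
  v <- apply_criteria(st, dup, n_genomic_loci = 2, is_sirna = FALSE)
  expect_true(attr(v, "pass"))

  # MFE boundary: -18.0 passes (inclusive), anything above fails
  st_weak <- st; st_weak$mfe <- -17.9
  v2 <- apply_criteria(st_weak, dup, 2, FALSE)
  expect_false(v2$pass[v2$criterion == "mfe"])
  st_edge <- st; st_edge$mfe <- -18.0
  v3 <- apply_criteria(st_edge, dup, 2, FALSE)
  expect_true(v3$pass[v3$criterion == "mfe"])

  # duplex mismatches: 5 fail, 4 pass
  dup5 <- dup; dup5$mismatches <- 5L
  expect_false(attr(apply_criteria(st, dup5, 2, FALSE), "pass"))
  dup4 <- dup; dup4$mismatches <- 4L
  expect_true(attr(apply_criteria(st, dup4, 2, FALSE), "pass"))

  # locus count: 30 loci rejected, siRNA signature rejected
  v4 <- apply_criteria(st, dup, 30, FALSE)
  expect_false(v4$pass[v4$criterion == "locus_count"])
  v5 <- apply_criteria(st, dup, 2, TRUE)
  expect_false(v5$pass[v5$criterion == "not_sirna"])

  # relaxing the MFE bound never shrinks the passing set
  relaxed <- apply_criteria(st_weak, dup, 2, FALSE, mfe_max = -10)
  expect_true(attr(relaxed, "pass"))
})

test_that("find_star returns the abundant opposite-arm read", {
  m <- "GGCAGCTGCAGTACGATCGGA"
  e5 <- "ACGTGCGATCGG"
  prec <- planted_hairpin(m, e5 = e5)
  st <- fold_mfe(prec)
  star_start <- nchar(e5) + nchar(m) + 12 + 2 + 1
  star <- substring(prec, star_start, star_start + nchar(m) - 1)
  shifted <- substring(prec, star_start + 1, star_start + nchar(m))
  lib <- tibble::tibble(seq = c(m, star, shifted), count = c(500L, 60L, 55L))
  hit <- find_star(lib, m, prec, st)
  expect_equal(hit$star, star)
  # the lower-count qualifying read loses; bump it to win
  lib2 <- lib; lib2$count <- c(500L, 60L, 600L)
  hit2 <- find_star(lib2, m, prec, st)
  expect_equal(hit2$star, shifted)
  # no opposite-arm reads -> no star
  expect_null(find_star(tibble::tibble(seq = m, count = 5L), m, prec, st))
})

test_that("families cluster by mature similarity and stay stable", {
  cand <- tibble::tibble(
    mature = c("AAAAAAAAAACCCCCCCCCC", "AAAAAAAAAACCCCCCCCCG",
               "GGGGGGGGGGTTTTTTTTTT", "AAAAAAAAAACCCCCCCCCC"),
    status = "novel", family = NA_character_)
  fam <- cluster_families(cand)
  expect_equal(fam$family[1], fam$family[2]) # distance 1
  expect_equal(fam$family[1], fam$family[4]) # identical
  expect_false(fam$family[1] == fam$family[3]) # distance 20
  # known candidates keep their reference family untouched
  cand2 <- tibble::tibble(mature = "ACGT", status = "known",
                          family = "miR156")
  expect_equal(cluster_families(cand2)$family, "miR156")
  # stable across row order
  fam2 <- cluster_families(cand[c(3, 1, 4, 2), ])
  expect_equal(sort(table(fam2$family)), sort(table(fam$family)))
})

test_that("genomic context classifies by precursor midpoint", {
  gm <- tibble::tibble(
    scaffold = "s", start = c(100, 100, 201, 301, 301),
    end = c(400, 200, 300, 400, 400), strand = "+",
    type = c("exon", "CDS", "intron", "exon", "CDS"), gene = "g")
  expect_equal(classify_genomic_context(
    tibble::tibble(scaffold = "s", start = 120, end = 180), gm), "CDS")
  expect_equal(classify_genomic_context(
    tibble::tibble(scaffold = "s", start = 220, end = 280), gm), "intron")
  expect_equal(classify_genomic_context(
    tibble::tibble(scaffold = "s", start = 900, end = 980), gm),
    "intergenic")
})

test_that("planted miRNAs are recovered and decoys rejected end to end", {
  fx <- small_fixture()
  tr <- fx$sim$truth$mirna
  cand <- fx$result$candidates
  pass <- cand[cand$pass, ]
  expect_gte(sum(tr$mature %in% pass$mature) / nrow(tr), 0.9)
  expect_equal(sum(fx$sim$truth$decoys$core_read %in% pass$mature), 0)
  # known and novel sets are disjoint
  expect_equal(length(intersect(pass$mature[pass$status == "known"],
                                pass$mature[pass$status == "novel"])), 0)
  # known candidates match the reference set
  expect_true(all(pass$mature[pass$status == "known"] %in%
                    fx$sim$refs$known_mirnas$seq))
  # arms recorded as planted
  m <- match(pass$mature, tr$mature)
  ok <- !is.na(m)
  expect_true(all(pass$arm[ok] == tr$arm[m[ok]]))
  # planted genomic context is recovered
  expect_true(all(pass$context[ok] == tr$context[m[ok]]))
  # stars: every expressed-star call sits in the planted star set
  with_star <- pass[ok & pass$star_expressed, ]
  expect_true(all(with_star$star %in% tr$star))
})
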