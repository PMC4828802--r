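# Folding engine, stem-loop detection and duplex analysis.

test_that("fold_mfe handles unpairable and simple hairpin sequences", {
  s <- fold_mfe("AAAAAAAAAA")
  expect_equal(s$mfe, 0)
  expect_equal(nrow(s$pairs), 0)
  expect_equal(s$dot_bracket, strrep(".", 10))

  h <- fold_mfe("GGGAAACCC")
  expect_equal(h$mfe, 3 * pair_energies()[["gc"]])
  expect_equal(nrow(h$pairs), 3)
  expect_equal(h$dot_bracket, "(((...)))")

  expect_error(fold_mfe("GGGAXACCC"), class = "srnapipe_input_error")
  expect_error(fold_mfe(strrep("A", 401)), class = "srnapipe_input_error")
})

test_that("fold_mfe energy equals the exhaustive enumeration oracle", {
  set.seed(421)
  for (i in 1:40) {
    n <- sample(6:15, 1)
    s <- rand_rna(n)
    expect_equal(fold_mfe(s)$mfe, oracle_mfe(s), info = s)
  }
})

test_that("folding is deterministic and pair-minimal at its energy", {
  set.seed(7)
  s <- rand_rna(60)
  a <- fold_mfe(s); b <- fold_mfe(s)
  expect_identical(a$dot_bracket, b$dot_bracket)
  expect_identical(a$mfe, b$mfe)
})

test_that("reverse-complement palindromes form maximal stems", {
  set.seed(11)
  for (n_half in c(8, 12, 15)) {
    half <- rand_rna(n_half)
    s <- paste0(half, revcomp(half))
    n <- 2 * n_half
    expect_equal(fold_mfe(s)$npairs, floor((n - 3) / 2))
  }
})

test_that("is_stemloop accepts clean hairpins and rejects everything else", {
  prec <- planted_hairpin()
  sl <- is_stemloop(fold_mfe(prec))
  expect_true(sl$is_stemloop)
  expect_equal(length(sl$arms), 3)
  expect_true(sl$arms$p5[1] < sl$arms$loop[1])
  expect_true(sl$arms$loop[2] < sl$arms$p3[1])

  expect_false(is_stemloop(fold_mfe("ACACACACACACAC"))$is_stemloop)

  # two hairpins side by side: two terminal loops
  one <- planted_hairpin()
  two <- paste0(one, "AAAA", planted_hairpin("TTGACAGAAGAGAGCGAGCAC"))
  st2 <- fold_mfe(two)
  expect_gt(srnapipe:::n_hairpin_loops(st2), 1)
  expect_false(is_stemloop(st2)$is_stemloop)
})

test_that("stem quality bound rejects loose interrupted stems", {
  prec <- planted_hairpin()
  st <- fold_mfe(prec)
  expect_lt(is_stemloop(st)$unpaired_frac, 0.05)
  set.seed(3)
  loose <- vapply(1:10, function(i) {
    is_stemloop(fold_mfe(dinuc_shuffle(prec)))$is_stemloop
  }, logical(1))
  expect_false(any(loose))
})

test_that("duplex_stats reads the canonical duplex off the structure", {
  m <- "GGCAGCTGCAGTACGATCGGA"
  prec <- planted_hairpin(m)
  st <- fold_mfe(prec)
  # fully complementary opposite arm, as planted
  d <- duplex_stats(m, revcomp(m), st)
  expect_equal(d$mismatches, 0L)
  expect_equal(d$max_bulge, 0L)

  # the shifted star with canonical 2-nt 3' overhangs on both strands
  e5 <- "ACGTGCGATCGG"
  star_start <- nchar(e5) + nchar(m) + 12 + 2 + 1
  star <- substring(prec, star_start, star_start + nchar(m) - 1)
  d2 <- duplex_stats(m, star, st)
  expect_equal(d2$overhang_mature_3p, 2L)
  expect_equal(d2$overhang_star_3p, 2L)
  expect_equal(d2$mismatches, 0L)
})

test_that("duplex alignment agrees with a recursive alignment oracle", {
  # printed novel-miRNA pair: mature/star from the emulated study
  mature <- "TGAGCCGAACCAATATCACTC"
  star <- "CGTGGTGTTGTTTCGGCTCATG"
  cols <- srnapipe:::duplex_columns_align(toupper(as_rna(mature)),
                                          toupper(as_rna(star)))
  impl_score <- sum(cols$kind == "pair") -
    sum(cols$kind %in% c("bulge_m", "bulge_s"))
  expect_equal(impl_score, oracle_duplex_score(mature, star))
  d <- duplex_stats(mature, star)
  expect_true(d$mismatches >= 0 && d$max_bulge >= 0)
  # symmetry of the mismatch count
  expect_equal(d$mismatches, duplex_stats(star, mature)$mismatches)
  # random pairs: optimal alignment score always matches the oracle
  set.seed(5)
  for (i in 1:10) {
    a <- rand_rna(12); b <- rand_rna(sample(10:14, 1))
    cl <- srnapipe:::duplex_columns_align(a, b)
    expect_equal(sum(cl$kind == "pair") -
                   sum(cl$kind %in% c("bulge_m", "bulge_s")),
                 oracle_duplex_score(a, b))
  }

  # constructed single-bulge case: one extra base on the mature strand
  m2 <- "GGCAGCTGCAGTACGATCGGA"
  bulged <- paste0(substring(m2, 1, 10), "A", substring(m2, 11))
  d2 <- duplex_stats(bulged, revcomp(m2))
  expect_equal(d2$max_bulge, 1L)
})

test_that("siRNA duplex signature requires the 2-nt 3' overhangs", {
  dup <- tibble::tibble(start = c(100, 98), end = c(120, 118),
                        strand = c("+", "-"), count = c(50, 40))
  expect_true(sirna_duplex_check(dup))
  blunt <- tibble::tibble(start = c(100, 100), end = c(120, 120),
                          strand = c("+", "-"), count = c(50, 40))
  expect_false(sirna_duplex_check(blunt))
  single <- tibble::tibble(start = 100, end = 120, strand = "+", count = 9)
  expect_false(sirna_duplex_check(single))
})
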