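# Read cleaning, collapsing, library overlap, mapping and annotation.

adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("trim_and_filter removes adapters and enforces length bounds", {
  insert26 <- "ACGTACGTACGTACGTACGTACGTAC"
  read <- paste0(insert26, substring(adapter, 1, 10))
  out <- trim_and_filter(read, adapter)
  expect_equal(out$seq, insert26)
  expect_equal(out$trimmed, 10L)

  # 15-nt insert is discarded after trimming
  short <- paste0("ACGTACGTACGTACG", adapter)
  expect_equal(nrow(trim_and_filter(short, adapter)), 0)

  # 30-nt read with no adapter match is retained unchanged
  keep30 <- strrep("AC", 15)
  expect_equal(trim_and_filter(keep30, adapter)$seq, keep30)

  # N-containing and low-quality reads are dropped
  out <- trim_and_filter(
    tibble::tibble(seq = c("ACGTNCGTACGTACGTACGT", strrep("AG", 10)),
                   qual = c(strrep("I", 20), strrep("I", 20))),
    adapter)
  expect_equal(out$seq, strrep("AG", 10))
  lowq <- tibble::tibble(seq = strrep("AG", 10),
                         qual = paste0(strrep("I", 19), "#"))
  expect_equal(nrow(trim_and_filter(lowq, adapter, min_qual = 20)), 0)

  expect_error(trim_and_filter("ACGT", "ACG"),
               class = "srnapipe_input_error")
})

test_that("collapse_reads aggregates duplicates and keeps totals", {
  lib <- collapse_reads(c(strrep("AC", 10), strrep("AC", 10),
                          strrep("GT", 11)), label = "CL")
  expect_equal(attr(lib, "unique_reads"), 2L)
  expect_equal(attr(lib, "total_reads"), 3L)
  expect_equal(glance(lib)$label, "CL")

  empty <- collapse_reads(character(0))
  expect_equal(attr(empty, "total_reads"), 0L)
  expect_equal(nrow(length_distribution(empty)), 0)

  set.seed(2)
  reads <- sample(c("ACGTACGTACGTACGTA", "TTGGCCAATTGGCCAAT",
                    "GACGACGACGACGACGA"), 57, replace = TRUE)
  lib2 <- collapse_reads(reads)
  expect_equal(attr(lib2, "total_reads"), 57L)
  ld <- length_distribution(lib2)
  expect_equal(sum(ld$total_reads), 57L)
})

test_that("overlap_stats partitions the libraries and is symmetric", {
  a <- collapse_reads(tibble::tibble(
    seq = c("AAACCCGGGTTTAAAC", "CCCGGGTTTAAACCCG", "GGGTTTAAACCCGGGT"),
    count = c(10L, 5L, 1L)), "A")
  b <- collapse_reads(tibble::tibble(
    seq = c("AAACCCGGGTTTAAAC", "TTTAAACCCGGGTTTA"),
    count = c(4L, 6L)), "B")
  ov <- overlap_stats(a, b)
  expect_equal(ov$total_reads[ov$type == "shared"], 14) # 10 + 4
  expect_equal(ov$total_reads[ov$type == "total"], 26)
  expect_equal(sum(ov$unique_reads[-1]), ov$unique_reads[1])
  # symmetry: swapping libraries swaps the specific rows
  vo <- overlap_stats(b, a)
  expect_equal(vo$total_reads[vo$type == "A specific"],
               ov$total_reads[ov$type == "A specific"])
  expect_equal(vo$total_pct[vo$type == "shared"],
               ov$total_pct[ov$type == "shared"])

  disjoint <- overlap_stats(
    collapse_reads(strrep("AC", 10), "A"),
    collapse_reads(strrep("GT", 10), "B"))
  expect_equal(disjoint$total_pct[disjoint$type == "shared"], 0)
})

test_that("map_perfect agrees with a naive substring scan on both strands", {
  set.seed(31)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000,
                                  replace = TRUE), collapse = ""),
              chr2 = paste(sample(c("A", "C", "G", "T"), 2000,
                                  replace = TRUE), collapse = ""))
  reads <- c(substring(genome[["chr1"]], 101, 124),    # plus-strand hit
             revcomp(substring(genome[["chr2"]], 501, 521)), # minus-strand
             strrep("ACGT", 6))                        # likely absent
  lm <- map_perfect(tibble::tibble(seq = reads), genome)
  for (r in reads) {
    expected <- oracle_scan(r, genome)
    got <- lm[lm$seq == r, ]
    if (is.null(expected)) {
      expect_equal(nrow(got), 0)
      expect_true(r %in% unmapped_reads(tibble::tibble(seq = reads), lm))
    } else {
      expect_equal(nrow(got), nrow(expected))
      expect_setequal(paste(got$scaffold, got$start, got$strand),
                      paste(expected$scaffold, expected$start,
                            expected$strand))
    }
  }
  expect_true(all(lm$strand[lm$seq == reads[2]] == "-"))
})

test_that("classify_reads applies the annotation precedence", {
  set.seed(5)
  genome <- c(s1 = paste(sample(c("A", "C", "G", "T"), 1000,
                                replace = TRUE), collapse = ""))
  rrna_read <- substring(genome[["s1"]], 51, 72)
  repeat_exon_read <- substring(genome[["s1"]], 301, 322)
  exon_read <- substring(genome[["s1"]], 401, 424)
  anti_read <- revcomp(substring(genome[["s1"]], 441, 462))
  unmapped <- strrep("GATC", 6)
  lib <- collapse_reads(tibble::tibble(
    seq = c(rrna_read, repeat_exon_read, exon_read, anti_read, unmapped),
    count = c(5L, 4L, 3L, 2L, 1L)))
  lm <- map_perfect(lib, genome)
  tab <- classify_reads(
    lib, lm,
    ncrna_ref = tibble::tibble(id = "r1", class = "rRNA",
                               seq = substring(genome[["s1"]], 40, 90)),
    repeat_intervals = tibble::tibble(scaffold = "s1", start = 290,
                                      end = 340),
    gene_models = tibble::tibble(
      scaffold = "s1", start = c(295, 390), end = c(330, 470),
      strand = "+", type = "exon", gene = c("g0", "g1")))
  asg <- attr(tab, "assignment")
  cat_of <- function(s) asg$category[asg$seq == s]
  expect_equal(cat_of(rrna_read), "rRNA")
  expect_equal(cat_of(repeat_exon_read), "repeat") # repeat beats exon
  expect_equal(cat_of(exon_read), "exon_sense")
  expect_equal(cat_of(anti_read), "exon_antisense")
  expect_equal(cat_of(unmapped), "others")
  # conservation of totals
  tot <- tab[tab$category == "Total", ]
  expect_equal(tot$total_reads, attr(lib, "total_reads"))
  expect_equal(tot$unique_reads, attr(lib, "unique_reads"))
  body <- tab[tab$category != "Total", ]
  expect_equal(sum(body$total_reads), tot$total_reads)
})
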