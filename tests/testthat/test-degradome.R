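# Degradome tag mapping, Allen scoring, site finding, category cascade and
# target calling.

test_that("map_tags uses 1-based 5'-end coordinates", {
  tx <- tibble::tibble(transcript_id = "t1",
                       seq = paste(rep("ACGT", 25), collapse = ""))
  tag <- substring(tx$seq, 11, 30) # 0-based 10..29
  tp <- map_tags(c(tag, tag), tx)
  hit <- tp[tp$transcript_id == "t1", ]
  # ACGT repeats every 4 nt, so the 20-mer matches at positions 3,7,11,...
  expect_true(11 %in% hit$position)
  expect_true(all(hit$count[hit$position == 11] == 2))
  # absent tag contributes nothing
  tp2 <- map_tags("GGGGGGGGGGGGGGGGGGGG", tx)
  expect_equal(nrow(tp2), 0)
})

test_that("allen_score follows the positional penalty scheme", {
  m <- "AUGGAGCUCCAAGGAUCCGAA"
  expect_equal(allen_score(m, revcomp(m)), 0)
  # G:U wobble opposite miRNA position 5, inside the doubled 2-13 region
  m2 <- "AUGGGGCUCCAAGGAUCCGAA"
  site <- revcomp(m2)
  # replace the transcript base pairing miRNA position 5 (site position L-4)
  L <- nchar(m2)
  s2 <- site
  substr(s2, L - 4, L - 4) <- "U" # G:U instead of G:C
  expect_equal(allen_score(m2, s2), 1.0) # 0.5 doubled
  # mismatch opposite position 20, outside the doubled region
  s3 <- site
  substr(s3, L - 19, L - 19) <- "C" # position 20 pairs site position L-19
  expect_equal(allen_score(m2, s3), 1.0)
  expect_error(allen_score(m, "ACGU"), class = "srnapipe_input_error")
})

test_that("find_sites returns scored windows with the expected cleavage", {
  set.seed(17)
  mir <- rand_rna(21)
  backbone <- paste(sample(c("A", "C", "G", "U"), 500, replace = TRUE),
                    collapse = "")
  site <- as.character(revcomp(mir))
  tx <- paste0(substring(backbone, 1, 199), site, substring(backbone, 221))
  hits <- find_sites(mir, tx, max_score = 3)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_start, 200L)
  expect_equal(hits$score, 0)
  expect_equal(hits$cleavage_pos, 200L + 21L - 10L)
  # boundary: a site scoring exactly the cutoff is kept
  all_scores <- find_sites(mir, tx, max_score = Inf)
  expect_true(all(find_sites(mir, tx, 4.5)$score <= 4.5))
  expect_gte(nrow(all_scores), nrow(find_sites(mir, tx, 4.5)))
  # random miRNA vs unrelated transcript: no sites at the 4.5 cutoff in
  # most trials
  miss <- vapply(1:20, function(i)
    nrow(find_sites(rand_rna(21), backbone, 4.5)), numeric(1))
  expect_gte(mean(miss == 0), 0.95)
})

test_that("categorize_site implements the five-class cascade", {
  tp <- function(...) tibble::tibble(position = c(...)[c(TRUE, FALSE)],
                                     count = c(...)[c(FALSE, TRUE)])
  # unique maximum -> 0
  expect_equal(categorize_site(tp(5, 50, 9, 5, 30, 5), 5), 0L)
  # tied maximum -> 1
  expect_equal(categorize_site(tp(5, 50, 9, 50, 30, 5), 5), 1L)
  # above the median of occupied positions, not the maximum -> 2
  expect_equal(categorize_site(tp(5, 20, 9, 50, 30, 5, 40, 2), 5), 2L)
  # at or below the median -> 3
  expect_equal(categorize_site(tp(5, 5, 9, 50, 30, 20, 40, 2), 5), 3L)
  expect_equal(categorize_site(tp(5, 2, 9, 50, 30, 20, 40, 2), 5), 3L)
  # single raw read at the site -> 4, tested before the maximum rule
  expect_equal(categorize_site(tp(5, 1, 9, 40), 5), 4L)
  expect_equal(categorize_site(tp(5, 1), 5), 4L)
  # zero-abundance positions are invisible to the median
  with_zero <- tibble::tibble(position = c(5, 9, 30, 40, 60),
                              count = c(20, 50, 5, 2, 0))
  without <- with_zero[with_zero$count > 0, ]
  expect_equal(categorize_site(with_zero[with_zero$count > 0, ], 5),
               categorize_site(without, 5))
  expect_error(categorize_site(tp(9, 3), 5), class = "srnapipe_input_error")
})

test_that("call_targets recovers planted cleavage sites as category 0", {
  fx <- small_fixture()
  tg <- fx$result$targets
  truth <- fx$sim$truth$targets
  pass <- fx$result$candidates[fx$result$candidates$pass, ]
  discovered <- truth[truth$mature %in% pass$mature, ]
  for (i in seq_len(nrow(discovered))) {
    hit <- tg[tg$transcript_id == discovered$transcript_id[i] &
                abs(tg$cleavage_pos - discovered$cleavage_pos[i]) <= 1, ]
    expect_gte(nrow(hit), 1)
    expect_true(any(hit$category == 0))
  }
  # every hit carries exactly one category and a score within the cutoff
  expect_true(all(tg$category %in% 0:4))
  expect_true(all(tg$score <= 4.5))
  # empty degradome -> empty table
  empty <- call_targets(tibble::tibble(mirna_id = "m", mature = rand_rna(21)),
                        map_tags(character(0), fx$sim$transcripts),
                        fx$sim$transcripts)
  expect_equal(nrow(empty), 0)
})

test_that("in-silico prediction is monotone and overlaps validation", {
  fx <- small_fixture()
  pred <- fx$result$predicted_targets
  tg <- fx$result$targets
  expect_true(all(pred$evidence == "predicted"))
  # the validated calls share sites with the pure-complementarity calls
  both <- dplyr::inner_join(
    tg, pred, by = c("mirna_id", "transcript_id"), suffix = c("", ".p"))
  expect_gt(nrow(both), 0)
  # raising the cutoff never removes predictions
  pass <- fx$result$candidates[fx$result$candidates$pass, ][1:3, ]
  mi <- tibble::tibble(mirna_id = pass$mirna_id, mature = pass$mature)
  p1 <- predict_targets_insilico(mi, fx$sim$transcripts, max_score = 2)
  p2 <- predict_targets_insilico(mi, fx$sim$transcripts, max_score = 4)
  expect_gte(nrow(p2), nrow(p1))
})
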