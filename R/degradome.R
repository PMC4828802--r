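# Degradome (PARE) analysis: tag mapping into per-transcript T-plots,
# Allen-style miRNA:target complementarity scoring, cleavage-site
# validation, and the five-category classification of cleavage sites.

#' Map degradome tags onto transcripts
#'
#' Each tag is truncated to its 5'-most `tag_len` nt and matched exactly
#' against every transcript; each perfect match contributes the tag's count
#' at the 1-based transcript position of its 5' end (multi-transcript tags
#' count at every match).
#'
#' @param tags data frame `seq`, `count` (or character vector).
#' @param transcripts data frame `transcript_id`, `seq`.
#' @param tag_len signature length (default 20 nt).
#' @return a `tplot_set`: tibble `transcript_id`, `position`, `count`, with
#'   transcript lengths in attribute `"lengths"`.
#' @export
map_tags <- function(tags, transcripts, tag_len = 20) {
  if (is.character(tags)) tags <- tibble(seq = tags, count = 1L)
  tags <- as_tibble(tags)
  if (is.null(tags[["count"]])) tags$count <- 1L
  tx <- as_tibble(transcripts)
  tags <- tags %>%
    mutate(seq = substring(toupper(as_dna(.data$seq)), 1, tag_len)) %>%
    filter(nchar(.data$seq) == tag_len) %>%
    group_by(.data$seq) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  lens <- setNames(nchar(tx$seq), tx$transcript_id)
  if (!nrow(tags) || !nrow(tx)) {
    return(structure(tibble(transcript_id = character(0),
                            position = integer(0), count = integer(0)),
                     lengths = lens, class = c("tplot_set", "tbl_df",
                                               "tbl", "data.frame")))
  }
  subject <- Biostrings::DNAStringSet(toupper(as_dna(tx$seq)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$seq))
  hits <- purrr::map_dfr(seq_along(subject), function(si) {
    m <- Biostrings::matchPDict(pd, subject[[si]])
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    if (sum(cnt) == 0) return(NULL)
    idx <- rep(seq_along(cnt), cnt)
    tibble(transcript_id = tx$transcript_id[si],
           position = unlist(st, use.names = FALSE),
           count = tags$count[idx])
  })
  if (is.null(hits) || !nrow(hits)) {
    return(structure(tibble(transcript_id = character(0),
                            position = integer(0), count = integer(0)),
                     lengths = lens, class = c("tplot_set", "tbl_df",
                                               "tbl", "data.frame")))
  }
  out <- hits %>%
    group_by(.data$transcript_id, .data$position) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$transcript_id, .data$position)
  structure(out, lengths = lens,
            class = c("tplot_set", class(out)))
}

#' Allen-style complementarity score of a miRNA against a binding site
#'
#' The miRNA (5'->3') is aligned ungapped against the reverse complement of
#' the site. Each mismatch scores 1, each G:U wobble 0.5, and positions
#' 2-13 of the miRNA (the seed-proximal region) double their penalty.
#' Perfect pairs score 0; lower totals mean better complementarity.
#'
#' @param mirna miRNA sequence.
#' @param site transcript window of the same length.
#' @return numeric penalty >= 0.
#' @export
#' @examples
#' allen_score("AUGGAGCUCC", revcomp("AUGGAGCUCC")) # 0
allen_score <- function(mirna, site) {
  m <- toupper(as_rna(mirna)); s <- toupper(as_rna(site))
  if (nchar(m) != nchar(s))
    stop_input("allen_score(): site length must equal miRNA length")
  mc <- chars(m)
  rc <- chars(revcomp(s))
  pen <- ifelse(mc == rc, 0,
                ifelse((mc == "G" & rc == "A") | (mc == "U" & rc == "C"),
                       0.5, 1))
  k <- seq_along(pen)
  sum(pen * ifelse(k >= 2 & k <= 13, 2, 1))
}

#' Candidate miRNA binding sites on a transcript
#'
#' Scores every window of miRNA length along the transcript with
#' [allen_score()] and keeps those at or below `max_score` (boundary
#' inclusive). Each site's expected cleavage position is the transcript
#' base paired to miRNA nucleotide 10.
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence (one string).
#' @param max_score score cutoff (default 4.5).
#' @return tibble `site_start`, `site_end`, `score`, `cleavage_pos`.
#' @export
find_sites <- function(mirna, transcript, max_score = 4.5) {
  m <- toupper(as_rna(mirna)); txs <- toupper(as_rna(transcript))
  L <- nchar(m); n <- nchar(txs)
  if (n < L) return(tibble(site_start = integer(0), site_end = integer(0),
                           score = numeric(0), cleavage_pos = integer(0)))
  mc <- chars(m)
  tc <- chars(txs)
  # complement of transcript, so pairing checks run per offset, vectorised
  comp <- chartr("ACGU", "UGCA", txs)
  cc <- chars(comp)
  nw <- n - L + 1
  pen <- numeric(nw)
  for (k in seq_len(L)) {
    # miRNA position k pairs transcript position (start + L - k)
    tpos <- (L - k + 1):(n - k + 1)
    b <- cc[tpos]                         # complement of transcript base
    p <- ifelse(mc[k] == b, 0,
                ifelse((mc[k] == "G" & b == "A") |
                         (mc[k] == "U" & b == "C"), 0.5, 1))
    pen <- pen + p * (if (k >= 2 && k <= 13) 2 else 1)
  }
  ok <- which(pen <= max_score)
  tibble(site_start = ok, site_end = ok + L - 1L, score = pen[ok],
         cleavage_pos = ok + L - 10L)
}

#' Categorise a cleavage site from its transcript T-plot
#'
#' The five-class cascade: a site whose abundance is a single raw read is
#' category 4; a unique maximum on the transcript is category 0; a tied
#' maximum is 1; above the median of occupied positions is 2; at or below
#' the median is 3. The median is taken over positions with at least one
#' tag only.
#'
#' @param tplot data frame `position`, `count` for one transcript (zero
#'   positions omitted).
#' @param position 1-based cleavage position; must carry tags.
#' @return integer category 0-4.
#' @export
categorize_site <- function(tplot, position) {
  tp <- as_tibble(tplot)
  ab <- tp$count[tp$position == position]
  if (!length(ab) || ab == 0)
    stop_input("no degradome signal at position %d", position)
  if (ab == 1) return(4L)
  mx <- max(tp$count)
  if (ab == mx) {
    if (sum(tp$count == mx) == 1) return(0L) else return(1L)
  }
  if (ab > median(tp$count)) 2L else 3L
}

#' Call degradome-validated miRNA targets
#'
#' For every miRNA x transcript pair, candidate binding sites
#' ([find_sites()]) are checked for degradome tags within `window` nt of
#' the expected cleavage position; a hit is recorded at the coordinate of
#' maximal abundance within the window and categorised against the
#' transcript's T-plot.
#'
#' @param mirnas data frame `mirna_id`, `mature` (and optionally `family`).
#' @param tplots a `tplot_set` from [map_tags()].
#' @param transcripts data frame `transcript_id`, `seq`.
#' @param max_score complementarity cutoff (default 4.5).
#' @param window cleavage-position tolerance in nt (default 1).
#' @return tibble `mirna_id`, `family`, `transcript_id`, `cleavage_pos`,
#'   `site_abundance`, `score`, `category`, sorted by family then
#'   transcript.
#' @export
call_targets <- function(mirnas, tplots, transcripts, max_score = 4.5,
                         window = 1) {
  mi <- as_tibble(mirnas)
  if (is.null(mi[["family"]])) mi$family <- mi$mirna_id
  tx <- as_tibble(transcripts)
  out <- purrr::map_dfr(seq_len(nrow(mi)), function(i) {
    purrr::map_dfr(seq_len(nrow(tx)), function(j) {
      tp <- tplots[tplots$transcript_id == tx$transcript_id[j], ]
      if (!nrow(tp)) return(NULL)
      sites <- find_sites(mi$mature[i], tx$seq[j], max_score = max_score)
      if (!nrow(sites)) return(NULL)
      purrr::map_dfr(seq_len(nrow(sites)), function(s) {
        win <- (sites$cleavage_pos[s] - window):(sites$cleavage_pos[s] + window)
        sig <- tp[tp$position %in% win, ]
        if (!nrow(sig) || all(sig$count == 0)) return(NULL)
        at <- sig$position[which.max(sig$count)]
        tibble(mirna_id = mi$mirna_id[i], family = mi$family[i],
               transcript_id = tx$transcript_id[j],
               cleavage_pos = at,
               site_abundance = max(sig$count),
               score = sites$score[s],
               category = categorize_site(tp, at))
      })
    })
  })
  if (is.null(out) || !nrow(out))
    return(tibble(mirna_id = character(0), family = character(0),
                  transcript_id = character(0), cleavage_pos = integer(0),
                  site_abundance = integer(0), score = numeric(0),
                  category = integer(0)))
  arrange(out, .data$family, .data$transcript_id, .data$cleavage_pos)
}

#' Predict miRNA targets by complementarity alone
#'
#' In-silico prediction without degradome evidence: every site at or below
#' `max_score` is reported and flagged `predicted`, to be contrasted with
#' degradome-validated hits.
#'
#' @inheritParams call_targets
#' @param max_score cutoff (default 3.0, stricter than the validated call).
#' @return tibble `mirna_id`, `family`, `transcript_id`, `site_start`,
#'   `site_end`, `cleavage_pos`, `score`, `evidence` = "predicted".
#' @export
predict_targets_insilico <- function(mirnas, transcripts, max_score = 3.0) {
  mi <- as_tibble(mirnas)
  if (is.null(mi[["family"]])) mi$family <- mi$mirna_id
  tx <- as_tibble(transcripts)
  out <- purrr::map_dfr(seq_len(nrow(mi)), function(i) {
    purrr::map_dfr(seq_len(nrow(tx)), function(j) {
      sites <- find_sites(mi$mature[i], tx$seq[j], max_score = max_score)
      if (!nrow(sites)) return(NULL)
      tibble(mirna_id = mi$mirna_id[i], family = mi$family[i],
             transcript_id = tx$transcript_id[j], sites)
    })
  })
  if (is.null(out) || !nrow(out))
    return(tibble(mirna_id = character(0), family = character(0),
                  transcript_id = character(0), site_start = integer(0),
                  site_end = integer(0), score = numeric(0),
                  cleavage_pos = integer(0), evidence = character(0)))
  mutate(out, evidence = "predicted")
}

#' T-plot of one transcript
#'
#' Degradome tag abundance by 5'-end position, with optional cleavage-site
#' highlighting.
#'
#' @param tplots a `tplot_set`.
#' @param transcript_id transcript to plot.
#' @param highlight optional positions to mark (e.g. called cleavage
#'   sites).
#' @return a ggplot object.
#' @export
plot_tplot <- function(tplots, transcript_id, highlight = NULL) {
  tp <- tplots[tplots$transcript_id == transcript_id, ]
  p <- ggplot2::ggplot(tp, ggplot2::aes(x = .data$position,
                                        y = .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::labs(title = transcript_id, x = "transcript position (nt)",
                  y = "tag abundance") +
    ggplot2::theme_minimal()
  if (!is.null(highlight))
    p <- p + ggplot2::geom_vline(xintercept = highlight,
                                 colour = "red", linetype = "dashed")
  p
}
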