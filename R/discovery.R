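# Known and novel miRNA identification: reference matching, precursor
# window extraction, hairpin trimming, the four identification criteria plus
# siRNA/locus-count exclusion, star detection, family clustering and
# genomic-context classification.

#' Default discovery parameters
#'
#' Thresholds of the identification criteria and their companions: hairpin
#' required (minimum stem 15 bp), at most 4 miRNA:miRNA* duplex mismatches,
#' asymmetric bulges of at most 2 nt, precursor MFE at most -18 kcal/mol
#' (inclusive), at most 24 perfect genomic loci, no siRNA duplex signature;
#' reference matching within 2 substitutions; locus clustering gap 200 nt
#' with at least 5 reads per locus.
#'
#' @param ... overrides of any default.
#' @return named list of parameters.
#' @export
discovery_params <- function(...) {
  p <- list(flank = 250L, min_stem = 15L, mfe_max = -18.0,
            max_duplex_mm = 4L, max_bulge = 2L, max_loci = 24L,
            max_mm = 2L, cluster_gap = 200L, min_locus_count = 5L,
            min_len = 16L, max_len = 30L, require_star = FALSE)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Match library sequences to reference mature miRNAs
#'
#' A library sequence hits a reference mature iff the two have equal length
#' and Hamming distance at most `max_mm` (substitutions only, no indels).
#' The best hit (fewest mismatches, ties by lexicographic reference id) is
#' retained per sequence.
#'
#' @param lib a `collapsed_library` or data frame with `seq`.
#' @param mature_ref data frame with `id`, `seq` and optionally `family`.
#' @param max_mm maximum substitutions (default 2).
#' @return tibble `seq`, `ref_id`, `family`, `mismatches`.
#' @export
match_known <- function(lib, mature_ref, max_mm = 2) {
  seqs <- unique(as_dna(as_tibble(lib)$seq))
  ref <- as_tibble(mature_ref)
  if (is.null(ref[["family"]])) ref$family <- ref$id
  ref$seq <- as_dna(ref$seq)
  hits <- purrr::map_dfr(seq_len(nrow(ref)), function(r) {
    rs <- ref$seq[r]
    cand <- seqs[nchar(seqs) == nchar(rs)]
    if (!length(cand)) return(NULL)
    rm_ <- chars(rs)
    mm <- vapply(cand, function(s)
      sum(chars(s) != rm_), numeric(1), USE.NAMES = FALSE)
    ok <- mm <= max_mm
    if (!any(ok)) return(NULL)
    tibble(seq = cand[ok], ref_id = ref$id[r], family = ref$family[r],
           mismatches = as.integer(mm[ok]))
  })
  if (!nrow(hits)) return(tibble(seq = character(0), ref_id = character(0),
                                 family = character(0),
                                 mismatches = integer(0)))
  hits %>%
    arrange(.data$seq, .data$mismatches, .data$ref_id) %>%
    distinct(.data$seq, .keep_all = TRUE)
}

#' Candidate precursor windows around a mature locus
#'
#' Emits the three windows `[start - f, end + g]` for
#' `(f, g) in {(flank, 20), (20, flank), (flank/2, flank/2)}`, clipped to
#' scaffold bounds. Window sequences are strand-oriented (reverse
#' complemented for minus-strand loci) so the mature always occurs forward.
#'
#' @param genome named character vector of scaffolds.
#' @param locus one-row data frame: `scaffold`, `start`, `end`, `strand`.
#' @param flank flank size in nt (default 250).
#' @return tibble `window_start`, `window_end` (plus-strand 1-based
#'   inclusive), `strand`, `seq`.
#' @export
extract_precursors <- function(genome, locus, flank = 250) {
  sc <- genome[[locus$scaffold]]
  if (is.null(sc) || locus$start < 1 || locus$end > nchar(sc))
    stop_input("locus outside scaffold bounds")
  fg <- list(c(flank, 20L), c(20L, flank),
             c(floor(flank / 2), floor(flank / 2)))
  purrr::map_dfr(fg, function(w) {
    up <- if (locus$strand == "+") w[1] else w[2]
    dn <- if (locus$strand == "+") w[2] else w[1]
    ws <- max(1L, locus$start - up)
    we <- min(nchar(sc), locus$end + dn)
    sq <- substring(sc, ws, we)
    if (locus$strand == "-") sq <- revcomp(sq)
    tibble(window_start = ws, window_end = we, strand = locus$strand,
           seq = sq)
  }) %>% distinct(.data$window_start, .data$window_end, .keep_all = TRUE)
}

#' Apply the miRNA identification criteria
#'
#' The candidate passes iff (1) its precursor folds into a single stem-loop
#' hairpin, (2) the miRNA:miRNA* duplex has at most `max_duplex_mm`
#' mismatches, (3) no asymmetric bulge exceeds `max_bulge` nt, (4) the
#' precursor MFE is at most `mfe_max` kcal/mol, the mature maps to at most
#' `max_loci` genomic loci, and the locus does not carry an siRNA duplex
#' signature.
#'
#' @param structure precursor `hairpin_structure`.
#' @param duplex one-row duplex tibble from [duplex_stats()], or NULL when
#'   no star/arm could be evaluated.
#' @param n_genomic_loci perfect-match locus count of the mature.
#' @param is_sirna result of [sirna_duplex_check()] at the locus.
#' @param mfe_max,max_duplex_mm,max_bulge,max_loci,min_stem thresholds (see
#'   [discovery_params()]).
#' @return tibble of per-criterion rows: `criterion`, `pass`, `reason`,
#'   with attribute `pass` (overall).
#' @export
apply_criteria <- function(structure, duplex, n_genomic_loci, is_sirna,
                           mfe_max = -18.0, max_duplex_mm = 4,
                           max_bulge = 2, max_loci = 24, min_stem = 15) {
  sl <- is_stemloop(structure, min_stem = min_stem)
  mm <- if (is.null(duplex)) NA_integer_ else duplex$mismatches
  bg <- if (is.null(duplex)) NA_integer_ else duplex$max_bulge
  v <- tibble(
    criterion = c("stemloop", "duplex_mismatches", "bulge", "mfe",
                  "locus_count", "not_sirna"),
    pass = c(sl$is_stemloop,
             !is.na(mm) && mm <= max_duplex_mm,
             !is.na(bg) && bg <= max_bulge,
             structure$mfe <= mfe_max,
             n_genomic_loci <= max_loci,
             !is_sirna),
    reason = c(
      sprintf("%d pairs, %d hairpin loop(s)", structure$npairs,
              n_hairpin_loops(structure)),
      sprintf("duplex mismatches = %s", mm),
      sprintf("max bulge = %s nt", bg),
      sprintf("MFE = %.1f kcal/mol", structure$mfe),
      sprintf("%d genomic loci", n_genomic_loci),
      sprintf("siRNA duplex signature: %s", is_sirna)))
  structure(v, pass = all(v$pass))
}

#' Find the expressed miRNA* for a candidate
#'
#' Searches the library for sequences lying on the precursor arm opposite
#' the mature whose duplex with the mature shows the canonical 2-nt 3'
#' overhang on both strands (within `tol` nt). The most abundant qualifying
#' sequence wins; ties go to the 5'-most.
#'
#' @param lib a `collapsed_library` (or tibble `seq`, `count`).
#' @param mature mature sequence (same alphabet as the precursor).
#' @param precursor_seq precursor sequence.
#' @param structure folded precursor.
#' @param tol overhang tolerance in nt (default 1).
#' @return one-row tibble `star`, `count`, `start` or NULL when no
#'   qualifying read exists.
#' @export
find_star <- function(lib, mature, precursor_seq, structure, tol = 1) {
  entries <- as_tibble(lib)[, c("seq", "count")]
  prec <- structure$sequence
  m <- locate_in(prec, toupper(as_rna(mature)))
  if (is.null(m)) return(NULL)
  sl <- is_stemloop(structure, min_stem = 1, max_unpaired_frac = 1)
  if (is.null(sl$arms)) return(NULL)
  loop_mid <- mean(sl$arms$loop)
  mature_5p <- mean(m) < loop_mid
  cand <- purrr::map_dfr(seq_len(nrow(entries)), function(i) {
    s <- toupper(as_rna(entries$seq[i]))
    if (identical(s, toupper(as_rna(mature)))) return(NULL)
    pos <- locate_in(prec, s)
    if (is.null(pos)) return(NULL)
    on_3p <- mean(pos) > loop_mid
    if (mature_5p != on_3p) return(NULL) # opposite arm only
    d <- duplex_stats(mature, s, structure)
    ok <- abs(d$overhang_mature_3p - 2) <= tol &&
      abs(d$overhang_star_3p - 2) <= tol && d$paired >= 10
    if (!ok) return(NULL)
    tibble(star = entries$seq[i], count = entries$count[i], start = pos[1])
  })
  if (is.null(cand) || !nrow(cand)) return(NULL)
  cand %>% arrange(desc(.data$count), .data$start) %>% head(1)
}

#' Genomic context of a precursor locus
#'
#' CDS if the precursor midpoint falls in an annotated CDS, intron if in an
#' intron, intergenic otherwise.
#'
#' @param locus one-row data frame `scaffold`, `start`, `end`.
#' @param gene_models feature data frame (`scaffold`, `start`, `end`,
#'   `type`).
#' @return "CDS", "intron" or "intergenic".
#' @export
classify_genomic_context <- function(locus, gene_models) {
  if (is.null(gene_models) || !nrow(gene_models)) return("intergenic")
  mid <- floor((locus$start + locus$end) / 2)
  gm <- gene_models[gene_models$scaffold == locus$scaffold &
                      gene_models$start <= mid & gene_models$end >= mid, ]
  if (any(gm$type == "CDS")) "CDS"
  else if (any(gm$type == "intron")) "intron"
  else "intergenic"
}

#' Cluster candidate matures into families
#'
#' Known candidates inherit their reference family. Novel candidates are
#' single-linkage clustered: two matures of equal length within Hamming
#' distance 2 share a family. Novel family ids are assigned in alphabetical
#' order of each cluster's smallest mature so they are stable across runs.
#'
#' @param candidates tibble with `mature`, `status` and (for known rows)
#'   `family`.
#' @param max_mm linkage distance (default 2).
#' @return the tibble with `family` filled for every row.
#' @export
cluster_families <- function(candidates, max_mm = 2) {
  cand <- as_tibble(candidates)
  novel <- which(cand$status == "novel")
  if (!length(novel)) return(cand)
  seqs <- cand$mature[novel]
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (nchar(seqs[i]) != nchar(seqs[j])) next
      if (sum(chars(seqs[i]) != chars(seqs[j])) <= max_mm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, numeric(1))
  key <- vapply(split(seqs, root), min, "") # smallest mature per cluster
  fam_order <- rank(key, ties.method = "first")
  fam <- sprintf("sit_novel_fam%02d",
                 fam_order[match(as.character(root), names(key))])
  cand$family[novel] <- fam
  cand
}

# -- candidate evaluation -----------------------------------------------------

# Evaluate one mature/locus pair: window extraction, folding, hairpin
# trimming, star detection and the criteria. Returns a one-row tibble or
# NULL when no window yields a foldable hairpin candidate.
evaluate_candidate <- function(mature, locus, genome, lib_counts, locus_map,
                               params, locus_reads = NULL) {
  mature <- toupper(as_dna(mature))
  windows <- extract_precursors(genome, locus, flank = params$flank)
  n_loci <- sum(locus_map$seq == mature)
  is_sirna <- if (is.null(locus_reads)) FALSE else
    sirna_duplex_check(locus_reads)
  best <- NULL
  for (w in seq_len(nrow(windows))) {
    wseq <- windows$seq[w]
    if (nchar(wseq) < 10 || nchar(wseq) > 400) next
    wst <- fold_mfe(wseq)
    anchor <- locate_in(wst$sequence, as_rna(mature))
    if (is.null(anchor)) next
    hp <- extract_hairpin(wst, anchor)
    if (is.null(hp)) next
    pseq <- substring(wseq, hp[1], hp[2])
    if (nchar(pseq) < 50) next
    pst <- fold_mfe(pseq)
    m <- locate_in(pst$sequence, as_rna(mature))
    if (is.null(m)) next
    sl <- is_stemloop(pst, min_stem = params$min_stem)
    arm <- candidate_arm(pst, m)
    star_hit <- find_star(lib_counts, mature, pseq, pst)
    dup <- if (!is.null(star_hit)) {
      duplex_stats(mature, star_hit$star, pst)
    } else projected_duplex(pst, m)
    verdicts <- apply_criteria(pst, dup, n_loci, is_sirna,
                               mfe_max = params$mfe_max,
                               max_duplex_mm = params$max_duplex_mm,
                               max_bulge = params$max_bulge,
                               max_loci = params$max_loci,
                               min_stem = params$min_stem)
    # precursor genomic coordinates (plus strand)
    if (windows$strand[w] == "+") {
      ps <- windows$window_start[w] + hp[1] - 1L
      pe <- windows$window_start[w] + hp[2] - 1L
    } else {
      pe <- windows$window_end[w] - hp[1] + 1L
      ps <- windows$window_end[w] - hp[2] + 1L
    }
    row <- tibble(
      mature = mature, star = if (is.null(star_hit)) NA_character_ else
        as_dna(star_hit$star),
      star_expressed = !is.null(star_hit),
      arm = arm, length = nchar(mature),
      scaffold = locus$scaffold, precursor_start = ps, precursor_end = pe,
      strand = windows$strand[w], precursor_seq = as_dna(pseq),
      precursor_len = nchar(pseq),
      mfe = pst$mfe, n_stem_pairs = pst$npairs,
      dot_bracket = pst$dot_bracket,
      duplex_mismatches = if (is.null(dup)) NA_integer_ else dup$mismatches,
      duplex_max_bulge = if (is.null(dup)) NA_integer_ else dup$max_bulge,
      n_genomic_loci = n_loci,
      pass = attr(verdicts, "pass") &&
        (!params$require_star || !is.null(star_hit)),
      verdicts = list(verdicts))
    if (is.null(best) ||
        (row$pass && !best$pass) ||
        (row$pass == best$pass && row$mfe < best$mfe)) best <- row
  }
  best
}

candidate_arm <- function(structure, m) {
  sl <- is_stemloop(structure, min_stem = 1, max_unpaired_frac = 1)
  if (is.null(sl$arms)) return(NA_character_)
  if (mean(m) < mean(sl$arms$loop)) "5p" else "3p"
}

# canonical star implied by the fold: the region paired with the mature,
# shifted 2 nt toward its 3' end
projected_duplex <- function(structure, m) {
  partners <- structure$partner[m[1]:m[2]]
  partners <- partners[partners > 0]
  if (length(partners) < 5) return(NULL)
  s <- c(min(partners) + 2L, max(partners) + 2L)
  s <- pmin(pmax(s, 1L), nchar(structure$sequence))
  star <- substring(structure$sequence, s[1], s[2])
  duplex_stats(substring(structure$sequence, m[1], m[2]), star, structure)
}

#' Predict novel miRNAs from unannotated reads
#'
#' Clusters unannotated mapped reads into loci (same scaffold and strand,
#' gap at most `cluster_gap` nt), takes each locus's most abundant read as
#' the mature candidate, evaluates the identification criteria on the best
#' precursor window, and drops candidates overlapping known miRNA loci or
#' other, stronger candidates.
#'
#' @param unannotated_lib tibble `seq`, `count` of reads not annotated as
#'   ncRNA, repeat, or known miRNA.
#' @param genome named character vector of scaffolds.
#' @param locus_map [map_perfect()] result covering `unannotated_lib`.
#' @param params [discovery_params()].
#' @param known_loci optional tibble of `scaffold`, `start`, `end` occupied
#'   by known miRNAs.
#' @return candidate tibble (one row per accepted or rejected locus; column
#'   `pass` holds the verdict), or an empty tibble.
#' @export
predict_novel <- function(unannotated_lib, genome, locus_map,
                          params = discovery_params(), known_loci = NULL) {
  lib <- as_tibble(unannotated_lib)
  lm <- locus_map %>%
    inner_join(lib[, c("seq", "count")], by = "seq") %>%
    arrange(.data$scaffold, .data$strand, .data$start)
  if (!nrow(lm)) return(empty_candidates())
  lm <- lm %>%
    group_by(.data$scaffold, .data$strand) %>%
    mutate(cluster = cumsum(c(1L, as.integer(
      .data$start[-1] - cummax(.data$end)[-dplyr::n()] > params$cluster_gap)))) %>%
    ungroup()
  clusters <- lm %>%
    group_by(.data$scaffold, .data$strand, .data$cluster) %>%
    filter(sum(.data$count[!duplicated(.data$seq)]) >= params$min_locus_count) %>%
    group_split()
  out <- purrr::map_dfr(clusters, function(cl) {
    top <- cl %>% arrange(desc(.data$count), .data$start) %>% head(1)
    locus <- tibble(scaffold = top$scaffold, start = top$start,
                    end = top$end, strand = top$strand)
    if (!is.null(known_loci) && nrow(known_loci)) {
      clash <- known_loci$scaffold == locus$scaffold &
        known_loci$start <= locus$end & known_loci$end >= locus$start
      if (any(clash)) return(NULL)
    }
    locus_reads <- cl %>%
      distinct(.data$seq, .keep_all = TRUE) %>%
      select("start", "end", "strand", "count")
    cand <- evaluate_candidate(top$seq, locus, genome, lib, locus_map,
                               params, locus_reads = locus_reads)
    if (is.null(cand)) return(NULL)
    cand$count <- top$count
    cand
  })
  if (is.null(out) || !nrow(out)) return(empty_candidates())
  dedup_candidates(out)
}

empty_candidates <- function() tibble(mature = character(0))

# overlapping candidate precursors collapse to the strongest
# (higher count, then lower MFE)
dedup_candidates <- function(cand) {
  cand <- cand %>% arrange(desc(.data$pass), desc(.data$count), .data$mfe)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) for (j in (i + 1):nrow(cand)) {
      if (!keep[j]) next
      same <- cand$scaffold[j] == cand$scaffold[i] &&
        cand$precursor_start[j] <= cand$precursor_end[i] &&
        cand$precursor_end[j] >= cand$precursor_start[i]
      if (same || cand$mature[j] == cand$mature[i]) keep[j] <- FALSE
    }
  }
  cand[keep, ]
}

#' Identify known and novel miRNAs in two libraries
#'
#' End-to-end discovery: reference matching (known), locus clustering of
#' the remaining unannotated reads (novel), criteria evaluation, star
#' detection, family clustering and genomic-context classification.
#'
#' @param lib_cl,lib_dt `collapsed_library` objects (clean inserts).
#' @param genome named character vector of scaffolds.
#' @param known_ref reference mature set (`id`, `family`, `seq`) or NULL.
#' @param annotation an `annotation_table` assignment for the union library
#'   (used to exclude ncRNA/repeat reads from novel prediction), or NULL.
#' @param gene_models feature tibble for context classification, or NULL.
#' @param locus_map optional precomputed [map_perfect()] of the union
#'   library.
#' @param params [discovery_params()].
#' @return tibble of class `mirna_candidates`; one row per evaluated
#'   candidate with criteria verdicts, counts in both libraries, family and
#'   context. Rows with `pass == TRUE` are the identified miRNAs.
#' @export
discover_mirnas <- function(lib_cl, lib_dt, genome, known_ref = NULL,
                            annotation = NULL, gene_models = NULL,
                            locus_map = NULL, params = discovery_params()) {
  union_lib <- full_join(
    tidy(lib_cl) %>% select("seq", count_cl = "count"),
    tidy(lib_dt) %>% select("seq", count_dt = "count"), by = "seq") %>%
    mutate(count_cl = dplyr::coalesce(.data$count_cl, 0L),
           count_dt = dplyr::coalesce(.data$count_dt, 0L),
           count = .data$count_cl + .data$count_dt)
  if (is.null(locus_map)) locus_map <- map_perfect(union_lib, genome)

  # known candidates
  known <- if (is.null(known_ref)) NULL else {
    hits <- match_known(union_lib, known_ref, max_mm = params$max_mm)
    if (nrow(hits)) {
      purrr::map_dfr(seq_len(nrow(hits)), function(h) {
        seqh <- hits$seq[h]
        loci <- locus_map[locus_map$seq == seqh, ]
        if (!nrow(loci)) return(NULL)
        cand <- NULL
        for (l in seq_len(min(nrow(loci), 8))) { # best-scoring locus wins
          c2 <- evaluate_candidate(seqh, loci[l, ], genome, union_lib,
                                   locus_map, params)
          if (is.null(c2)) next
          if (is.null(cand) || (c2$pass && !cand$pass) ||
              (c2$pass == cand$pass && c2$mfe < cand$mfe)) cand <- c2
        }
        if (is.null(cand)) return(NULL)
        cand$count <- union_lib$count[union_lib$seq == seqh][1]
        cand$family <- hits$family[h]
        cand$ref_id <- hits$ref_id[h]
        cand$ref_mismatches <- hits$mismatches[h]
        cand$status <- "known"
        cand
      })
    } else NULL
  }

  # unannotated set for novel prediction: drop ncRNA/repeat/known-miRNA
  excluded <- character(0)
  if (!is.null(annotation)) {
    asg <- attr(annotation, "assignment")
    excluded <- asg$seq[asg$category %in%
                          c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                            "miRNA")]
  }
  if (!is.null(known) && nrow(known)) excluded <- c(excluded, known$mature)
  unann <- union_lib %>% filter(!.data$seq %in% excluded)
  known_loci <- if (!is.null(known) && nrow(known))
    known %>% select("scaffold", start = "precursor_start",
                     end = "precursor_end") else NULL
  novel <- predict_novel(unann, genome, locus_map, params = params,
                         known_loci = known_loci)
  if (nrow(novel)) novel$status <- "novel"

  cand <- bind_rows(known, novel)
  if (!nrow(cand)) return(structure(empty_candidates(),
                                    class = c("mirna_candidates",
                                              class(empty_candidates()))))
  if (is.null(cand[["family"]])) cand$family <- NA_character_
  cand <- cand %>%
    left_join(union_lib %>% select("seq", "count_cl", "count_dt"),
              by = c(mature = "seq")) %>%
    mutate(count_cl = dplyr::coalesce(.data$count_cl, 0L),
           count_dt = dplyr::coalesce(.data$count_dt, 0L))
  cand <- cluster_families(cand, max_mm = params$max_mm)
  cand$context <- vapply(seq_len(nrow(cand)), function(i)
    classify_genomic_context(
      tibble(scaffold = cand$scaffold[i], start = cand$precursor_start[i],
             end = cand$precursor_end[i]), gene_models), "")
  novel_rows <- which(cand$status == "novel")
  ids <- character(nrow(cand))
  ids[cand$status == "known"] <-
    sprintf("sit-%s-%s", cand$family[cand$status == "known"],
            cand$arm[cand$status == "known"])
  if (length(novel_rows))
    ids[novel_rows] <- sprintf("sit_novel_miR%02d", seq_along(novel_rows))
  cand$mirna_id <- make.unique(ids, sep = "_")
  cand <- cand %>% relocate("mirna_id", "status", "family")
  structure(cand, class = c("mirna_candidates", class(cand)))
}
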