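# RNA secondary structure: minimum-energy folding under a per-pair energy
# model, stem-loop detection, and miRNA:miRNA* duplex analysis.

#' Default per-pair energies (kcal/mol)
#'
#' The folding engine minimises the sum of per-pair stacking-free energies
#' e(G:C) = -3.0, e(A:U) = -2.0, e(G:U) = -1.0 kcal/mol with a minimum
#' hairpin loop of 3 nt and no loop penalties. This is a deliberately simple
#' Nussinov-style model: hairpin acceptance thresholds (see
#' [apply_criteria()]) are calibrated against it, and it is not expected to
#' reproduce nearest-neighbour (Turner model) energies.
#'
#' @return named numeric vector with elements `gc`, `au`, `gu`.
#' @export
pair_energies <- function() c(gc = -3.0, au = -2.0, gu = -1.0)

#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' Dynamic-programming minimisation of total pair energy over all nested
#' (pseudoknot-free) structures. Ties are broken toward fewer pairs, then by
#' a fixed deterministic traceback order, so identical input always yields an
#' identical structure.
#'
#' @param seq a single RNA (or DNA; T is read as U) sequence, 10-400 nt,
#'   alphabet ACGU/ACGT.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param energies named vector as returned by [pair_energies()].
#' @return an object of class `hairpin_structure`: a list with elements
#'   `sequence` (RNA), `partner` (integer vector, 0 = unpaired),
#'   `pairs` (tibble of i < j index pairs), `dot_bracket`, `mfe`
#'   (kcal/mol, <= 0) and `npairs`.
#' @export
#' @examples
#' fold_mfe("GGGAAACCC")$mfe # 3 G:C pairs -> -9
fold_mfe <- function(seq, min_loop = 3, energies = pair_energies()) {
  stopifnot(is.character(seq), length(seq) == 1)
  rna <- toupper(as_rna(seq))
  n <- nchar(rna)
  if (n < 1 || n > 400)
    stop_input("fold_mfe() expects 1-400 nt, got %d", n)
  if (grepl("[^ACGU]", rna))
    stop_input("fold_mfe() sequence contains characters outside ACGU")
  res <- .nussinov_fold(rna, as.integer(min_loop),
                        energies[["gc"]], energies[["au"]], energies[["gu"]])
  partner <- res$partner
  i <- which(partner > seq_len(n))
  pairs <- tibble(i = i, j = partner[i])
  db <- rep(".", n)
  db[pairs$i] <- "("
  db[pairs$j] <- ")"
  structure(
    list(sequence = rna, partner = partner, pairs = pairs,
         dot_bracket = paste(db, collapse = ""),
         mfe = res$mfe, npairs = res$npairs, min_loop = min_loop),
    class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat("<hairpin_structure> ", nchar(x$sequence), " nt, ",
      x$npairs, " pairs, MFE ", format(x$mfe), " kcal/mol\n", sep = "")
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' @describeIn fold_mfe base pairs of a folded structure as a tibble.
#' @param x a `hairpin_structure`.
#' @param ... unused.
#' @export
tidy.hairpin_structure <- function(x, ...) {
  mutate(x$pairs,
         base_i = substring(x$sequence, .data$i, .data$i),
         base_j = substring(x$sequence, .data$j, .data$j))
}

#' @describeIn fold_mfe one-row summary (length, pairs, MFE, hairpin count).
#' @export
glance.hairpin_structure <- function(x, ...) {
  tibble(length = nchar(x$sequence), npairs = x$npairs, mfe = x$mfe,
         n_hairpin_loops = n_hairpin_loops(x),
         is_stemloop = is_stemloop(x)$is_stemloop)
}

# number of terminal (hairpin) loops = runs "(" ... ")" with only dots between
n_hairpin_loops <- function(structure) {
  stringr::str_count(structure$dot_bracket, "\\(\\.*\\)")
}

#' Test whether a folded structure is a marked stem-loop hairpin
#'
#' A structure qualifies when it has exactly one terminal loop (hence no
#' multiloop), a stem of at least `min_stem` base pairs, and a well-paired
#' stem: at most `max_unpaired_frac` of the bases between the outermost and
#' innermost pairs (terminal loop excluded) may be unpaired. Occasional
#' bulges and small internal loops are therefore allowed, while the loose,
#' interrupted stems that arbitrary sequences form under a maximum-pairing
#' energy model are not. The unpaired-fraction bound is calibrated to this
#' package's per-pair energy model (see the package vignette).
#'
#' @param structure a `hairpin_structure` from [fold_mfe()].
#' @param min_stem minimum number of base pairs in the stem (default 15,
#'   typical of plant pre-miRNA stems).
#' @param max_unpaired_frac maximum unpaired fraction within the stem span
#'   (default 0.15).
#' @return a list with `is_stemloop` (logical), `unpaired_frac`, and, when
#'   true, `arms`: 1-based inclusive intervals `p5`, `loop`, `p3`.
#' @export
is_stemloop <- function(structure, min_stem = 15, max_unpaired_frac = 0.15) {
  stopifnot(inherits(structure, "hairpin_structure"))
  pr <- structure$pairs
  unp <- 1
  if (nrow(pr)) {
    loop_len <- max(min(pr$j) - max(pr$i) - 1, 0)
    span <- max(pr$j) - min(pr$i) + 1 - loop_len
    unp <- (span - 2 * nrow(pr)) / span
  }
  ok <- nrow(pr) >= min_stem && n_hairpin_loops(structure) == 1 &&
    unp <= max_unpaired_frac
  arms <- NULL
  if (ok) {
    arms <- list(p5 = c(min(pr$i), max(pr$i)),
                 loop = c(max(pr$i) + 1, min(pr$j) - 1),
                 p3 = c(min(pr$j), max(pr$j)))
  }
  list(is_stemloop = ok, unpaired_frac = unp, arms = arms)
}

# Trim a folded window to the maximal un-branched stem enclosing `anchor`
# (1-based interval, typically the mature read). Walks outward from the
# hairpin loop nearest the anchor through enclosing pairs until the first
# branch point, then returns the enclosed interval. NULL when the anchor's
# region holds no hairpin.
extract_hairpin <- function(structure, anchor) {
  pr <- structure$pairs
  if (nrow(pr) == 0) return(NULL)
  # hairpin-loop closing pairs: no other pair strictly inside
  inner <- purrr::map_lgl(seq_len(nrow(pr)), function(k) {
    !any(pr$i > pr$i[k] & pr$j < pr$j[k])
  })
  loops <- pr[inner, , drop = FALSE]
  # prefer the loop whose stem would contain the anchor: closing pair whose
  # chain is nearest the anchor midpoint
  mid <- mean(anchor)
  k <- which.min(abs((loops$i + loops$j) / 2 - mid))
  ci <- loops$i[k]; cj <- loops$j[k]
  repeat {
    enclosing <- pr[pr$i < ci & pr$j > cj, , drop = FALSE]
    if (nrow(enclosing) == 0) break
    nxt <- enclosing[which.max(enclosing$i), ]
    # branch check: another pair between nxt and current chain on either side
    side <- pr$i > nxt$i & pr$j < nxt$j & !(pr$i >= ci & pr$j <= cj) &
      !(pr$i <= ci & pr$j >= cj)
    if (any(side)) break
    ci <- nxt$i; cj <- nxt$j
  }
  if (!(anchor[1] >= ci && anchor[2] <= cj)) return(NULL)
  c(ci, cj)
}

# -- duplex analysis ----------------------------------------------------------

#' miRNA:miRNA* duplex statistics
#'
#' Builds one fixed alignment of the mature strand (5'->3') against the star
#' strand (3'->5') and summarises it. When a folded precursor structure is
#' supplied and both strands lie within it, the alignment is read off the
#' structure's base pairs; otherwise a global alignment (pairable = match 1,
#' mismatch 0, gap -1, ties toward fewer gaps) of the mature against the
#' reversed star is used.
#'
#' @param mature,star RNA sequences (character scalars).
#' @param structure optional `hairpin_structure` of the precursor containing
#'   both strands.
#' @return a tibble with one row: `mismatches` (opposed unpaired positions in
#'   the duplex region), `max_bulge` (longest run of unopposed bases on
#'   either strand), `gu_pairs`, `overhang_mature_3p`, `overhang_star_3p`,
#'   `paired` (number of paired columns).
#' @export
duplex_stats <- function(mature, star, structure = NULL) {
  mature <- toupper(as_rna(mature)); star <- toupper(as_rna(star))
  cols <- NULL
  if (!is.null(structure)) {
    m <- locate_in(structure$sequence, mature)
    s <- locate_in(structure$sequence, star)
    if (is.null(m) || is.null(s))
      stop_input("mature/star are not substrings of the precursor")
    # the walker runs mature 5'->3' against star 3'->5' and is agnostic to
    # which arm of the hairpin each strand sits on
    cols <- duplex_columns_structure(structure, m, s)
  }
  if (is.null(cols)) cols <- duplex_columns_align(mature, star)
  summarise_duplex(cols)
}

locate_in <- function(sequence, sub) {
  p <- regexpr(sub, sequence, fixed = TRUE)[1]
  if (p < 0) NULL else c(p, p + nchar(sub) - 1)
}

# alignment columns from a folded precursor: mature interval m on the 5' side,
# star interval s on the 3' side. Returns tibble(kind) with kinds
# pair / mismatch / bulge_m / bulge_s / overhang, in mature 5'->3' order,
# or NULL when the two strands do not oppose each other in the structure.
duplex_columns_structure <- function(structure, m, s) {
  partner <- structure$partner
  p <- m[1]; q <- s[2]
  if (!any(partner[m[1]:m[2]] >= s[1] & partner[m[1]:m[2]] <= s[2]))
    return(NULL)
  kind <- character(0)
  while (p <= m[2] && q >= s[1]) {
    pp <- partner[p]; pq <- partner[q]
    if (pp == q) {
      kind <- c(kind, "pair"); p <- p + 1; q <- q - 1
    } else if (pp == 0 && pq == 0) {
      kind <- c(kind, "mismatch"); p <- p + 1; q <- q - 1
    } else if (pq != 0 && (pq > p && pq <= m[2])) {
      kind <- c(kind, "bulge_m"); p <- p + 1      # star waits for p' = pq
    } else if (pp != 0 && (pp < q && pp >= s[1])) {
      kind <- c(kind, "bulge_s"); q <- q - 1      # mature waits for q' = pp
    } else if (pq != 0) {
      kind <- c(kind, "bulge_s"); q <- q - 1      # q pairs outside the duplex
    } else {
      kind <- c(kind, "bulge_m"); p <- p + 1      # p pairs outside the duplex
    }
  }
  if (p <= m[2]) kind <- c(kind, rep("bulge_m", m[2] - p + 1))
  if (q >= s[1]) kind <- c(kind, rep("bulge_s", q - s[1] + 1))
  mat <- chars(substring(structure$sequence, m[1], m[2]))
  str <- chars(substring(structure$sequence, s[1], s[2]))
  gu <- 0
  pi_ <- 0; qi <- 0
  for (k in kind) {
    if (k == "pair") {
      pi_ <- pi_ + 1; qi <- qi + 1
      a <- mat[pi_]; b <- rev(str)[qi]
      if ((a == "G" && b == "U") || (a == "U" && b == "G")) gu <- gu + 1
    } else if (k == "mismatch") { pi_ <- pi_ + 1; qi <- qi + 1 }
    else if (k == "bulge_m") pi_ <- pi_ + 1
    else qi <- qi + 1
  }
  tibble(kind = kind, gu = gu)
}

# global alignment of mature vs reverse(star); pairable bases score 1,
# non-pairable 0, gaps -1; among equal scores fewer gaps win.
duplex_columns_align <- function(mature, star) {
  a <- chars(mature)
  b <- rev(chars(star))          # star 3'->5'
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1); G <- matrix(0L, n + 1, m + 1)
  S[, 1] <- -(0:m)[1]            # filled below
  for (i in 1:(n + 1)) { S[i, 1] <- -(i - 1); G[i, 1] <- i - 1L }
  for (j in 1:(m + 1)) { S[1, j] <- -(j - 1); G[1, j] <- j - 1L }
  TB <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in star), 3 left
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (can_pair(a[i - 1], b[j - 1])) 1 else 0
      cand <- c(S[i - 1, j - 1] + sc, S[i - 1, j] - 1, S[i, j - 1] - 1)
      gaps <- c(G[i - 1, j - 1], G[i - 1, j] + 1L, G[i, j - 1] + 1L)
      best <- max(cand)
      pick <- which(cand == best)
      pick <- pick[which.min(gaps[pick])]
      S[i, j] <- best; G[i, j] <- gaps[pick]; TB[i, j] <- pick
    }
  }
  i <- n + 1; j <- m + 1; kind <- character(0); gu <- 0
  while (i > 1 || j > 1) {
    t <- if (i == 1) 3L else if (j == 1) 2L else TB[i, j]
    if (t == 1L) {
      if (can_pair(a[i - 1], b[j - 1])) {
        kind <- c("pair", kind)
        if ((a[i - 1] == "G" && b[j - 1] == "U") ||
            (a[i - 1] == "U" && b[j - 1] == "G")) gu <- gu + 1
      } else kind <- c("mismatch", kind)
      i <- i - 1; j <- j - 1
    } else if (t == 2L) { kind <- c("bulge_m", kind); i <- i - 1 }
    else { kind <- c("bulge_s", kind); j <- j - 1 }
  }
  tibble(kind = kind, gu = gu)
}

summarise_duplex <- function(cols) {
  kind <- cols$kind
  paired_idx <- which(kind == "pair")
  if (length(paired_idx) == 0) {
    return(tibble(mismatches = sum(kind == "mismatch"), max_bulge = 0L,
                  gu_pairs = 0L, overhang_mature_3p = 0L,
                  overhang_star_3p = 0L, paired = 0L))
  }
  lo <- min(paired_idx); hi <- max(paired_idx)
  inner <- kind[lo:hi]
  mismatches <- sum(inner == "mismatch")
  runs <- rle(inner)
  bulge_runs <- runs$lengths[runs$values %in% c("bulge_m", "bulge_s")]
  max_bulge <- if (length(bulge_runs)) max(bulge_runs) else 0L
  # mature 3' end is the tail of the column list; star 3' end is the head
  tail_k <- if (hi < length(kind)) kind[(hi + 1):length(kind)] else character(0)
  head_k <- if (lo > 1) kind[1:(lo - 1)] else character(0)
  over_m <- sum(tail_k %in% c("bulge_m", "mismatch"))
  over_s <- sum(head_k %in% c("bulge_s", "mismatch"))
  tibble(mismatches = mismatches, max_bulge = as.integer(max_bulge),
         gu_pairs = as.integer(cols$gu[1]),
         overhang_mature_3p = as.integer(over_m),
         overhang_star_3p = as.integer(over_s),
         paired = length(paired_idx))
}

#' siRNA duplex signature at a locus
#'
#' siRNAs arise as short double-stranded duplexes whose two strands each
#' carry a 2-nt 3' overhang. Given the reads mapped to one locus this tests
#' whether the most abundant plus-strand and minus-strand reads form such a
#' duplex, in which case the locus is excluded from miRNA calling.
#'
#' @param locus_reads data frame with columns `start`, `end` (genomic,
#'   1-based inclusive), `strand` ("+"/"-") and `count`.
#' @param overhang expected 3' overhang in nt (default 2).
#' @return logical scalar.
#' @export
sirna_duplex_check <- function(locus_reads, overhang = 2) {
  lr <- as_tibble(locus_reads)
  if (nrow(lr) < 2) return(FALSE)
  plus <- lr %>% filter(.data$strand == "+") %>% arrange(desc(.data$count))
  minus <- lr %>% filter(.data$strand == "-") %>% arrange(desc(.data$count))
  if (nrow(plus) == 0 || nrow(minus) == 0) return(FALSE)
  p <- plus[1, ]; m <- minus[1, ]
  # plus 3' end = p$end; minus 5' end = m$end; minus 3' end = m$start
  (p$end - m$end) == overhang && (p$start - m$start) == overhang
}
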