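# Read cleaning, collapsing, library overlap, exact genome mapping and
# category annotation of small-RNA libraries.

#' Trim adapters and filter small-RNA reads
#'
#' Removes the 3' adapter by the longest-prefix rule (the longest prefix of
#' `adapter` found as a suffix of the read is cut off), then discards reads
#' that fall outside `[min_len, max_len]` after trimming, contain `N`, or
#' carry any base with quality below `min_qual`.
#'
#' @param reads data frame with column `seq` (and optionally `qual`, a
#'   phred+33 string per read), or a character vector of sequences.
#' @param adapter 3' adapter sequence (DNA, >= 5 nt).
#' @param min_len,max_len retained insert length bounds (default 16-30 nt).
#' @param min_qual minimum per-base phred score; only enforced when `qual`
#'   is present (default 0).
#' @return tibble with columns `seq` (trimmed) and `trimmed` (nt removed).
#' @export
trim_and_filter <- function(reads, adapter, min_len = 16, max_len = 30,
                            min_qual = 0) {
  if (is.character(reads)) reads <- tibble(seq = reads)
  reads <- as_tibble(reads)
  adapter <- toupper(as_dna(adapter))
  if (nchar(adapter) < 5)
    stop_input("adapter must be at least 5 nt, got %d", nchar(adapter))
  if (nrow(reads) == 0)
    return(tibble(seq = character(0), trimmed = integer(0)))
  seqs <- toupper(as_dna(reads$seq))
  len <- nchar(seqs)
  trimmed <- integer(length(seqs))
  # longest adapter prefix matching the read suffix; check long before short
  for (k in seq(min(nchar(adapter), max(len)), 1)) {
    open <- trimmed == 0L & len >= k
    if (!any(open)) break
    hit <- open & substring(seqs, len - k + 1, len) == substring(adapter, 1, k)
    trimmed[hit] <- k
  }
  seqs <- substring(seqs, 1, len - trimmed)
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len &
    !grepl("N", seqs, fixed = TRUE)
  if (!is.null(reads[["qual"]]) && min_qual > 0) {
    minq <- vapply(substring(reads[["qual"]], 1, nchar(seqs)), function(q) {
      if (nchar(q) == 0) return(Inf)
      min(utf8ToInt(q)) - 33
    }, numeric(1), USE.NAMES = FALSE)
    keep <- keep & minq >= min_qual
  }
  tibble(seq = seqs[keep], trimmed = trimmed[keep])
}

#' Collapse identical reads into a counted library
#'
#' @param reads data frame with column `seq` (a `count` column, if present,
#'   is summed), or a character vector.
#' @param label library label, e.g. `"CL"` or `"DT"`.
#' @return a `collapsed_library`: tibble of `seq`, `count` (descending)
#'   with attributes `label`, `total_reads`, `unique_reads`.
#' @export
collapse_reads <- function(reads, label = "lib") {
  if (is.character(reads)) reads <- tibble(seq = reads)
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    out <- tibble(seq = character(0), count = integer(0))
  } else {
    if (is.null(reads[["count"]])) reads$count <- 1L
    out <- reads %>%
      group_by(.data$seq) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      arrange(desc(.data$count), .data$seq)
  }
  structure(out, label = label,
            total_reads = sum(out$count), unique_reads = nrow(out),
            class = c("collapsed_library", class(out)))
}

#' @export
print.collapsed_library <- function(x, ...) {
  cat(sprintf("<collapsed_library '%s'> %s total reads, %s unique\n",
              attr(x, "label"),
              format(attr(x, "total_reads"), big.mark = ","),
              format(attr(x, "unique_reads"), big.mark = ",")))
  NextMethod()
}

#' @describeIn collapse_reads library entries as a plain tibble.
#' @param x a `collapsed_library`.
#' @param ... unused.
#' @export
tidy.collapsed_library <- function(x, ...) {
  tibble(seq = x$seq, count = x$count, length = nchar(x$seq))
}

#' @describeIn collapse_reads one-row totals summary.
#' @export
glance.collapsed_library <- function(x, ...) {
  tibble(label = attr(x, "label"), total_reads = attr(x, "total_reads"),
         unique_reads = attr(x, "unique_reads"))
}

#' Read-length distribution of a collapsed library
#'
#' @param lib a `collapsed_library`.
#' @return tibble of `length`, `unique_reads`, `total_reads`.
#' @export
length_distribution <- function(lib) {
  tidy(lib) %>%
    group_by(length = .data$length) %>%
    summarise(unique_reads = n(), total_reads = sum(.data$count),
              .groups = "drop") %>%
    arrange(.data$length)
}

#' Shared and library-specific sequence statistics for two libraries
#'
#' Partitions the union of unique sequences into shared, A-specific and
#' B-specific sets and reports unique- and total-read counts with
#' percentages of the two-library grand totals. The shared total counts
#' reads from both libraries for every shared sequence.
#'
#' @param libA,libB `collapsed_library` objects.
#' @return tibble with rows `total`, `shared`, `<A> specific`,
#'   `<B> specific` and columns `unique_reads`, `unique_pct`,
#'   `total_reads`, `total_pct` (percentages rounded half-up to 2 dp).
#' @export
overlap_stats <- function(libA, libB) {
  a <- tidy(libA); b <- tidy(libB)
  shared <- intersect(a$seq, b$seq)
  a_only <- setdiff(a$seq, b$seq); b_only <- setdiff(b$seq, a$seq)
  cs <- sum(a$count[a$seq %in% shared]) + sum(b$count[b$seq %in% shared])
  overlap_percentages(
    shared_unique = length(shared),
    a_unique = length(a_only), b_unique = length(b_only),
    shared_total = cs,
    a_total = sum(a$count[a$seq %in% a_only]),
    b_total = sum(b$count[b$seq %in% b_only]),
    labels = c(attr(libA, "label"), attr(libB, "label")))
}

#' Overlap-table percentage arithmetic
#'
#' Lower-level builder behind [overlap_stats()]: given the category counts
#' it computes grand totals and percentages (count / grand total x 100,
#' rounded half-up to 2 dp).
#'
#' @param shared_unique,a_unique,b_unique unique-sequence counts per
#'   category.
#' @param shared_total,a_total,b_total total-read counts per category (the
#'   shared total includes reads from both libraries).
#' @param labels two library labels.
#' @return tibble as described in [overlap_stats()].
#' @export
#' @examples
#' overlap_percentages(363399, 1124459, 1579854,
#'                     12839242, 1284842, 10374842)
overlap_percentages <- function(shared_unique, a_unique, b_unique,
                                shared_total, a_total, b_total,
                                labels = c("A", "B")) {
  gu <- shared_unique + a_unique + b_unique
  gt <- shared_total + a_total + b_total
  tibble(
    type = c("total", "shared", paste(labels[1], "specific"),
             paste(labels[2], "specific")),
    unique_reads = c(gu, shared_unique, a_unique, b_unique),
    unique_pct = percent_of(c(gu, shared_unique, a_unique, b_unique), gu),
    total_reads = c(gt, shared_total, a_total, b_total),
    total_pct = percent_of(c(gt, shared_total, a_total, b_total), gt))
}

# -- exact genome mapping -----------------------------------------------------

#' Map collapsed reads to a genome by exact match
#'
#' Finds every perfect-match locus of each unique sequence on either strand
#' of the genome (minus-strand hits are exact matches of the reverse
#' complement). Coordinates are 1-based inclusive on the plus strand.
#'
#' @param lib a `collapsed_library` or data frame with a `seq` column.
#' @param genome named character vector of scaffold sequences (DNA) or a
#'   [Biostrings::DNAStringSet].
#' @return tibble of `seq`, `scaffold`, `start`, `end`, `strand`; sequences
#'   with no locus are absent (see [unmapped_reads()]).
#' @export
map_perfect <- function(lib, genome) {
  seqs <- unique(as_tibble(lib)$seq)
  gset <- as_dnastringset(genome)
  if (length(seqs) == 0)
    return(tibble(seq = character(0), scaffold = character(0),
                  start = integer(0), end = integer(0), strand = character(0)))
  widths <- nchar(seqs)
  hits <- purrr::map_dfr(sort(unique(widths)), function(w) {
    sub <- seqs[widths == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    purrr::map_dfr(c("+", "-"), function(strand) {
      subject <- if (strand == "+") gset else Biostrings::reverseComplement(gset)
      purrr::map_dfr(seq_along(subject), function(si) {
        m <- Biostrings::matchPDict(pd, subject[[si]])
        st_list <- Biostrings::startIndex(m)
        cnt <- lengths(st_list)
        if (sum(cnt) == 0) return(NULL)
        idx <- rep(seq_along(cnt), cnt)
        st <- unlist(st_list, use.names = FALSE)
        slen <- Biostrings::width(gset)[si]
        start_plus <- if (strand == "+") st else slen - (st + w - 1) + 1
        tibble(seq = sub[idx], scaffold = names(gset)[si],
               start = as.integer(start_plus),
               end = as.integer(start_plus + w - 1L), strand = strand)
      })
    })
  })
  arrange(hits, .data$seq, .data$scaffold, .data$start, .data$strand)
}

#' @describeIn map_perfect sequences of `lib` absent from the locus map.
#' @param locus_map result of `map_perfect()`.
#' @export
unmapped_reads <- function(lib, locus_map) {
  setdiff(as_tibble(lib)$seq, locus_map$seq)
}

as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  Biostrings::DNAStringSet(toupper(as_dna(genome)))
}

# -- annotation ---------------------------------------------------------------

annotation_categories <- c(
  "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA", "repeat",
  "exon_sense", "exon_antisense", "intron_sense", "intron_antisense",
  "others")

#' Annotate collapsed reads into sequence categories
#'
#' Assigns every unique sequence exactly one category using the fixed
#' precedence rRNA > tRNA > snRNA > snoRNA > miRNA > repeat > exon_sense >
#' exon_antisense > intron_sense > intron_antisense > others. ncRNA and
#' known-miRNA membership require the full read to match exactly within a
#' reference sequence; repeat/exon/intron require a perfect-match locus
#' contained in the annotated interval. Multi-locus reads take their
#' highest-precedence category and contribute their whole count once.
#'
#' @param lib a `collapsed_library`.
#' @param locus_map output of [map_perfect()] for `lib`.
#' @param ncrna_ref data frame of reference ncRNAs: columns `id`, `class`
#'   (rRNA/tRNA/snRNA/snoRNA), `seq`; or NULL.
#' @param repeat_intervals data frame `scaffold`, `start`, `end` (1-based
#'   inclusive); or NULL.
#' @param gene_models data frame of features: `scaffold`, `start`, `end`,
#'   `strand`, `type` (exon/intron/CDS), `gene`; or NULL.
#' @param known_mirnas data frame with `id`, `seq` of reference mature
#'   miRNAs; or NULL.
#' @return an `annotation_table`: tibble with one row per category plus a
#'   `Total` row; columns `category`, `unique_reads`, `unique_pct`,
#'   `total_reads`, `total_pct`. The per-sequence assignment is attached as
#'   attribute `"assignment"` (tibble `seq`, `category`).
#' @export
classify_reads <- function(lib, locus_map, ncrna_ref = NULL,
                           repeat_intervals = NULL, gene_models = NULL,
                           known_mirnas = NULL) {
  entries <- tidy(lib)
  cat <- rep("others", nrow(entries))
  names(cat) <- entries$seq

  assign_if <- function(cat, seqs, category) {
    hit <- names(cat) %in% seqs & cat == "others"
    cat[hit] <- category
    cat
  }
  # reference-sequence categories, in precedence order
  for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    refs <- if (is.null(ncrna_ref)) character(0) else
      as_dna(ncrna_ref$seq[ncrna_ref$class == cls])
    if (length(refs))
      cat <- assign_if(cat, substring_members(entries$seq, refs), cls)
  }
  if (!is.null(known_mirnas) && nrow(known_mirnas))
    cat <- assign_if(cat, substring_members(entries$seq,
                                            as_dna(known_mirnas$seq)), "miRNA")
  # interval categories from the locus map
  if (nrow(locus_map)) {
    lm <- locus_map
    if (!is.null(repeat_intervals) && nrow(repeat_intervals)) {
      inrep <- loci_within(lm, repeat_intervals)
      cat <- assign_if(cat, unique(lm$seq[inrep]), "repeat")
    }
    if (!is.null(gene_models) && nrow(gene_models)) {
      for (spec in list(c("exon", "sense"), c("exon", "antisense"),
                        c("intron", "sense"), c("intron", "antisense"))) {
        feat <- gene_models[gene_models$type == spec[1], , drop = FALSE]
        if (!nrow(feat)) next
        within <- loci_within(lm, feat, return_pairs = TRUE)
        if (!nrow(within)) next
        same <- lm$strand[within$lmi] == feat$strand[within$fti]
        want <- if (spec[2] == "sense") same else !same
        cat <- assign_if(cat, unique(lm$seq[within$lmi[want]]),
                         paste(spec, collapse = "_"))
      }
    }
  }
  assignment <- tibble(seq = entries$seq, category = unname(cat))
  tab <- assignment %>%
    left_join(entries, by = "seq") %>%
    mutate(category = factor(.data$category, levels = annotation_categories)) %>%
    group_by(.data$category, .drop = FALSE) %>%
    summarise(unique_reads = n(), total_reads = sum(.data$count),
              .groups = "drop") %>%
    mutate(category = as.character(.data$category),
           total_reads = dplyr::coalesce(.data$total_reads, 0L))
  tu <- sum(tab$unique_reads); tt <- sum(tab$total_reads)
  tab <- tab %>%
    mutate(unique_pct = percent_of(.data$unique_reads, tu),
           total_pct = percent_of(.data$total_reads, tt)) %>%
    bind_rows(tibble(category = "Total", unique_reads = tu,
                     total_reads = tt, unique_pct = 100, total_pct = 100)) %>%
    select("category", "unique_reads", "unique_pct",
           "total_reads", "total_pct")
  structure(tab, assignment = assignment, label = attr(lib, "label"),
            class = c("annotation_table", class(tab)))
}

# which of `seqs` occur as exact substrings of any sequence in `refs`
substring_members <- function(seqs, refs) {
  if (!length(seqs) || !length(refs)) return(character(0))
  subject <- Biostrings::DNAStringSet(toupper(refs))
  widths <- nchar(seqs)
  unlist(lapply(unique(widths), function(w) {
    sub <- seqs[widths == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    n <- rowSums(Biostrings::vcountPDict(pd, subject))
    sub[n > 0]
  }))
}

# loci fully contained in annotation intervals (same scaffold)
loci_within <- function(locus_map, intervals, return_pairs = FALSE) {
  q <- GenomicRanges::GRanges(locus_map$scaffold,
                              IRanges::IRanges(locus_map$start, locus_map$end))
  s <- GenomicRanges::GRanges(intervals$scaffold,
                              IRanges::IRanges(intervals$start, intervals$end))
  ov <- GenomicRanges::findOverlaps(q, s, type = "within")
  if (return_pairs)
    tibble(lmi = S4Vectors::queryHits(ov), fti = S4Vectors::subjectHits(ov))
  else unique(S4Vectors::queryHits(ov))
}
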