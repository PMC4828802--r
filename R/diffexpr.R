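# TPM normalisation and two-library differential expression of tag counts:
# Audic-Claverie exact test (primary), Fisher's exact test and Pearson
# chi-square on the 2x2 table, with the study thresholds |log2FC| >= 1,
# p <= 0.01 and the minimum-frequency-10 filter.

#' Tags-per-million normalisation
#'
#' `count / total * 1e6`. Report tables print TPM to one decimal
#' (half-up); the returned value is unrounded.
#'
#' @param count tag count(s) of a sequence.
#' @param total library total of clean reads (> 0).
#' @return numeric TPM.
#' @export
#' @examples
#' round_half_up(tpm(20970, 14124084), 1) # 1484.7
tpm <- function(count, total) {
  if (any(total <= 0)) stop_input("tpm(): library total must be positive")
  if (any(count < 0)) stop_input("tpm(): counts must be non-negative")
  count / total * 1e6
}

#' Audic-Claverie exact test for two tag-count libraries
#'
#' Conditional on observing `x` tags in a library of `N1` reads, the count
#' `y` in a second library of `N2` reads follows
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!} (1+N2/N1)^{-(x+y+1)},}
#' a negative-binomial tail model computed here in log space. The two-sided
#' p-value is `min(1, 2 * min(P(K <= y), P(K >= y)))`.
#'
#' @param x,y non-negative counts (vectorised).
#' @param N1,N2 positive library totals.
#' @return two-sided p-value(s) in (0, 1].
#' @export
#' @examples
#' audic_claverie(0, 0, 1e6, 1e6) # 1
audic_claverie <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop_input("audic_claverie(): negative counts")
  if (any(N1 <= 0) || any(N2 <= 0)) stop_input("audic_claverie(): totals must be positive")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) ac_one(x[i], y[i], N1[i], N2[i]), numeric(1))
}

# log p(k|x) for k a vector
ac_log_pk <- function(k, x, r) {
  # r = N2/N1
  lchoose(x + k, k) + k * log(r) - (x + k + 1) * log1p(r)
}

logsumexp <- function(lp) {
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

ac_one <- function(x, y, N1, N2) {
  r <- N2 / N1
  lower <- logsumexp(ac_log_pk(0:y, x, r))
  # upper tail summed outward from y until terms are negligible
  upper <- ac_upper_tail(y, x, r)
  p <- 2 * min(exp(lower), upper)
  min(1, max(p, exp(ac_log_pk(y, x, r)))) # never below the point mass
}

ac_upper_tail <- function(y, x, r) {
  acc <- -Inf
  k0 <- y
  mode <- max(y, ceiling(x * r)) # terms decay beyond the distribution mode
  repeat {
    ks <- k0:(k0 + 4095)
    lp <- ac_log_pk(ks, x, r)
    acc <- logsumexp(c(acc, lp))
    k0 <- k0 + 4096
    if (k0 > mode && lp[length(lp)] < acc - 46) break # < 1e-20 relative
  }
  exp(acc)
}

#' Fisher's exact test on the 2x2 count table
#'
#' Table `[[x, N1 - x], [y, N2 - y]]`; two-sided p-value by summing
#' hypergeometric probabilities no larger than the observed one
#' (via [stats::fisher.test()]).
#'
#' @inheritParams audic_claverie
#' @return two-sided p-value(s).
#' @export
fisher_2x2 <- function(x, y, N1, N2) {
  if (any(x > N1) || any(y > N2))
    stop_input("fisher_2x2(): count exceeds its library total")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(c(x[i], N1[i] - x[i], y[i], N2[i] - y[i]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
}

#' Pearson chi-square test on the 2x2 count table
#'
#' df = 1, no continuity correction. Degenerate tables (any expected cell
#' zero) return p = 1 with attribute `degenerate`.
#'
#' @inheritParams audic_claverie
#' @return p-value(s); attribute `degenerate` flags zero-expectation tables.
#' @export
chisq_2x2 <- function(x, y, N1, N2) {
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  N1 <- rep_len(as.numeric(N1), n); N2 <- rep_len(as.numeric(N2), n)
  tot <- N1 + N2
  p <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    o <- c(x[i], N1[i] - x[i], y[i], N2[i] - y[i])
    e <- c(N1[i] * (x[i] + y[i]), N1[i] * (tot[i] - x[i] - y[i]),
           N2[i] * (x[i] + y[i]), N2[i] * (tot[i] - x[i] - y[i])) / tot[i]
    if (any(e == 0)) { p[i] <- 1; degen[i] <- TRUE; next }
    stat <- sum((o - e)^2 / e)
    p[i] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  attr(p, "degenerate") <- degen
  p
}

#' Call differentially expressed miRNAs between two libraries
#'
#' Normalises counts to TPM, computes the log2 fold-change (second library
#' over first, zeros replaced by a 0.5-read pseudo-TPM), runs the
#' Audic-Claverie (primary), Fisher and chi-square tests, and calls each
#' record `up` (log2FC >= `lfc_min` and primary p <= `alpha`), `down`,
#' `ns`, or `filtered` (count below `min_count` in both libraries, or in
#' either when `strict_filter`). A Benjamini-Hochberg column on the primary
#' p-values is included for information; calls do not use it.
#'
#' @param records data frame with columns `mirna_id`, `count_cl`,
#'   `count_dt`.
#' @param total_cl,total_dt library totals of clean reads.
#' @param min_count minimum sequencing frequency (default 10).
#' @param lfc_min fold-change threshold on |log2FC| (default 1).
#' @param alpha significance threshold on the primary p-value (default
#'   0.01).
#' @param strict_filter require `min_count` in both libraries instead of
#'   either (default FALSE).
#' @return tibble of class `srna_de`: `mirna_id`, counts, `tpm_cl`,
#'   `tpm_dt`, `log2fc`, `p_ac`, `p_fisher`, `p_chisq`, `padj_ac`,
#'   `de_call`.
#' @export
call_de <- function(records, total_cl, total_dt, min_count = 10,
                    lfc_min = 1.0, alpha = 0.01, strict_filter = FALSE) {
  rec <- as_tibble(records)
  stopifnot(all(c("mirna_id", "count_cl", "count_dt") %in% names(rec)))
  if (nrow(rec) == 0) {
    out <- tibble(mirna_id = character(0), count_cl = integer(0),
                  count_dt = integer(0), tpm_cl = numeric(0),
                  tpm_dt = numeric(0), log2fc = numeric(0), p_ac = numeric(0),
                  p_fisher = numeric(0), p_chisq = numeric(0),
                  padj_ac = numeric(0), de_call = character(0))
    return(structure(out, total_cl = total_cl, total_dt = total_dt,
                     class = c("srna_de", class(out))))
  }
  pseudo_cl <- tpm(0.5, total_cl); pseudo_dt <- tpm(0.5, total_dt)
  out <- rec %>%
    mutate(
      tpm_cl = tpm(.data$count_cl, total_cl),
      tpm_dt = tpm(.data$count_dt, total_dt),
      log2fc = log2(ifelse(.data$tpm_dt == 0, pseudo_dt, .data$tpm_dt) /
                    ifelse(.data$tpm_cl == 0, pseudo_cl, .data$tpm_cl)),
      p_ac = audic_claverie(.data$count_cl, .data$count_dt,
                            total_cl, total_dt),
      p_fisher = fisher_2x2(.data$count_cl, .data$count_dt,
                            total_cl, total_dt),
      p_chisq = as.numeric(chisq_2x2(.data$count_cl, .data$count_dt,
                                     total_cl, total_dt)),
      padj_ac = p.adjust(.data$p_ac, method = "BH"),
      filtered = if (strict_filter)
        .data$count_cl < min_count | .data$count_dt < min_count
      else .data$count_cl < min_count & .data$count_dt < min_count,
      de_call = case_when(
        filtered ~ "filtered",
        .data$log2fc >= lfc_min & .data$p_ac <= alpha ~ "up",
        .data$log2fc <= -lfc_min & .data$p_ac <= alpha ~ "down",
        TRUE ~ "ns")) %>%
    select(-"filtered")
  structure(out, total_cl = total_cl, total_dt = total_dt,
            class = c("srna_de", class(out)))
}

#' @describeIn call_de one-row summary of a DE table (totals and call
#'   counts).
#' @param x an `srna_de` table.
#' @param ... unused.
#' @export
glance.srna_de <- function(x, ...) {
  tibble(n = nrow(x),
         n_up = sum(x$de_call == "up"), n_down = sum(x$de_call == "down"),
         n_ns = sum(x$de_call == "ns"),
         n_filtered = sum(x$de_call == "filtered"),
         total_cl = attr(x, "total_cl"), total_dt = attr(x, "total_dt"))
}

#' @describeIn call_de volcano plot of the DE table (log2FC vs -log10 of
#'   the primary p-value, coloured by call).
#' @param object an `srna_de` table.
#' @export
autoplot.srna_de <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_ac),
                 colour = .data$de_call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = "log2 fold-change (DT/CL, TPM)",
                  y = "-log10 p (Audic-Claverie)", colour = "call") +
    ggplot2::theme_minimal()
}
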