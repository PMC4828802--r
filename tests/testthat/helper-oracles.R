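# Independent oracles used by the tests. These deliberately avoid the code
# paths they verify: the folding oracle enumerates every nested structure,
# the count-test oracle uses the negative-binomial identity through
# stats::pnbinom, the mapping oracle is a naive substring scan, and the
# duplex oracle is a plain recursive alignment.

oracle_pair_energy <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
  if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(-1)
  0
}

# minimum energy over ALL nested structures by explicit enumeration
oracle_mfe <- function(seq, min_loop = 3) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(s)
  best <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    # enumerate: i unpaired, or i paired with every admissible k
    vals <- best(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      e <- oracle_pair_energy(s[i], s[k])
      if (e >= 0) next
      inner <- if (k - 1 >= i + 1) best(i + 1, k - 1) else 0
      right <- if (k + 1 <= j) best(k + 1, j) else 0
      vals <- c(vals, e + inner + right)
    }
    min(vals)
  }
  if (n < 2) return(0)
  best(1, n)
}

# two-sided Audic-Claverie p-value through the negative-binomial identity:
# p(k | x) = dnbinom(k, size = x + 1, prob = N1 / (N1 + N2))
oracle_ac <- function(x, y, N1, N2) {
  pr <- N1 / (N1 + N2)
  lower <- stats::pnbinom(y, size = x + 1, prob = pr)
  upper <- 1 - (if (y > 0) stats::pnbinom(y - 1, size = x + 1, prob = pr) else 0)
  min(1, 2 * min(lower, upper))
}

# all exact-match loci of `read` in a genome, both strands, by brute scan
oracle_scan <- function(read, genome) {
  hits <- list()
  for (sc in names(genome)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else srnapipe::revcomp(read)
      p <- gregexpr(pat, genome[[sc]], fixed = TRUE)[[1]]
      if (p[1] == -1) next
      hits[[length(hits) + 1]] <- data.frame(
        seq = read, scaffold = sc, start = as.integer(p),
        end = as.integer(p) + nchar(read) - 1L, strand = strand)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# recursive global alignment of mature vs reversed star (pairable = 1,
# mismatch 0, gap -1), returning the optimal score; memoised via an env
oracle_duplex_score <- function(mature, star) {
  a <- strsplit(toupper(chartr("T", "U", mature)), "")[[1]]
  b <- rev(strsplit(toupper(chartr("T", "U", star)), "")[[1]])
  pairable <- function(x, y) {
    (x == "G" && y == "C") || (x == "C" && y == "G") ||
      (x == "A" && y == "U") || (x == "U" && y == "A") ||
      (x == "G" && y == "U") || (x == "U" && y == "G")
  }
  memo <- new.env()
  go <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    r <- if (i > length(a) && j > length(b)) 0
    else if (i > length(a)) -(length(b) - j + 1)
    else if (j > length(b)) -(length(a) - i + 1)
    else max(go(i + 1, j + 1) + (if (pairable(a[i], b[j])) 1 else 0),
             go(i + 1, j) - 1, go(i, j + 1) - 1)
    memo[[key]] <- r
    r
  }
  go(1, 1)
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")
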