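#' Round half away from zero
#'
#' Commercial rounding used for every percentage and TPM printed by the
#' report tables, so that e.g. 0.835 becomes 0.84 rather than base R's
#' round-half-even 0.83.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.835, 52.4065), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, rounded half-up
#'
#' The percentage arithmetic used throughout the overlap and annotation
#' tables: `count / total * 100`, rounded half-up to `digits` decimals.
#'
#' @param count,total numeric vectors.
#' @param digits decimal places (default 2, as in the report tables).
#' @return numeric percentage.
#' @export
#' @examples
#' percent_of(12839242, 24498926) # 52.41
percent_of <- function(count, total, digits = 2) {
  round_half_up(100 * count / total, digits)
}

# -- sequence helpers ---------------------------------------------------------

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return `as_dna()` transliterates U->T; `as_rna()` T->U.
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' Reverse complement of DNA/RNA sequences
#'
#' @param x character vector (DNA or RNA; output alphabet follows input:
#'   sequences containing U return RNA).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  is_rna <- grepl("U", x, fixed = TRUE)
  d <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as_dna(x))))
  d[is_rna] <- as_rna(d[is_rna])
  unname(d)
}

# TRUE when two RNA bases can pair (Watson-Crick or G:U wobble)
can_pair <- function(a, b) {
  (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# draw counts around means: negative binomial with dispersion phi
# (var = mu + phi * mu^2); phi == 0 degenerates to the rounded mean.
draw_counts <- function(mu, dispersion) {
  if (dispersion <= 0) return(as.integer(round(mu)))
  as.integer(rnbinom(length(mu), mu = mu, size = 1 / dispersion))
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "srnapipe_input_error")
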