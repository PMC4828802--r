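# Figure helpers for the report bundle.

#' Read-length distribution plot
#'
#' Bar chart of unique (or total) read counts by insert length for one or
#' more libraries, the usual first look at a small-RNA library (plant
#' libraries peak at 24 nt, with a secondary miRNA mode near 21 nt).
#'
#' @param ... named `collapsed_library` objects, or a single data frame
#'   with columns `library`, `length`, and the chosen `weight` column.
#' @param weight `"unique_reads"` or `"total_reads"`.
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(..., weight = c("unique_reads",
                                                     "total_reads")) {
  weight <- match.arg(weight)
  libs <- list(...)
  df <- if (length(libs) == 1 && is.data.frame(libs[[1]]) &&
            "library" %in% names(libs[[1]])) {
    as_tibble(libs[[1]])
  } else {
    nm <- names(libs) %||% paste0("lib", seq_along(libs))
    purrr::map2_dfr(libs, nm, function(l, n)
      mutate(length_distribution(l), library = n))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$length),
                                   y = .data[[weight]],
                                   fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read length (nt)", y = gsub("_", " ", weight),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Hairpin structure plot
#'
#' Arc diagram of a folded precursor: bases along the x axis, one arc per
#' base pair; a well-formed pre-miRNA shows a single nested arc stack.
#'
#' @param structure a `hairpin_structure` from [fold_mfe()].
#' @return a ggplot object.
#' @export
plot_hairpin <- function(structure) {
  pr <- structure$pairs
  arcs <- purrr::map_dfr(seq_len(nrow(pr)), function(k) {
    t <- seq(0, pi, length.out = 40)
    r <- (pr$j[k] - pr$i[k]) / 2
    tibble(pair = k, x = (pr$i[k] + pr$j[k]) / 2 + r * cos(t),
           y = r * sin(t))
  })
  ggplot2::ggplot(arcs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$pair)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::labs(x = "position (nt)", y = NULL,
                  title = sprintf("MFE %.1f kcal/mol, %d pairs",
                                  structure$mfe, structure$npairs)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
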