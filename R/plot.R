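#' Plot match records as segments along the panel
#'
#' Each match is drawn as a horizontal segment over its site interval, one
#' row per haplotype pair, colored by length. Useful for eyeballing where
#' long shared (IBD-candidate) segments concentrate.
#'
#' @param object A tibble of match records (`mpbwt_matches`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpbwt_matches <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste0(df$hap_i, "-", df$hap_j)
  df$pair <- factor(df$pair, levels = unique(df$pair[order(df$start, df$end)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$pair, yend = .data$pair,
                                   color = .data$length)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::labs(x = "site (0-based)", y = "haplotype pair",
                  color = "length (sites)") +
    ggplot2::theme_minimal()
}

#' Plot a haplotype panel as an allele-code heat map
#'
#' Rows are haplotypes, columns sites, fill the allele code. With
#' `sorted = TRUE` rows at each site follow the reversed-prefix order of the
#' transform (`y` columns), which makes the run-length structure the
#' compressor exploits visible.
#'
#' @param object A [haplotype_panel].
#' @param sorted Show the reversed-prefix-sorted columns instead of raw rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplotype_panel <- function(object, sorted = FALSE, ...) {
  X <- if (sorted) pbwt_transform(object)$y else object$alleles
  df <- tibble::tibble(
    haplotype = rep(seq_len(nrow(X)) - 1L, times = ncol(X)),
    site = rep(seq_len(ncol(X)) - 1L, each = nrow(X)),
    allele = factor(as.vector(X))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$haplotype,
                                   fill = .data$allele)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "site (0-based)",
                  y = if (sorted) "sorted position" else "haplotype",
                  fill = "allele") +
    ggplot2::theme_minimal()
}
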