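## fractionation: post-polyploidy gene loss statistics -- per-chromosome
## loss rates, deletion run-length spectra, and geometric fitting with a
## lack-of-fit F-test.

#' Per-chromosome gene loss rates from a homology table
#'
#' For every reference chromosome and every non-reference column, the loss
#' fraction is the share of rows holding the missing marker.  For sibling
#' column groups of a multiplicity-2 species the row-wise
#' "both siblings missing" fraction is reported as well.
#'
#' @param table A `wgd_homtable`.
#' @return List: `per_column` (data.frame `chrom`, `column`, `rows`,
#'   `filled`, `loss`) and `both_missing` (data.frame `chrom`, `species`,
#'   `group`, `loss_both`).
#' @export
loss_rates <- function(table) {
  tab <- table$table
  spec <- table$spec
  chroms <- split(seq_len(nrow(tab)), table$ref_genes$chrom)
  target_cols <- setdiff(colnames(tab), spec$reference)
  per_col <- list()
  both <- list()
  for (chrom in names(chroms)) {
    rows <- chroms[[chrom]]
    if (!length(rows)) { warning("chromosome ", chrom, " has zero rows"); next }
    for (col in target_cols) {
      filled <- sum(tab[rows, col] != ".")
      per_col[[length(per_col) + 1L]] <- data.frame(
        chrom = chrom, column = col, rows = length(rows),
        filled = filled, loss = 1 - filled / length(rows),
        stringsAsFactors = FALSE)
    }
    for (s in spec$species) {
      m <- spec$multiplicity[[s]]
      if (m < 2) next
      for (px in 0:spec$n_ref_paralogs) {
        cols <- ortho_col_names(s, m, px)
        miss <- rowSums(tab[rows, cols, drop = FALSE] != ".") == 0
        both[[length(both) + 1L]] <- data.frame(
          chrom = chrom, species = s,
          group = if (px == 0) "o" else paste0("p", px),
          loss_both = mean(miss), stringsAsFactors = FALSE)
      }
    }
  }
  list(per_column = do.call(rbind, per_col),
       both_missing = if (length(both)) do.call(rbind, both) else NULL)
}

#' Run-length spectrum of consecutive missing genes in one table column
#'
#' Maximal runs of the missing marker along reference gene order are counted
#' by length within each reference chromosome (runs never span chromosome
#' boundaries).  Runs longer than `l_max` -- typically lost chromosome
#' fragments rather than gene-by-gene fractionation -- are tallied apart and
#' excluded from the spectrum.
#'
#' @param table A `wgd_homtable`, or a character vector of cell values.
#' @param column Column name (when `table` is a `wgd_homtable`).
#' @param chrom Optional chromosome vector parallel to a raw cell vector.
#' @param l_max Longest run length kept in the spectrum (default 15).
#' @return Object of class `run_spectrum`: `counts` (named vector, lengths
#'   1..`l_max`), `l_max`, `excluded_long_runs`, `excluded_dots`,
#'   `total_dots`.
#' @export
run_lengths <- function(table, column = NULL, chrom = NULL, l_max = 15) {
  if (inherits(table, "wgd_homtable")) {
    values <- table$table[, column]
    chrom <- table$ref_genes$chrom
  } else {
    values <- table
    if (is.null(chrom)) chrom <- rep("chr0", length(values))
  }
  counts <- setNames(integer(l_max), seq_len(l_max))
  excluded <- 0L
  excluded_dots <- 0L
  for (v in split(values == ".", chrom)) {
    r <- rle(v)
    runs <- r$lengths[r$values]
    short <- runs[runs <= l_max]
    if (length(short)) {
      t_ <- table(factor(short, levels = seq_len(l_max)))
      counts <- counts + as.integer(t_)
    }
    excluded <- excluded + sum(runs > l_max)
    excluded_dots <- excluded_dots + sum(runs[runs > l_max])
  }
  structure(list(counts = counts, l_max = l_max,
                 excluded_long_runs = excluded,
                 excluded_dots = excluded_dots,
                 total_dots = sum(seq_len(l_max) * counts) + excluded_dots),
            class = "run_spectrum")
}

#' @export
print.run_spectrum <- function(x, ...) {
  cat("<run_spectrum>", sum(x$counts), "runs <=", x$l_max, "|",
      x$excluded_long_runs, "longer runs excluded\n")
  invisible(x)
}

#' Fit a geometric distribution to a deletion run-length spectrum
#'
#' Observed run counts are fit by least squares to `N * p * (1-p)^(l-1)`
#' over `l = 1..l_max`, where `N` is the total number of runs (including
#' those beyond `l_max`, so the truncated tail is modelled rather than
#' renormalised away) and the extension parameter `p` is free: larger `p`
#' means shorter deletion runs (mean run length `1/p`).  Fit quality is the
#' coefficient of determination.  A lack-of-fit F statistic compares the
#' residual mean square against the multinomial sampling variance expected
#' under the fitted model, `mean(N q_l (1 - q_l))`; its upper tail
#' probability on `(l_max - 1, Inf)` degrees of freedom is the reported
#' p-value -- a LARGE p-value accepts the geometric model.  A chi-square
#' goodness-of-fit (with a pooled `> l_max` tail class) is emitted alongside
#' as a cross-check.
#'
#' @param spectrum A [run_lengths()] spectrum, or a bare vector of run
#'   lengths.
#' @param l_max Cap when `spectrum` is a bare vector of run lengths.
#' @return Object of class `geom_fit`: `p`, `r2`, `f_stat`, `p_value`,
#'   `chi2`, `chi2_df`, `chi2_p`, `n_runs`, `fitted`.
#' @export
fit_geometric <- function(spectrum, l_max = 15) {
  if (!inherits(spectrum, "run_spectrum")) {
    lens <- spectrum
    spectrum <- structure(list(
      counts = setNames(as.integer(table(factor(pmin(lens, l_max + 1L),
                                                levels = seq_len(l_max)))),
                        seq_len(l_max)),
      l_max = l_max,
      excluded_long_runs = sum(lens > l_max),
      excluded_dots = sum(lens[lens > l_max]),
      total_dots = sum(lens)), class = "run_spectrum")
  }
  counts <- spectrum$counts
  l_max <- spectrum$l_max
  N <- sum(counts) + spectrum$excluded_long_runs
  l <- seq_len(l_max)
  nz <- sum(counts > 0)
  if (nz <= 1) {
    ## degenerate: a single observed run length
    return(structure(list(p = 1, r2 = 1, f_stat = 0, p_value = 1,
                          chi2 = 0, chi2_df = 0, chi2_p = 1, n_runs = N,
                          fitted = counts), class = "geom_fit"))
  }
  sse_fun <- function(p) sum((counts - N * p * (1 - p)^(l - 1))^2)
  opt <- optimize(sse_fun, c(1e-6, 1))
  p <- opt$minimum
  fitted <- N * p * (1 - p)^(l - 1)
  sse <- opt$objective
  sst <- sum((counts - mean(counts))^2)
  r2 <- 1 - sse / sst
  q <- p * (1 - p)^(l - 1)
  samp_var <- mean(N * q * (1 - q))
  df1 <- l_max - 1
  f_stat <- (sse / df1) / samp_var
  p_value <- pf(f_stat, df1, Inf, lower.tail = FALSE)
  ## chi-square cross-check with pooled tail class
  e <- c(fitted, N * (1 - p)^l_max)
  o <- c(counts, spectrum$excluded_long_runs)
  keep <- e >= 1
  chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
  chi2_df <- max(sum(keep) - 2, 1)
  structure(list(p = p, r2 = r2, f_stat = f_stat, p_value = p_value,
                 chi2 = chi2, chi2_df = chi2_df,
                 chi2_p = pchisq(chi2, chi2_df, lower.tail = FALSE),
                 n_runs = N, fitted = fitted),
            class = "geom_fit")
}

#' @export
print.geom_fit <- function(x, ...) {
  cat(sprintf(
    "<geom_fit> p = %.4f (mean run %.2f)  R2 = %.4f  F = %.3f (P = %.4f)\n",
    x$p, 1 / x$p, x$r2, x$f_stat, x$p_value))
  invisible(x)
}
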