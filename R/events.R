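## event_classify: Ks-window labelling of blocks, ortholog depth profiling
## and polyploidy multiplicity inference.

#' Define event Ks windows
#'
#' @param event Character vector of event names (e.g. `"AST"`, `"ECH"`,
#'   `"speciation:V-A"`).
#' @param low,high Window bounds on the Ks axis; windows must not overlap.
#' @return data.frame of class `ks_windows`.
#' @export
ks_windows <- function(event, low, high) {
  w <- data.frame(event = as.character(event), low = low, high = high,
                  stringsAsFactors = FALSE)
  stopifnot(all(w$low < w$high))
  w <- w[order(w$low), , drop = FALSE]
  if (nrow(w) > 1 && any(w$low[-1] < w$high[-nrow(w)])) {
    stop("event Ks windows overlap")
  }
  class(w) <- c("ks_windows", "data.frame")
  w
}

#' Label blocks by the event window containing their median Ks
#'
#' Each block is labelled by the unique window containing its `median_ks`;
#' blocks whose median falls between windows, and flagged blocks (mostly
#' saturated/failed pairs), stay `"unassigned"`.
#'
#' @param blocks An annotated `wgd_blocks` object.
#' @param windows A [ks_windows()] data.frame.
#' @return The `wgd_blocks` object with `blocks$event` filled.
#' @export
partition_blocks <- function(blocks, windows) {
  windows <- ks_windows(windows$event, windows$low, windows$high)
  b <- blocks$blocks
  b$event <- "unassigned"
  for (i in seq_len(nrow(windows))) {
    hit <- !b$flagged & !is.na(b$median_ks) &
      b$median_ks >= windows$low[i] & b$median_ks <= windows$high[i]
    b$event[hit] <- windows$event[i]
  }
  blocks$blocks <- b
  blocks
}

#' Suggest event Ks windows from block medians (1-D Gaussian mixture)
#'
#' Fits a 1-D Gaussian mixture (unequal variances, \pkg{mclust}) to the
#' block median-Ks values and returns one window per component: mean +/- 2
#' standard deviations, truncated where adjacent component densities cross.
#' With `n_components = NULL` the number of components (1..`max_components`)
#' is chosen by BIC.  Components whose means are closer than 0.1 Ks units
#' collapse into a single window, with a warning.
#'
#' @param values Numeric vector of block median Ks values (>= 10).
#' @param n_components Number of mixture components, or `NULL` for BIC.
#' @param max_components Upper bound for BIC selection (default 3).
#' @return A [ks_windows()] data.frame with events named `peak_1`,
#'   `peak_2`, ... in increasing Ks order, and attributes `means`, `sds`,
#'   `proportions`.
#' @export
suggest_windows <- function(values, n_components = NULL, max_components = 3) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need >= 10 median Ks values")
  if (length(unique(values)) == 1) {
    w <- ks_windows("peak_1", values[1] - 0.05, values[1] + 0.05)
    attr(w, "means") <- values[1]; attr(w, "sds") <- 0
    return(w)
  }
  G <- n_components %||% seq_len(max_components)
  fit <- mclust::Mclust(values, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) fit <- mclust::Mclust(values, G = 1, modelNames = "V",
                                          verbose = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  pro <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]; pro <- pro[o]
  if (length(mu) > 1 && any(diff(mu) < 0.1)) {
    warning("mixture components collapse (means < 0.1 apart); ",
            "returning a single window")
    mu <- mean(values); sig <- sd(values); pro <- 1
  }
  low <- mu - 2 * sig
  high <- mu + 2 * sig
  if (length(mu) > 1) {
    for (i in seq_len(length(mu) - 1)) {
      cut <- component_crossing(mu[i], sig[i], pro[i],
                                mu[i + 1], sig[i + 1], pro[i + 1])
      high[i] <- min(high[i], cut)
      low[i + 1] <- max(low[i + 1], cut)
    }
  }
  low <- pmax(low, 0)
  bad <- low >= high
  if (any(bad)) { # extremely narrow component squeezed out by truncation
    low[bad] <- mu[bad] - 1e-6
    high[bad] <- mu[bad] + 1e-6
  }
  w <- ks_windows(paste0("peak_", seq_along(mu)), low, high)
  attr(w, "means") <- mu; attr(w, "sds") <- sig; attr(w, "proportions") <- pro
  w
}

## Ks value where two weighted Gaussian densities cross, searched between
## the two means; falls back to the midpoint if they do not cross there.
component_crossing <- function(m1, s1, p1, m2, s2, p2) {
  f <- function(x) p1 * dnorm(x, m1, s1) - p2 * dnorm(x, m2, s2)
  if (f(m1) > 0 && f(m2) < 0) {
    tryCatch(uniroot(f, c(m1, m2))$root, error = function(e) (m1 + m2) / 2)
  } else {
    (m1 + m2) / 2
  }
}

#' Ortholog depth along a reference genome
#'
#' Tiles each reference chromosome into windows of `window_genes` gene ranks
#' and counts, per window, the number of distinct block footprints (one
#' block's reference-side rank interval) overlapping it among blocks
#' labelled with `event`.
#'
#' @param reference A `wgd_genome`.
#' @param blocks A labelled `wgd_blocks` object from a comparison involving
#'   the reference genome.
#' @param event Label selecting the orthologous blocks (default: every label
#'   starting with `"speciation"`, plus `"orth"`); `NULL` uses all blocks.
#' @param window_genes Window width in gene ranks (default 100).
#' @return data.frame of class `depth_profile`: `chrom`, `win_start`,
#'   `win_end` (0-based rank interval, end exclusive), `depth`.
#' @export
depth_profile <- function(reference, blocks, event = NULL,
                          window_genes = 100) {
  b <- blocks$blocks
  if (!is.null(event)) {
    b <- b[b$event %in% event, , drop = FALSE]
  } else {
    sel <- grepl("^speciation|^orth", b$event)
    if (any(sel)) b <- b[sel, , drop = FALSE]
  }
  ## orient footprints onto the reference side
  if (identical(blocks$genome_a, reference$species)) {
    fp <- data.frame(chrom = b$chrom_a, lo = b$start_a, hi = b$end_a)
  } else if (identical(blocks$genome_b, reference$species)) {
    fp <- data.frame(chrom = b$chrom_b, lo = b$start_b, hi = b$end_b)
  } else {
    stop("blocks do not involve the reference genome")
  }
  out <- list()
  for (ci in seq_len(nrow(reference$chromosomes))) {
    chrom <- reference$chromosomes$chrom[ci]
    n <- reference$chromosomes$n_genes[ci]
    starts <- seq(0L, n - 1L, by = window_genes)
    ends <- pmin(starts + window_genes, n)
    f <- fp[fp$chrom == chrom, , drop = FALSE]
    depth <- vapply(seq_along(starts), function(w) {
      sum(f$lo < ends[w] & f$hi >= starts[w])
    }, numeric(1))
    out[[ci]] <- data.frame(chrom = chrom, win_start = starts,
                            win_end = ends, depth = as.integer(depth),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("depth_profile", "data.frame")
  res
}

#' Infer polyploidy multiplicity from an ortholog depth profile
#'
#' The multiplicity is the modal depth among windows with nonzero depth; the
#' supporting fraction is the share of nonzero windows at the mode.  Against
#' an unduplicated reference, a mode of 2 indicates one extra genome
#' doubling (tetraploidization) after the shared event; 3 indicates a
#' tripling (hexaploidization); 1 indicates no extra polyploidy.
#'
#' @param profile A [depth_profile()] data.frame (>= 10 nonzero windows).
#' @return List of class `ploidy_call`: `multiplicity`, `support`,
#'   `interpretation`, `n_windows`, `depth_table`.
#' @export
infer_ploidy <- function(profile) {
  nz <- profile$depth[profile$depth > 0]
  if (!length(nz)) stop("no windows with nonzero ortholog depth")
  if (length(nz) < 10) stop("need >= 10 windows with nonzero depth")
  tab <- table(nz)
  mult <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  interp <- switch(as.character(mult),
                   "1" = "no extra polyploidy",
                   "2" = "tetraploidization after the shared event",
                   "3" = "hexaploidization after the shared event",
                   paste0("depth ", mult, ": multiple nested duplications"))
  structure(list(multiplicity = mult,
                 support = unname(tab[as.character(mult)] / sum(tab)),
                 interpretation = interp,
                 n_windows = length(nz),
                 depth_table = tab),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call> multiplicity %d (%s), support %.2f over %d windows\n",
              x$multiplicity, x$interpretation, x$support, x$n_windows))
  invisible(x)
}
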