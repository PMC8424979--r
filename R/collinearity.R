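## collinearity: detection of collinear (syntenic) blocks by chaining
## homologous gene pairs in chromosome rank coordinates.

new_blocks <- function(blocks, pairs, genome_a, genome_b) {
  structure(list(blocks = blocks, pairs = pairs,
                 genome_a = genome_a, genome_b = genome_b),
            class = "wgd_blocks")
}

#' @export
print.wgd_blocks <- function(x, ...) {
  cat("<wgd_blocks>", x$genome_a, "vs", x$genome_b, "|",
      nrow(x$blocks), "blocks,", nrow(x$pairs), "pairs\n")
  invisible(x)
}

empty_blocks_df <- function() {
  data.frame(block_id = integer(0), genome_a = character(0),
             genome_b = character(0), chrom_a = character(0),
             chrom_b = character(0), n_pairs = integer(0),
             orientation = character(0), start_a = integer(0),
             end_a = integer(0), start_b = integer(0), end_b = integer(0),
             median_ks = numeric(0), flagged = logical(0),
             event = character(0), stringsAsFactors = FALSE)
}

empty_pairs_df <- function() {
  data.frame(block_id = integer(0), gene_a = character(0),
             gene_b = character(0), rank_a = integer(0), rank_b = integer(0),
             ks = numeric(0), ka = numeric(0), status = character(0),
             stringsAsFactors = FALSE)
}

## Best chain by dynamic programming over hits on one chromosome pair.
## Monotone strictly increasing in rank_a; rank_b strictly increasing
## (dir = +1) or strictly decreasing (dir = -1); the rank gap between
## consecutive chain members is <= max_gap on both axes.  Score = number of
## pairs; ties broken by smaller total gap, then by lexicographic first
## gene id (determinism).
best_chain <- function(ra, rb, ga, dir, max_gap) {
  n <- length(ra)
  o <- order(ra, dir * rb)
  ra <- ra[o]; rb <- rb[o]; ga <- ga[o]
  len <- rep(1L, n); gap <- rep(0, n); pred <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- dir * (rb[i] - rb[j])
      if (da < 1L || db < 1L) next
      if (da > max_gap + 1L || db > max_gap + 1L) next
      cl <- len[j] + 1L
      cg <- gap[j] + (da - 1L) + (db - 1L)
      if (cl > len[i] || (cl == len[i] && cg < gap[i])) {
        len[i] <- cl; gap[i] <- cg; pred[i] <- j
      }
    }
  }
  best <- which(len == max(len))
  if (length(best) > 1L) best <- best[order(gap[best])]
  ## among equal (length, gap) champions prefer the chain whose first gene
  ## id is lexicographically smallest
  first_gene <- vapply(best, function(i) {
    while (pred[i] > 0L) i <- pred[i]
    ga[i]
  }, character(1))
  b <- best[order(gap[best], first_gene)][1L]
  chain <- integer(0)
  while (b > 0L) { chain <- c(b, chain); b <- pred[b] }
  o[chain]
}

#' Detect collinear blocks between (or within) two genomes
#'
#' Homologous gene pairs are chained along chromosome rank coordinates: a
#' block is a maximal set of pairs strictly monotone on both axes whose
#' consecutive members are at most `max_gap` intervening genes apart on each
#' axis.  Chains are extracted greedily (largest pair count first, both
#' orientations considered), each hit joining at most one block.  For a
#' self-comparison, trivial self-pairs are dropped and each paralogous block
#' is reported once (canonical orientation: `chrom_a < chrom_b`, or
#' `rank_a < rank_b` on the same chromosome).
#'
#' @param hits Hit data.frame (`query`, `subject`, ...), queries from
#'   `genome_a` and subjects from `genome_b`.
#' @param genome_a,genome_b `wgd_genome` objects (pass the same object twice
#'   for a within-genome scan).
#' @param max_gap Maximum number of intervening genes between consecutive
#'   block members on each axis (default 50).
#' @param min_pairs Minimum pairs per reported block (default 4).
#' @return A `wgd_blocks` object.
#' @export
detect_blocks <- function(hits, genome_a, genome_b, max_gap = 50,
                          min_pairs = 4) {
  self <- identical(genome_a$species, genome_b$species)
  ia <- match(hits$query, genome_a$genes$id)
  ib <- match(hits$subject, genome_b$genes$id)
  if (!self && (anyNA(ia) || anyNA(ib))) {
    ## tolerate tables carrying both search directions: reorient rows whose
    ## query lives in genome_b
    ia2 <- match(hits$query, genome_b$genes$id)
    ib2 <- match(hits$subject, genome_a$genes$id)
    flip <- is.na(ia) & !is.na(ia2) & !is.na(ib2)
    if (any(flip)) {
      tmp <- hits$query[flip]
      hits$query[flip] <- hits$subject[flip]
      hits$subject[flip] <- tmp
      ia[flip] <- ib2[flip]
      ib[flip] <- ia2[flip]
    }
    dup <- duplicated(hits[, c("query", "subject")])
    if (any(dup)) {
      hits <- hits[!dup, , drop = FALSE]
      ia <- ia[!dup]; ib <- ib[!dup]
    }
  }
  if (anyNA(ia) || anyNA(ib)) stop("hit references a gene absent from genome")
  h <- data.frame(gene_a = hits$query, gene_b = hits$subject,
                  chrom_a = genome_a$genes$chrom[ia],
                  rank_a = genome_a$genes$rank[ia],
                  chrom_b = genome_b$genes$chrom[ib],
                  rank_b = genome_b$genes$rank[ib],
                  stringsAsFactors = FALSE)
  if (self) {
    h <- h[h$gene_a != h$gene_b, , drop = FALSE]
    swap <- h$chrom_a > h$chrom_b |
      (h$chrom_a == h$chrom_b & h$rank_a > h$rank_b)
    h[swap, c("gene_a", "gene_b", "chrom_a", "rank_a", "chrom_b", "rank_b")] <-
      h[swap, c("gene_b", "gene_a", "chrom_b", "rank_b", "chrom_a", "rank_a")]
    h <- h[!duplicated(h[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  blocks <- list(); pairs <- list(); bid <- 0L
  if (nrow(h)) {
    h <- h[order(h$chrom_a, h$chrom_b, h$rank_a, h$rank_b), , drop = FALSE]
    groups <- split(h, list(h$chrom_a, h$chrom_b), drop = TRUE)
    groups <- groups[order(names(groups))]
    for (g in groups) {
      repeat {
        if (nrow(g) < min_pairs) break
        fwd <- best_chain(g$rank_a, g$rank_b, g$gene_a, +1L, max_gap)
        rev_ <- best_chain(g$rank_a, g$rank_b, g$gene_a, -1L, max_gap)
        use_fwd <- length(fwd) >= length(rev_)
        chain <- if (use_fwd) fwd else rev_
        if (length(chain) < min_pairs) break
        bid <- bid + 1L
        cp <- g[chain, , drop = FALSE]
        blocks[[bid]] <- data.frame(
          block_id = bid, genome_a = genome_a$species,
          genome_b = genome_b$species, chrom_a = cp$chrom_a[1],
          chrom_b = cp$chrom_b[1], n_pairs = nrow(cp),
          orientation = if (use_fwd) "+" else "-",
          start_a = min(cp$rank_a), end_a = max(cp$rank_a),
          start_b = min(cp$rank_b), end_b = max(cp$rank_b),
          median_ks = NA_real_, flagged = FALSE, event = NA_character_,
          stringsAsFactors = FALSE)
        pairs[[bid]] <- data.frame(
          block_id = bid, gene_a = cp$gene_a, gene_b = cp$gene_b,
          rank_a = cp$rank_a, rank_b = cp$rank_b, ks = NA_real_,
          ka = NA_real_, status = NA_character_, stringsAsFactors = FALSE)
        g <- g[-chain, , drop = FALSE]
      }
    }
  }
  new_blocks(
    if (length(blocks)) do.call(rbind, blocks) else empty_blocks_df(),
    if (length(pairs)) do.call(rbind, pairs) else empty_pairs_df(),
    genome_a$species, genome_b$species)
}

#' Tally blocks at increasing minimum-length thresholds
#'
#' @param blocks A `wgd_blocks` object (or its `blocks` data.frame).
#' @param thresholds Minimum pairs per block for each summary row.
#' @return data.frame with `threshold`, `n_blocks`, `n_pairs` and
#'   `mean_pairs_per_block` (2 decimals; `NA` when no block qualifies).
#' @export
summarize_blocks <- function(blocks, thresholds = c(4, 10, 20, 50)) {
  b <- if (inherits(blocks, "wgd_blocks")) blocks$blocks else blocks
  out <- lapply(thresholds, function(th) {
    sel <- b$n_pairs >= th
    n <- sum(sel)
    np <- sum(b$n_pairs[sel])
    data.frame(threshold = th, n_blocks = n, n_pairs = np,
               mean_pairs_per_block = if (n > 0) round(np / n, 2) else
                 NA_real_)
  })
  do.call(rbind, out)
}

#' Write blocks (header line per block, then its pair rows)
#'
#' @param blocks A `wgd_blocks` object.
#' @param path Output path.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("## block_id genome_a genome_b chrom_a chrom_b n_pairs",
                   "orientation median_ks event"), con)
  for (i in seq_len(nrow(blocks$blocks))) {
    bl <- blocks$blocks[i, ]
    writeLines(paste0("# ", paste(bl$block_id, bl$genome_a, bl$genome_b,
                                  bl$chrom_a, bl$chrom_b, bl$n_pairs,
                                  bl$orientation, bl$median_ks, bl$event,
                                  sep = "\t")), con)
    pp <- blocks$pairs[blocks$pairs$block_id == bl$block_id, ]
    write.table(pp[, c("block_id", "gene_a", "gene_b", "rank_a", "rank_b",
                       "ks", "ka", "status")],
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
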