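## Independent oracles and shared fixtures for the test suite.

## ---- exhaustive chain enumeration (oracle for detect_blocks) -------------
## Depth-first enumeration of every chain of hits satisfying strict
## monotonicity on both axes (rank_b increasing for dir = +1, decreasing for
## dir = -1) and the per-axis gap bound.  Returns the maximum chain length.
## Deliberately brute force and structurally unlike the package's DP.
brute_max_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  for (dir in c(1L, -1L)) {
    extend <- function(last, size) {
      best <<- max(best, size)
      for (i in seq_len(n)) {
        if (last > 0L) {
          da <- ra[i] - ra[last]
          db <- dir * (rb[i] - rb[last])
          if (da < 1L || db < 1L) next
          if (da > max_gap + 1L || db > max_gap + 1L) next
        }
        extend(i, size + 1L)
      }
    }
    extend(0L, 0L)
  }
  best
}

## ---- recursive NG86 pathway oracle ---------------------------------------
## Counts synonymous/nonsynonymous differences between two sense codons by
## recursively walking every minimal mutational pathway, skipping pathways
## that enter a stop codon (falling back to all pathways when every one is
## blocked).  Independent of the package's permutation-matrix machinery.
oracle_path_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  walk <- function(cur, target, allow_stop) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(diffs)) return(list(c(sd = 0, nd = 0)))
    res <- list()
    for (p in diffs) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (gc[[nxt]] == "*" && nxt != target && !allow_stop) next
      syn <- gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]]
      step <- if (syn) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (tail in walk(nxt, target, allow_stop)) {
        res[[length(res) + 1L]] <- step + tail
      }
    }
    res
  }
  paths <- walk(c1, c2, allow_stop = FALSE)
  if (!length(paths)) paths <- walk(c1, c2, allow_stop = TRUE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

## ---- tiny genome / block builders ----------------------------------------
## A genome whose chromosome layout is given as a named list of gene-id
## vectors (genes get consecutive coordinates).
toy_genome <- function(chrom_genes, tag, cds = NULL) {
  df <- do.call(rbind, lapply(names(chrom_genes), function(ch) {
    ids <- chrom_genes[[ch]]
    data.frame(id = ids, chrom = ch,
               start = seq_along(ids) * 1000L,
               end = seq_along(ids) * 1000L + 500L,
               stringsAsFactors = FALSE)
  }))
  new_genome(df, tag, cds = cds)
}

## Perfect-diagonal hits between two id vectors (optionally skipping some).
diag_hits <- function(a, b, skip = integer(0)) {
  keep <- setdiff(seq_along(a), skip)
  data.frame(query = a[keep], subject = b[keep], evalue = 1e-20,
             bitscore = 200, stringsAsFactors = FALSE)
}

random_cds <- function(n_codons) {
  wgdkit:::codon_idx_to_cds(wgdkit:::random_ancestral_cds(n_codons))
}

## ---- cached simulation fixtures ------------------------------------------
## One small bundle shared across test files (testthat keeps one session).
sim_small <- function() {
  cache <- getOption("wgdkit.test.cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(wgdkit.test.cache = cache)
  }
  if (is.null(cache$small)) {
    cache$small <- simulate_history(sim_config(
      seed = 101, ancestral_genes = 500, ancestral_chromosomes = 2,
      codons_per_gene = 150))
  }
  cache$small
}

sim_default_pipeline <- function() {
  cache <- getOption("wgdkit.test.cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(wgdkit.test.cache = cache)
  }
  if (is.null(cache$default_run)) {
    cache$default_run <- run_pipeline(list(seed = 11))
  }
  cache$default_run
}
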