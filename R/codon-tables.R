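## Genetic-code lookup tables underpinning the Nei-Gojobori (NG86) estimator.
## Everything here is precomputed once per session and cached: per-codon
## synonymous site fractions, single-step codon neighbourhoods, and the full
## 64x64 pathway-averaged synonymous/nonsynonymous difference matrices.

.wgd_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

codon_table <- function() {
  if (!is.null(.wgd_cache$codons)) return(.wgd_cache$codons)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  tab <- list(
    codon = codons,
    aa = unname(gc),
    is_stop = unname(gc == "*"),
    index = setNames(seq_along(codons), codons)
  )
  .wgd_cache$codons <- tab
  tab
}

## All 9 single-nucleotide mutational neighbours of a codon.
codon_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- b
      out <- c(out, nb)
    }
  }
  out
}

## Per-codon synonymous site count: at each position, the fraction of the 3
## possible single-nucleotide changes that preserve the amino acid (changes
## to stop codons count as nonsynonymous).  Stop codons get NA.
syn_sites_per_codon <- function() {
  if (!is.null(.wgd_cache$syn_sites)) return(.wgd_cache$syn_sites)
  tab <- codon_table()
  s <- numeric(64)
  for (i in seq_len(64)) {
    if (tab$is_stop[i]) { s[i] <- NA_real_; next }
    cod <- tab$codon[i]
    nsyn <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(cod, pos, pos))) {
        nb <- cod
        substr(nb, pos, pos) <- b
        j <- tab$index[[nb]]
        if (!tab$is_stop[j] && tab$aa[j] == tab$aa[i]) nsyn <- nsyn + 1
      }
    }
    s[i] <- nsyn / 3
  }
  names(s) <- tab$codon
  .wgd_cache$syn_sites <- s
  s
}

## Classify one mutational step between two sense codons: 1 = synonymous.
step_is_syn <- function(i, j, tab) {
  tab$aa[i] == tab$aa[j]
}

## Pathway-averaged (sd, nd) for a single codon pair.  All orderings of the
## differing positions are enumerated; pathways passing through a stop codon
## are excluded from the average (if every pathway is blocked -- possible
## only for a handful of stop-adjacent pairs -- all pathways are used, with
## steps into/out of stops counted as nonsynonymous).
pair_path_counts <- function(c1, c2, tab) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  orders <- if (length(pos) == 1) list(pos) else
    apply(perms(length(pos)), 1, function(o) pos[o], simplify = FALSE)
  paths <- lapply(orders, function(ord) {
    cur <- c1
    sdd <- 0; ndd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      i <- tab$index[[cur]]; j <- tab$index[[nxt]]
      if (tab$is_stop[j] && nxt != c2) blocked <- TRUE
      if (!tab$is_stop[i] && !tab$is_stop[j] && step_is_syn(i, j, tab)) {
        sdd <- sdd + 1
      } else {
        ndd <- ndd + 1
      }
      cur <- nxt
    }
    c(sd = sdd, nd = ndd, blocked = as.numeric(blocked))
  })
  m <- do.call(rbind, paths)
  keep <- m[, "blocked"] == 0
  if (any(keep)) m <- m[keep, , drop = FALSE]
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

## 64x64 pathway-averaged difference matrices (stop rows/cols NA).
path_count_matrices <- function() {
  if (!is.null(.wgd_cache$SD)) {
    return(list(SD = .wgd_cache$SD, ND = .wgd_cache$ND))
  }
  tab <- codon_table()
  SD <- matrix(NA_real_, 64, 64, dimnames = list(tab$codon, tab$codon))
  ND <- SD
  sense <- which(!tab$is_stop)
  for (i in sense) {
    for (j in sense) {
      if (j < i) next
      cnt <- pair_path_counts(tab$codon[i], tab$codon[j], tab)
      SD[i, j] <- SD[j, i] <- cnt["sd"]
      ND[i, j] <- ND[j, i] <- cnt["nd"]
    }
  }
  .wgd_cache$SD <- SD
  .wgd_cache$ND <- ND
  list(SD = SD, ND = ND)
}

## Synonymous / nonsynonymous sense neighbours per codon (for the mutation
## simulator).  Neighbours that are stop codons are never offered.
codon_mutation_menu <- function() {
  if (!is.null(.wgd_cache$menu)) return(.wgd_cache$menu)
  tab <- codon_table()
  syn <- vector("list", 64)
  nonsyn <- vector("list", 64)
  for (i in seq_len(64)) {
    if (tab$is_stop[i]) next
    nbs <- codon_neighbours(tab$codon[i])
    idx <- tab$index[nbs]
    sense <- idx[!tab$is_stop[idx]]
    syn[[i]] <- unname(sense[tab$aa[sense] == tab$aa[i]])
    nonsyn[[i]] <- unname(sense[tab$aa[sense] != tab$aa[i]])
  }
  menu <- list(syn = syn, nonsyn = nonsyn)
  .wgd_cache$menu <- menu
  menu
}

## Split a CDS string into codon indices (1..64).  Assumes length %% 3 == 0.
cds_to_codon_idx <- function(cds) {
  tab <- codon_table()
  n <- nchar(cds)
  if (n < 3L) return(integer(0))
  starts <- seq(1L, n, 3L)
  unname(tab$index[substring(cds, starts, starts + 2L)])
}

codon_idx_to_cds <- function(idx) {
  paste(codon_table()$codon[idx], collapse = "")
}
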