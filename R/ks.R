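## ks_engine: codon alignment and Nei-Gojobori (NG86) Ka/Ks estimation with
## Jukes-Cantor multiple-hit correction.

#' Align two coding sequences codon-by-codon
#'
#' The translated proteins are globally aligned (Needleman-Wunsch, match +1 /
#' mismatch -1, gap opening 10, gap extension 0.5 by default) and the
#' alignment is back-threaded onto the nucleotide sequences; columns
#' containing a gap are dropped.  Equal-length sequence pairs whose direct
#' codon pairing already shows at least 30% amino-acid identity skip the
#' alignment step (no gaps can improve an ungapped pairing of full-length
#' homologous CDS at that identity), which matters when scoring tens of
#' thousands of pairs.
#'
#' @param cds_a,cds_b Nucleotide CDS strings (in frame; a terminal stop codon
#'   is tolerated and stripped).
#' @param match,mismatch,gap_open,gap_ext Protein alignment scoring
#'   parameters.
#' @return A two-column integer matrix of aligned codon indices (1..64), one
#'   row per gapless aligned codon pair.
#' @export
codon_align <- function(cds_a, cds_b, match = 1, mismatch = -1,
                        gap_open = 10, gap_ext = 0.5) {
  tab <- codon_table()
  prep <- function(cds, label) {
    n <- nchar(cds)
    if (n %% 3 != 0) cds <- substr(cds, 1, n - n %% 3)
    idx <- cds_to_codon_idx(cds)
    if (anyNA(idx)) stop("non-ACGT codon in ", label)
    if (length(idx) && tab$is_stop[idx[length(idx)]]) idx <- idx[-length(idx)]
    if (!length(idx)) stop("empty CDS after translation (", label, ")")
    if (any(tab$is_stop[idx])) stop("internal stop codon in ", label)
    idx
  }
  ia <- prep(cds_a, "cds_a")
  ib <- prep(cds_b, "cds_b")
  if (length(ia) == length(ib)) {
    ident <- mean(tab$aa[ia] == tab$aa[ib])
    if (ident >= 0.3) return(cbind(codon_a = ia, codon_b = ib))
  }
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  sm <- matrix(mismatch, 20, 20, dimnames = list(aa, aa))
  diag(sm) <- match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(tab$aa[ia], collapse = "")),
    Biostrings::AAString(paste(tab$aa[ib], collapse = "")),
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_ext,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pos_a <- cumsum(sa != "-")
  pos_b <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  cbind(codon_a = ia[pos_a[keep]], codon_b = ib[pos_b[keep]])
}

#' Nei-Gojobori (NG86) Ka/Ks from aligned codon pairs
#'
#' Synonymous site counts use the standard genetic code (per position, the
#' fraction of the 3 possible changes that are synonymous), averaged over the
#' two sequences.  Codons differing at several positions are resolved by
#' averaging synonymous/nonsynonymous difference counts over all minimal
#' mutational pathways, excluding pathways through stop codons.  Proportions
#' are Jukes-Cantor corrected: `K = -3/4 * log(1 - 4/3 * p)`; a proportion at
#' or beyond 3/4 yields `NA` with status `"saturated"` rather than an error.
#'
#' @param pairs Aligned codon pairs as returned by [codon_align()] (a
#'   two-column matrix of codon indices, or a list of `c(codon_a, codon_b)`
#'   3-letter strings).
#' @return List of class `ng86_result`: `ks`, `ka`, `s_sites`, `n_sites`,
#'   `sd` (synonymous differences), `nd`, `ps`, `pn`, `status`.
#' @export
ng86 <- function(pairs) {
  if (is.list(pairs) && !is.matrix(pairs)) {
    tab <- codon_table()
    pairs <- do.call(rbind, lapply(pairs, function(p)
      c(tab$index[[p[1]]], tab$index[[p[2]]])))
  }
  if (!nrow(pairs)) stop("need at least one aligned codon pair")
  syn <- syn_sites_per_codon()
  mats <- path_count_matrices()
  sa <- syn[pairs[, 1]]
  sb <- syn[pairs[, 2]]
  if (anyNA(sa) || anyNA(sb)) stop("stop codon among aligned pairs")
  s_sites <- (sum(sa) + sum(sb)) / 2
  n_sites <- 3 * nrow(pairs) - s_sites
  sd_ <- sum(mats$SD[pairs])
  nd_ <- sum(mats$ND[pairs])
  if (s_sites <= 0) stop("zero synonymous sites: degenerate input")
  ps <- sd_ / s_sites
  pn <- nd_ / n_sites
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  ks <- jc(ps)
  ka <- jc(pn)
  status <- if (is.na(ks) || is.na(ka)) "saturated" else "ok"
  structure(list(ks = ks, ka = ka, s_sites = s_sites, n_sites = n_sites,
                 sd = sd_, nd = nd_, ps = ps, pn = pn, status = status),
            class = "ng86_result")
}

#' @export
print.ng86_result <- function(x, ...) {
  cat(sprintf("<ng86> Ks = %s  Ka = %s  (S = %.2f, N = %.2f, status = %s)\n",
              format(x$ks, digits = 4), format(x$ka, digits = 4),
              x$s_sites, x$n_sites, x$status))
  invisible(x)
}

## Ka/Ks for one gene pair given genomes with attached CDS.
ks_for_pair <- function(gene_a, gene_b, genome_a, genome_b) {
  cds_a <- genome_a$cds[[gene_a]]
  cds_b <- genome_b$cds[[gene_b]]
  if (is.null(cds_a) || is.null(cds_b)) {
    return(list(ks = NA_real_, ka = NA_real_, status = "no_cds"))
  }
  res <- tryCatch(ng86(codon_align(cds_a, cds_b)),
                  error = function(e) NULL)
  if (is.null(res)) return(list(ks = NA_real_, ka = NA_real_,
                                status = "failed"))
  list(ks = res$ks, ka = res$ka, status = res$status)
}

#' Fill per-pair Ks/Ka and per-block median Ks on detected blocks
#'
#' Saturated and failed pairs are excluded from a block's median; a block is
#' flagged when more than half of its pairs are excluded (its median is `NA`
#' when no pair survives).  Genes flagged invalid for Ks at load time
#' (internal stops) yield status `"invalid_cds"`.
#'
#' @param blocks A `wgd_blocks` object.
#' @param genome_a,genome_b The genomes the blocks were detected on, with
#'   CDS attached.
#' @return The `wgd_blocks` object with `pairs$ks`, `pairs$ka`,
#'   `pairs$status`, `blocks$median_ks` and `blocks$flagged` filled.
#' @export
annotate_block_ks <- function(blocks, genome_a, genome_b) {
  if (is.null(genome_a$cds) || is.null(genome_b$cds)) {
    stop("annotate_block_ks needs CDS attached to both genomes")
  }
  valid_a <- setNames(genome_a$genes$ks_valid, genome_a$genes$id)
  valid_b <- setNames(genome_b$genes$ks_valid, genome_b$genes$id)
  p <- blocks$pairs
  for (i in seq_len(nrow(p))) {
    if (!isTRUE(valid_a[[p$gene_a[i]]]) || !isTRUE(valid_b[[p$gene_b[i]]])) {
      p$status[i] <- "invalid_cds"
      next
    }
    r <- ks_for_pair(p$gene_a[i], p$gene_b[i], genome_a, genome_b)
    p$ks[i] <- r$ks; p$ka[i] <- r$ka; p$status[i] <- r$status
  }
  blocks$pairs <- p
  for (i in seq_len(nrow(blocks$blocks))) {
    bid <- blocks$blocks$block_id[i]
    ks <- p$ks[p$block_id == bid]
    ok <- !is.na(ks)
    blocks$blocks$median_ks[i] <- if (any(ok)) median(ks[ok]) else NA_real_
    blocks$blocks$flagged[i] <- mean(!ok) > 0.5
  }
  blocks
}

#' Write the per-pair Ks table
#'
#' @param blocks An annotated `wgd_blocks` object.
#' @param path Output path.
#' @export
write_ks <- function(blocks, path) {
  write_tsv_commented(
    blocks$pairs[, c("gene_a", "gene_b", "block_id", "ka", "ks", "status")],
    path)
}
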