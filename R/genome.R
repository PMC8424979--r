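## genome_io: gene annotations, coding sequences and homology hit tables.

#' Construct a genome object from a gene data frame
#'
#' Internal constructor shared by [load_genome()] and the simulator.  Genes
#' are sorted by (chromosome, start) and assigned a dense 0-based `rank`
#' within each chromosome.
#'
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param species_tag Short species label (e.g. `"V"`).
#' @param cds Optional named character vector of coding sequences (names are
#'   gene ids).
#' @return An object of class `wgd_genome`: a list with elements `species`,
#'   `genes` (with `rank` and `ks_valid` columns), `chromosomes` and `cds`.
#' @export
new_genome <- function(genes, species_tag, cds = NULL) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(genes)))
  genes$id <- as.character(genes$id)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(genes$id)) {
    stop("duplicate gene id: ",
         paste(unique(genes$id[duplicated(genes$id)])[1:3], collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (is.null(genes$strand)) genes$strand <- "unknown"
  genes <- genes[order(genes$chrom, genes$start, genes$id), , drop = FALSE]
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chrom,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  genes$ks_valid <- TRUE
  g <- structure(list(
    species = species_tag,
    genes = genes,
    chromosomes = as.data.frame(table(chrom = genes$chrom),
                                stringsAsFactors = FALSE),
    cds = NULL
  ), class = "wgd_genome")
  names(g$chromosomes) <- c("chrom", "n_genes")
  if (!is.null(cds)) g <- attach_cds(g, cds)
  g
}

#' @export
print.wgd_genome <- function(x, ...) {
  cat("<wgd_genome> species:", x$species,
      "|", nrow(x$genes), "genes on", nrow(x$chromosomes), "chromosomes",
      if (!is.null(x$cds)) "| CDS attached" else "", "\n")
  invisible(x)
}

## CDS trimming policy: a length not divisible by 3 has its trailing 1-2 nt
## removed (logged); a terminal stop codon is stripped; any internal stop
## flags the gene as unusable for Ks (ks_valid = FALSE) without dropping it.
attach_cds <- function(genome, cds) {
  cds <- cds[names(cds) %in% genome$genes$id]
  trimmed <- 0L
  tab <- codon_table()
  for (i in seq_along(cds)) {
    n <- nchar(cds[[i]])
    if (n %% 3 != 0) {
      cds[[i]] <- substr(cds[[i]], 1L, n - n %% 3L)
      trimmed <- trimmed + 1L
    }
  }
  if (trimmed) wgd_log(trimmed, " CDS trimmed to a multiple of 3 nt")
  bad <- character(0)
  for (id in names(cds)) {
    idx <- cds_to_codon_idx(cds[[id]])
    if (anyNA(idx)) { bad <- c(bad, id); next }  # ambiguity codes
    if (length(idx) && tab$is_stop[idx[length(idx)]]) {
      idx <- idx[-length(idx)]
      cds[[id]] <- codon_idx_to_cds(idx)
    }
    if (!length(idx) || any(tab$is_stop[idx])) bad <- c(bad, id)
  }
  if (length(bad)) {
    wgd_log(length(bad), " CDS flagged invalid for Ks (internal stop/empty)")
    genome$genes$ks_valid[genome$genes$id %in% bad] <- FALSE
  }
  genome$genes$ks_valid[!genome$genes$id %in% names(cds)] <- FALSE
  genome$cds <- cds
  genome
}

#' Load a genome from a GFF3 or 4-column gene-bed annotation
#'
#' GFF3 files (`.gff`, `.gff3`) are parsed with \pkg{rtracklayer}; features
#' of type `gene` (or `mRNA` when no `gene` features exist) are kept and the
#' gene id is taken from the `ID` attribute.  Any other file is read as a
#' 4-column tab-delimited gene bed: `id`, `chrom`, `start`, `end` (1-based
#' inclusive), with an optional 5th `strand` column.
#'
#' @param annotation_path Path to the annotation file.
#' @param fasta_path Optional FASTA of coding sequences; sequences are
#'   attached by gene id and run through the CDS trimming policy.
#' @param species_tag Species label stored on the genome (defaults to the
#'   annotation file stem).
#' @return A `wgd_genome` object.
#' @export
load_genome <- function(annotation_path, fasta_path = NULL,
                        species_tag = NULL) {
  if (!file.exists(annotation_path)) stop("no such file: ", annotation_path)
  if (is.null(species_tag)) {
    species_tag <- sub("\\.[^.]*$", "", basename(annotation_path))
  }
  if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(annotation_path)
    type <- as.character(gr$type)
    keep <- type == "gene"
    if (!any(keep)) keep <- type == "mRNA"
    gr <- gr[keep]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene features must carry ID=")
    genes <- data.frame(
      id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    genes$strand[genes$strand == "*"] <- "unknown"
  } else {
    genes <- read.delim(annotation_path, header = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
    if (ncol(genes) < 4) stop("gene bed needs >= 4 columns (id chrom start end)")
    names(genes)[1:4] <- c("id", "chrom", "start", "end")
    if (ncol(genes) >= 5) names(genes)[5] <- "strand"
  }
  cds <- NULL
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    cds <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  }
  new_genome(genes, species_tag, cds = cds)
}

#' Write a genome's gene models as a commented-header TSV
#'
#' @param genome A `wgd_genome`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path) {
  write_tsv_commented(
    genome$genes[, c("id", "chrom", "start", "end", "strand", "rank")], path)
}

#' Load an all-vs-all homology hit table
#'
#' Accepts the 12-column BLAST tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) or a declared
#' 3-column `query subject evalue` dialect.  Hits above the E-value cutoff
#' and self-hits are removed, then at most `top_n` subjects are retained per
#' query (ranked by bitscore, ties by E-value); `top_n = 0` disables the
#' thinning.  Malformed rows are skipped with a warning.
#'
#' @param path Tab-delimited hit table.
#' @param evalue_cutoff Maximum E-value retained (default `1e-5`).
#' @param top_n Best hits kept per query (default 5; 0 = keep all).
#' @return data.frame with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
load_hits <- function(path, evalue_cutoff = 1e-5, top_n = 5) {
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 12) {
    hits <- data.frame(query = as.character(raw[[1]]),
                       subject = as.character(raw[[2]]),
                       evalue = suppressWarnings(as.numeric(raw[[11]])),
                       bitscore = suppressWarnings(as.numeric(raw[[12]])),
                       stringsAsFactors = FALSE)
  } else if (ncol(raw) >= 3) {
    hits <- data.frame(query = as.character(raw[[1]]),
                       subject = as.character(raw[[2]]),
                       evalue = suppressWarnings(as.numeric(raw[[3]])),
                       bitscore = if (ncol(raw) >= 4)
                         suppressWarnings(as.numeric(raw[[4]])) else
                           -log10(pmax(suppressWarnings(as.numeric(raw[[3]])),
                                       1e-300)),
                       stringsAsFactors = FALSE)
  } else {
    stop("hit table must have >= 3 columns")
  }
  bad <- is.na(hits$evalue) | is.na(hits$bitscore) |
    hits$query == "" | hits$subject == ""
  if (any(bad)) {
    warning(sum(bad), " malformed hit rows skipped")
    hits <- hits[!bad, , drop = FALSE]
  }
  filter_hits(hits, evalue_cutoff = evalue_cutoff, top_n = top_n)
}

#' Filter an in-memory hit table (E-value cutoff, self-hits, top-n)
#'
#' The same filtering [load_hits()] applies, exposed for hit tables built in
#' code (e.g. by the simulator).  Idempotent.
#'
#' @inheritParams load_hits
#' @param hits data.frame with `query`, `subject`, `evalue`, `bitscore`.
#' @return Filtered data.frame.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-5, top_n = 5) {
  hits <- hits[hits$evalue <= evalue_cutoff & hits$query != hits$subject, ,
               drop = FALSE]
  if (top_n > 0 && nrow(hits)) {
    hits <- hits[order(hits$query, -hits$bitscore, hits$evalue,
                       hits$subject), , drop = FALSE]
    keep <- stats::ave(seq_len(nrow(hits)), hits$query,
                       FUN = seq_along) <= top_n
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  if (!nrow(hits)) warning("zero hits survive filtering")
  hits
}

#' Write a hit table in the 3-column dialect
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  write_tsv_commented(hits[, c("query", "subject", "evalue", "bitscore")],
                      path)
}
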