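## homology_table: the event-related multi-genome colinear gene table.
## With one reference diploid, one further diploid and one tetraploid this
## is the classic 12-column layout: reference + 2 paralog columns from the
## shared hexaploidy, 3 ortholog columns for the diploid, 6 for the
## tetraploid (2 sibling columns per reference column).

#' Specify the column plan of a homology table
#'
#' @param reference_tag Reference species tag.
#' @param species_tags Non-reference species tags, in column order.
#' @param multiplicity Integer vector (same length): expected orthologous
#'   regions per reference region (1 for a diploid sharing only the
#'   reference's paleo-history, 2 for a lineage that doubled afterwards).
#' @param n_ref_paralogs Extra collinear genes per reference gene from the
#'   shared event (2 under a hexaploidy).
#' @return Object of class `wgd_tablespec` with the derived column names.
#' @export
table_spec <- function(reference_tag, species_tags, multiplicity,
                       n_ref_paralogs = 2) {
  stopifnot(length(species_tags) == length(multiplicity))
  cols <- c(reference_tag,
            paste0(reference_tag, "-p", seq_len(n_ref_paralogs)))
  for (i in seq_along(species_tags)) {
    s <- species_tags[i]; m <- multiplicity[i]
    cols <- c(cols, ortho_col_names(s, m, 0),
              unlist(lapply(seq_len(n_ref_paralogs),
                            function(px) ortho_col_names(s, m, px))))
  }
  structure(list(reference = reference_tag, species = species_tags,
                 multiplicity = setNames(as.integer(multiplicity),
                                         species_tags),
                 n_ref_paralogs = as.integer(n_ref_paralogs),
                 columns = cols),
            class = "wgd_tablespec")
}

## Column names for species s, multiplicity m, anchored on reference column
## px (0 = the reference gene column itself, 1.. = its paralog columns).
ortho_col_names <- function(s, m, px) {
  base <- if (px == 0) paste0(s, "-o") else paste0(s, "-p", px)
  if (m == 1) return(base)
  if (px == 0) paste0(base, seq_len(m)) else paste0(base, letters[seq_len(m)])
}

## One "view" per block direction: anchor genes on the reference axis,
## partner genes to be placed in a column.
block_views <- function(blocks, pairs, anchor = c("a", "b")) {
  anchor <- match.arg(anchor)
  lapply(seq_len(nrow(blocks)), function(i) {
    bl <- blocks[i, ]
    pp <- pairs[pairs$block_id == bl$block_id, ]
    if (anchor == "a") {
      list(block_id = bl$block_id, n_pairs = bl$n_pairs,
           chrom = bl$chrom_a, lo = bl$start_a, hi = bl$end_a,
           partner_chrom = bl$chrom_b,
           anchor_genes = pp$gene_a, partner_genes = pp$gene_b)
    } else {
      list(block_id = bl$block_id, n_pairs = bl$n_pairs,
           chrom = bl$chrom_b, lo = bl$start_b, hi = bl$end_b,
           partner_chrom = bl$chrom_a,
           anchor_genes = pp$gene_b, partner_genes = pp$gene_a)
    }
  })
}

## Assign block views to a fixed number of column slots.  Views are taken
## largest-first; a slot is free if no view already assigned to it overlaps
## the candidate's anchor interval on the same chromosome by more than a
## boundary margin (fragments of one homologous region may abut or slightly
## overlap where chains frayed, and must stay in one column).  Among free slots
## prefer (i) a slot NOT holding the candidate's sibling-linked genes (the
## tetraploid's own self-collinearity partners must land in different
## columns), (ii) a slot already holding views from the same partner
## chromosome (footprint continuity), (iii) the lowest slot index.  Views
## with no free slot are dropped and counted.
assign_slots <- function(views, n_slots, link_map = NULL) {
  ord <- order(-vapply(views, `[[`, numeric(1), "n_pairs"),
               vapply(views, `[[`, numeric(1), "block_id"))
  slots <- replicate(n_slots, list(), simplify = FALSE)
  assignment <- integer(length(views))
  dropped <- 0L
  for (vi in ord) {
    v <- views[[vi]]
    margin <- max(3, 0.1 * (v$hi - v$lo + 1))
    free <- which(vapply(slots, function(sl) {
      !any(vapply(sl, function(w) {
        ov <- min(w$hi, v$hi) - max(w$lo, v$lo) + 1
        w$chrom == v$chrom &&
          ov > max(margin, 0.1 * (w$hi - w$lo + 1))
      }, logical(1)))
    }, logical(1)))
    if (!length(free)) { dropped <- dropped + 1L; next }
    score <- numeric(length(free))
    if (!is.null(link_map)) {
      sibs <- unique(unlist(link_map[v$partner_genes], use.names = FALSE))
      if (length(sibs)) {
        holds_sib <- vapply(slots[free], function(sl)
          any(vapply(sl, function(w) any(w$partner_genes %in% sibs),
                     logical(1))), logical(1))
        score[holds_sib] <- score[holds_sib] - 2
      }
    }
    cont <- vapply(slots[free], function(sl)
      any(vapply(sl, function(w)
        w$chrom == v$chrom && w$partner_chrom == v$partner_chrom,
        logical(1))), logical(1))
    score[cont] <- score[cont] + 1
    ## sibling column labels are arbitrary: when several slots tie, pick one
    ## by a deterministic hash of the partner chromosome rather than always
    ## the lowest index, so "column 1" does not systematically collect the
    ## locally denser homologous region
    best <- free[score == max(score)]
    k <- if (length(best) == 1) best else
      best[1 + sum(utf8ToInt(v$partner_chrom)) %% length(best)]
    slots[[k]] <- c(slots[[k]], list(v))
    assignment[vi] <- k
  }
  list(assignment = assignment, dropped = dropped, order = ord)
}

## Build one gene -> partner map per slot, respecting the one-cell-per-gene
## rule within a column.  Views are consumed in assignment (largest-first)
## order, so on conflicts the longer block wins.  A pair whose cell is
## already taken in its view's slot is offered the sibling slots (block
## boundaries of co-orthologous fragments fray by a few genes); only pairs
## no slot can hold are counted as conflicts.
slot_maps <- function(views, assignment, ord, n_slots) {
  maps <- replicate(n_slots, new.env(parent = emptyenv()), simplify = FALSE)
  used <- replicate(n_slots, new.env(parent = emptyenv()), simplify = FALSE)
  conflicts <- 0L
  for (vi in ord) {
    k <- assignment[vi]
    if (k == 0L) next
    v <- views[[vi]]
    for (j in seq_along(v$anchor_genes)) {
      a <- v$anchor_genes[j]; p <- v$partner_genes[j]
      placed <- FALSE
      for (kk in c(k, setdiff(seq_len(n_slots), k))) {
        if (is.null(maps[[kk]][[a]]) && is.null(used[[kk]][[p]])) {
          maps[[kk]][[a]] <- c(p, v$block_id)
          used[[kk]][[p]] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) conflicts <- conflicts + 1L
    }
  }
  list(maps = maps, conflicts = conflicts)
}

lookup_slot <- function(map, genes) {
  t(vapply(genes, function(g) {
    v <- map[[g]]
    if (is.null(v) || is.na(g)) c(".", NA_character_) else v
  }, character(2)))
}

#' Build the event-related multi-genome homologous gene table
#'
#' Rows are the reference genes in genome order.  The reference's paralog
#' columns are filled from its self-comparison blocks labelled with
#' `self_event`; each non-reference species' columns are filled from the
#' cross-genome blocks labelled as speciation orthologs, split across
#' sibling columns (for a post-speciation polyploid) by footprint slotting
#' aided by the polyploid's own self-collinearity.  Missing collinear genes
#' are the literal dot `"."`.
#'
#' @param spec A [table_spec()].
#' @param reference The reference `wgd_genome`.
#' @param blocks_list List of labelled `wgd_blocks`: the reference
#'   self-comparison, one cross-comparison per species, and (optionally) the
#'   polyploid's self-comparison for sibling linking.
#' @param self_event Label of the shared-event paralog blocks (default
#'   `"ECH"`).
#' @param ortho_event Label(s) of speciation ortholog blocks; default: any
#'   label starting with `"speciation"` or `"orth"`.
#' @param sibling_event Label of the polyploid's own duplication blocks used
#'   for sibling linking (default `"AST"`).
#' @return Object of class `wgd_homtable`: `table` (character matrix),
#'   `provenance` (block-id matrix), `ref_genes`, `spec`, `dropped`,
#'   `conflicts`.
#' @export
build_table <- function(spec, reference, blocks_list, self_event = "ECH",
                        ortho_event = NULL, sibling_event = "AST") {
  stopifnot(inherits(spec, "wgd_tablespec"))
  ref <- spec$reference
  ref_genes <- reference$genes[, c("id", "chrom", "rank")]
  nrows <- nrow(ref_genes)
  tab <- matrix(".", nrows, length(spec$columns),
                dimnames = list(NULL, spec$columns))
  prov <- matrix(NA_character_, nrows, length(spec$columns),
                 dimnames = list(NULL, spec$columns))
  tab[, ref] <- ref_genes$id
  dropped <- 0L; conflicts <- 0L

  is_orth <- function(ev) {
    if (!is.null(ortho_event)) ev %in% ortho_event else
      grepl("^speciation|^orth", ev)
  }
  find_blocks <- function(a, b) {
    for (bl in blocks_list) {
      if ((identical(bl$genome_a, a) && identical(bl$genome_b, b)) ||
          (identical(bl$genome_a, b) && identical(bl$genome_b, a))) return(bl)
    }
    NULL
  }

  ## reference paralog columns from the shared-event self blocks
  px_cols <- paste0(ref, "-p", seq_len(spec$n_ref_paralogs))
  selfb <- find_blocks(ref, ref)
  par_maps <- NULL
  if (!is.null(selfb)) {
    bsel <- selfb$blocks[selfb$blocks$event %in% self_event, , drop = FALSE]
    views <- c(block_views(bsel, selfb$pairs, "a"),
               block_views(bsel, selfb$pairs, "b"))
    if (length(views)) {
      asg <- assign_slots(views, spec$n_ref_paralogs)
      dropped <- dropped + asg$dropped
      sm <- slot_maps(views, asg$assignment, asg$order, spec$n_ref_paralogs)
      conflicts <- conflicts + sm$conflicts
      par_maps <- sm$maps
      for (px in seq_len(spec$n_ref_paralogs)) {
        cell <- lookup_slot(par_maps[[px]], ref_genes$id)
        tab[, px_cols[px]] <- cell[, 1]
        prov[, px_cols[px]] <- cell[, 2]
      }
    }
  }

  ## ortholog columns per species
  for (s in spec$species) {
    m <- spec$multiplicity[[s]]
    crossb <- find_blocks(ref, s)
    if (is.null(crossb)) next
    bsel <- crossb$blocks[is_orth(crossb$blocks$event), , drop = FALSE]
    anchor_side <- if (identical(crossb$genome_a, ref)) "a" else "b"
    views <- block_views(bsel, crossb$pairs, anchor_side)
    if (!length(views)) next
    link_map <- NULL
    if (m > 1) {
      sb <- find_blocks(s, s)
      if (!is.null(sb)) {
        dup <- sb$blocks[sb$blocks$event %in% sibling_event, , drop = FALSE]
        pp <- sb$pairs[sb$pairs$block_id %in% dup$block_id, ]
        if (nrow(pp)) {
          link_map <- split(c(pp$gene_b, pp$gene_a), c(pp$gene_a, pp$gene_b))
        }
      }
    }
    asg <- assign_slots(views, m, link_map)
    dropped <- dropped + asg$dropped
    sm <- slot_maps(views, asg$assignment, asg$order, m)
    conflicts <- conflicts + sm$conflicts
    for (k in seq_len(m)) {
      for (px in 0:spec$n_ref_paralogs) {
        col <- ortho_col_names(s, m, px)[if (m == 1) 1 else k]
        anchors <- if (px == 0) ref_genes$id else tab[, px_cols[px]]
        cell <- lookup_slot(sm$maps[[k]], anchors)
        tab[, col] <- cell[, 1]
        prov[, col] <- cell[, 2]
      }
    }
  }
  if (dropped) wgd_log(dropped, " block views beyond column multiplicity dropped")
  if (conflicts) wgd_log(conflicts, " cell conflicts resolved by block length")
  structure(list(table = tab, provenance = prov, ref_genes = ref_genes,
                 spec = spec, dropped = dropped, conflicts = conflicts),
            class = "wgd_homtable")
}

#' @export
print.wgd_homtable <- function(x, ...) {
  cat("<wgd_homtable>", nrow(x$table), "rows x", ncol(x$table),
      "columns | reference", x$spec$reference, "\n")
  invisible(x)
}

#' Per-column fill statistics of a homology table
#'
#' @param table A `wgd_homtable`.
#' @return List: `stats` (data.frame `column`, `filled`, `retention`) and
#'   `co_retention` (for each sibling column pair of a multiplicity-2
#'   species, the fraction of rows with both siblings present).
#' @export
column_stats <- function(table) {
  tab <- table$table
  filled <- colSums(tab != ".")
  stats <- data.frame(column = colnames(tab), filled = as.integer(filled),
                      retention = as.numeric(filled / nrow(tab)),
                      stringsAsFactors = FALSE)
  co <- list()
  spec <- table$spec
  for (s in spec$species) {
    m <- spec$multiplicity[[s]]
    if (m < 2) next
    for (px in 0:spec$n_ref_paralogs) {
      cols <- ortho_col_names(s, m, px)
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        key <- paste(cols[i], cols[j], sep = "&")
        co[[key]] <- mean(tab[, cols[i]] != "." & tab[, cols[j]] != ".")
      }
    }
  }
  list(stats = stats, co_retention = unlist(co))
}

#' Export per-cell tick records for a circular or linear alignment graph
#'
#' One record per non-missing cell: the column (track), the global and
#' within-chromosome reference position, and the chromosome of the gene in
#' the cell (the colour key), plus a layout coordinate (`angle` in radians
#' for circular, `x` for linear).
#'
#' @param table A `wgd_homtable`.
#' @param layout `"circular"` or `"linear"`.
#' @param gene_chrom Named chromosome lookup for every placed gene id
#'   (defaults to the reference's own genes; supply a combined lookup to
#'   colour other species' ticks).
#' @return data.frame of tick records.
#' @export
export_alignment_graph <- function(table, layout = c("circular", "linear"),
                                   gene_chrom = NULL) {
  layout <- match.arg(layout)
  if (is.null(gene_chrom)) {
    gene_chrom <- setNames(table$ref_genes$chrom, table$ref_genes$id)
  }
  tab <- table$table
  n <- nrow(tab)
  recs <- list()
  for (col in colnames(tab)) {
    sel <- which(tab[, col] != ".")
    if (!length(sel)) next
    ids <- tab[sel, col]
    recs[[col]] <- data.frame(
      column = col, track = match(col, colnames(tab)), row = sel,
      ref_chrom = table$ref_genes$chrom[sel],
      ref_rank = table$ref_genes$rank[sel],
      cell_gene = ids,
      cell_chrom = unname(gene_chrom[ids]),
      coord = if (layout == "circular") 2 * pi * (sel - 1) / n else sel,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(column = character(0), track = integer(0), row = integer(0),
               ref_chrom = character(0), ref_rank = integer(0),
               cell_gene = character(0), cell_chrom = character(0),
               coord = numeric(0))
  rownames(out) <- NULL
  attr(out, "layout") <- layout
  out
}

#' Write a homology table as TSV (dot = missing), plus provenance
#'
#' @param table A `wgd_homtable`.
#' @param path Output path; provenance goes to `<path>.provenance`.
#' @export
write_homtable <- function(table, path) {
  df <- as.data.frame(table$table, stringsAsFactors = FALSE)
  write_tsv_commented(df, path)
  pv <- as.data.frame(table$provenance, stringsAsFactors = FALSE)
  write_tsv_commented(pv, paste0(path, ".provenance"))
  invisible(path)
}
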