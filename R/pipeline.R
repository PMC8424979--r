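## cli_reporting: one orchestrated run from config to reports, plus dotplot
## data export.  The R functions are the primary interface; the thin
## command-line wrapper in inst/scripts/wgdkit.R drives this module.

#' Run the full paleopolyploidy inference pipeline
#'
#' Stages: load or simulate the genomes and hit tables; detect collinear
#' blocks for every genome comparison (self and cross); annotate Ks;
#' partition blocks into event groups via Ks windows (user-supplied or
#' mixture-suggested); profile ortholog depth against the reference and
#' infer each species' multiplicity; build the event-related homology table;
#' fractionation statistics with a geometric run-length fit; Ks peak
#' fitting, lineage rate correction and calibrated dating.
#'
#' @param config A list (or path to a YAML file) with any of: `seed`,
#'   `simulate` (arguments to [sim_config()]), `inputs` (per-species
#'   `annotation`/`cds` paths and per-pair hit-table paths), `reference`,
#'   `second_reference`, `evalue_cutoff`, `top_n`, `max_gap`, `min_pairs`,
#'   `windows` (`"auto"` or a [ks_windows()] per comparison),
#'   `window_genes`, `l_max`, `calibration`, `out_dir`.  Defaults mirror the
#'   field's standard settings (E-value 1e-5, gap 50, min pairs 4,
#'   calibration 115-130 Mya).
#' @return List of class `wgd_pipeline_result`: `summary` (block tallies,
#'   ploidy calls, peaks, rate factors, dates), `blocks`, `table`,
#'   `fractionation`, `peaks`, `genomes`, and `out_dir` when written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML pipeline config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1, evalue_cutoff = 1e-5, top_n = 5, max_gap = 50,
                   min_pairs = 4, windows = "auto", window_genes = 100,
                   l_max = 15, calibration = c(115, 130),
                   out_dir = NULL, second_reference = NULL)
  config <- modifyList(defaults, config)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }

  ## -- load ---------------------------------------------------------------
  inp <- stage("load", {
    if (!is.null(config$simulate) || is.null(config$inputs)) {
      cfg <- do.call(sim_config, c(list(seed = config$seed),
                                   config$simulate %||% list()))
      bundle <- simulate_history(cfg)
      list(genomes = bundle$genomes,
           hits = lapply(bundle$hits, filter_hits,
                         evalue_cutoff = config$evalue_cutoff,
                         top_n = config$top_n),
           bundle = bundle)
    } else {
      genomes <- lapply(names(config$inputs$species), function(tag) {
        s <- config$inputs$species[[tag]]
        load_genome(s$annotation, s$cds, species_tag = tag)
      })
      names(genomes) <- names(config$inputs$species)
      hits <- lapply(config$inputs$hits, load_hits,
                     evalue_cutoff = config$evalue_cutoff,
                     top_n = config$top_n)
      list(genomes = genomes, hits = hits, bundle = NULL)
    }
  })
  genomes <- inp$genomes
  tags <- names(genomes)
  reference <- config$reference %||% tags[1]

  comparisons <- c(paste0(tags, "-", tags),
                   utils::combn(tags, 2, FUN = paste, collapse = "-"))
  comparisons <- intersect(comparisons, names(inp$hits))

  ## -- blocks + ks --------------------------------------------------------
  blocks <- stage("blocks", {
    out <- list()
    for (cmp in comparisons) {
      sp <- strsplit(cmp, "-")[[1]]
      out[[cmp]] <- detect_blocks(inp$hits[[cmp]], genomes[[sp[1]]],
                                  genomes[[sp[2]]],
                                  max_gap = config$max_gap,
                                  min_pairs = config$min_pairs)
    }
    out
  })
  block_summaries <- lapply(blocks, summarize_blocks)

  blocks <- stage("ks", {
    for (cmp in comparisons) {
      sp <- strsplit(cmp, "-")[[1]]
      if (is.null(genomes[[sp[1]]]$cds) || is.null(genomes[[sp[2]]]$cds)) {
        stop("no CDS for comparison ", cmp,
             ": supply cds FASTA paths for both species")
      }
      blocks[[cmp]] <- annotate_block_ks(blocks[[cmp]], genomes[[sp[1]]],
                                         genomes[[sp[2]]])
    }
    blocks
  })

  ## -- classify -----------------------------------------------------------
  windows <- stage("classify", {
    out <- list()
    for (cmp in comparisons) {
      sp <- strsplit(cmp, "-")[[1]]
      if (!identical(config$windows, "auto") &&
          !is.null(config$windows[[cmp]])) {
        w <- config$windows[[cmp]]
      } else {
        med <- blocks[[cmp]]$blocks$median_ks
        w <- tryCatch(
          suggest_windows(med, n_components = NULL, max_components = 2),
          error = function(e) {
            warning("comparison ", cmp, ": ", conditionMessage(e),
                    "; using one window spanning the observed medians")
            rng <- range(med, na.rm = TRUE)
            ks_windows("peak_1", rng[1] - 0.05, rng[2] + 0.05)
          })
        labels <- if (sp[1] == sp[2]) {
          if (nrow(w) == 1) "ECH" else c("AST", "ECH")
        } else {
          if (nrow(w) == 1) paste0("speciation:", cmp) else
            c(paste0("speciation:", cmp), "ECH")
        }
        w$event <- labels
      }
      blocks[[cmp]] <- partition_blocks(blocks[[cmp]], w)
      out[[cmp]] <- w
    }
    out
  })

  ploidy <- stage("ploidy", {
    out <- list()
    for (s in setdiff(tags, reference)) {
      cmp <- comparisons[grepl(paste0("^", reference, "-", s, "$|^", s, "-",
                                      reference, "$"), comparisons)][1]
      prof <- depth_profile(genomes[[reference]], blocks[[cmp]],
                            event = paste0("speciation:", cmp),
                            window_genes = config$window_genes)
      out[[s]] <- infer_ploidy(prof)
      out[[s]]$profile <- prof
    }
    out
  })
  multiplicity <- vapply(ploidy, `[[`, integer(1), "multiplicity")

  ## -- homology table -----------------------------------------------------
  table <- stage("table", {
    others <- setdiff(tags, reference)
    spec <- table_spec(reference, others, multiplicity[others])
    build_table(spec, genomes[[reference]], blocks)
  })
  table2 <- NULL
  if (!is.null(config$second_reference)) {
    table2 <- stage("table", {
      ref2 <- config$second_reference
      others <- setdiff(tags, ref2)
      mult2 <- vapply(others, function(s)
        if (s %in% names(multiplicity)) multiplicity[[s]] else 1L,
        integer(1))
      build_table(table_spec(ref2, others, mult2), genomes[[ref2]], blocks)
    })
  }

  ## -- fractionation ------------------------------------------------------
  fractionation <- stage("fractionation", {
    losses <- loss_rates(table)
    polyploid <- names(multiplicity)[multiplicity >= 2]
    geom <- NULL; spectrum <- NULL
    if (length(polyploid)) {
      s <- polyploid[1]
      cols <- ortho_col_names(s, multiplicity[[s]], 0)
      specs <- lapply(cols, function(cl)
        run_lengths(table, cl, l_max = config$l_max))
      counts <- Reduce(`+`, lapply(specs, `[[`, "counts"))
      spectrum <- structure(list(
        counts = counts, l_max = config$l_max,
        excluded_long_runs = sum(vapply(specs, `[[`, numeric(1),
                                        "excluded_long_runs")),
        excluded_dots = sum(vapply(specs, `[[`, numeric(1),
                                   "excluded_dots")),
        total_dots = sum(vapply(specs, `[[`, numeric(1), "total_dots"))),
        class = "run_spectrum")
      geom <- fit_geometric(spectrum)
    }
    list(losses = losses, spectrum = spectrum, geometric = geom)
  })

  ## -- peaks, rate correction, dating -------------------------------------
  peaks <- stage("peaks", {
    ## fit ranges come from the labelled pairs themselves (block-median
    ## windows are much tighter than the pair-level Ks spread)
    trim_range <- function(ks) unname(stats::quantile(ks, c(0.005, 0.995)))
    ech_peaks <- list()
    for (s in tags) {
      cmp <- paste0(s, "-", s)
      if (!cmp %in% comparisons) next
      ks <- event_pair_ks(blocks[[cmp]], "ECH")
      ech_peaks[[s]] <- fit_peak(ks, ks_range = trim_range(ks))
    }
    corr <- correct_rates(ech_peaks)
    excess <- vapply(setdiff(tags, corr$reference), function(s)
      rate_excess(ech_peaks[[s]]$mu, ech_peaks[[corr$reference]]$mu),
      numeric(1))
    dates <- list()
    ast_peak <- NULL
    polyploid <- names(multiplicity)[multiplicity >= 2]
    if (length(polyploid)) {
      s <- polyploid[1]
      cmp <- paste0(s, "-", s)
      w <- windows[[cmp]]
      if ("AST" %in% w$event) {
        ks_adj <- adjust_ks(corr, event_pair_ks(blocks[[cmp]], "AST"), s)
        ast_peak <- fit_peak(ks_adj, ks_range = trim_range(ks_adj))
        dates[["AST"]] <- date_event(ast_peak$mu, corr$mu_reference,
                                     config$calibration, event = "AST")
      }
    }
    for (cmp in comparisons) {
      sp <- strsplit(cmp, "-")[[1]]
      if (sp[1] == sp[2]) next
      ev <- paste0("speciation:", cmp)
      if (!ev %in% windows[[cmp]]$event) next
      w <- windows[[cmp]]
      ks_adj <- adjust_ks(corr, event_pair_ks(blocks[[cmp]], ev),
                          sp[1], sp[2])
      pk <- tryCatch(fit_peak(ks_adj, ks_range = trim_range(ks_adj)),
                     error = function(e) NULL)
      if (!is.null(pk)) {
        dates[[ev]] <- date_event(pk$mu, corr$mu_reference,
                                  config$calibration, event = ev)
      }
    }
    list(ech = ech_peaks, ast = ast_peak, correction = corr,
         rate_excess_pct = excess, dates = dates)
  })

  summary <- list(
    seed = config$seed,
    reference = reference,
    block_summaries = block_summaries,
    windows = lapply(windows, function(w) as.data.frame(unclass(w))),
    ploidy = lapply(ploidy, function(p)
      list(multiplicity = p$multiplicity, support = p$support,
           interpretation = p$interpretation)),
    table_columns = colnames(table$table),
    retention = column_stats(table)$stats,
    geometric = if (!is.null(fractionation$geometric))
      unclass(fractionation$geometric)[c("p", "r2", "f_stat", "p_value")],
    peaks = list(
      ech = lapply(peaks$ech, function(p) list(mu = p$mu, sigma = p$sigma,
                                               r2 = p$r2, n = p$n)),
      ast = if (!is.null(peaks$ast))
        list(mu = peaks$ast$mu, sigma = peaks$ast$sigma, r2 = peaks$ast$r2)),
    rate_factors = as.list(peaks$correction$factors),
    rate_excess_pct = as.list(peaks$rate_excess_pct),
    dates = lapply(peaks$dates, function(d)
      list(t_low = d$t_low, t_high = d$t_high, ratio = d$peak_ratio)))

  res <- structure(list(summary = summary, blocks = blocks, table = table,
                        table_second_reference = table2,
                        fractionation = fractionation, peaks = peaks,
                        ploidy = ploidy, genomes = genomes,
                        bundle = inp$bundle, out_dir = config$out_dir),
                   class = "wgd_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

## Pair-level Ks values of blocks labelled with one event.
event_pair_ks <- function(blocks, event) {
  ids <- blocks$blocks$block_id[blocks$blocks$event == event]
  ks <- blocks$pairs$ks[blocks$pairs$block_id %in% ids]
  ks[is.finite(ks)]
}

#' @export
print.wgd_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<wgd_pipeline_result> reference:", s$reference, "\n")
  for (sp in names(s$ploidy)) {
    cat(sprintf("  %s: multiplicity %d (%s), support %.2f\n", sp,
                s$ploidy[[sp]]$multiplicity, s$ploidy[[sp]]$interpretation,
                s$ploidy[[sp]]$support))
  }
  for (sp in names(s$peaks$ech)) {
    cat(sprintf("  ECH peak %s: mu = %.4f (R2 %.3f)\n", sp,
                s$peaks$ech[[sp]]$mu, s$peaks$ech[[sp]]$r2))
  }
  for (ev in names(s$dates)) {
    cat(sprintf("  %s dated %.2f - %.2f Mya\n", ev, s$dates[[ev]]$t_low,
                s$dates[[ev]]$t_high))
  }
  invisible(x)
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  for (cmp in names(res$blocks)) {
    write_blocks(res$blocks[[cmp]], file.path(dir, paste0("blocks.", cmp,
                                                          ".tsv")))
    write_ks(res$blocks[[cmp]], file.path(dir, paste0("ks.", cmp, ".tsv")))
  }
  write_homtable(res$table, file.path(dir, "homology_table.tsv"))
  if (!is.null(res$fractionation$losses$per_column)) {
    write_tsv_commented(res$fractionation$losses$per_column,
                        file.path(dir, "loss_rates.tsv"))
  }
  if (!is.null(res$fractionation$spectrum)) {
    write_tsv_commented(
      data.frame(length = seq_len(res$fractionation$spectrum$l_max),
                 count = as.integer(res$fractionation$spectrum$counts)),
      file.path(dir, "run_length_spectrum.tsv"))
  }
  graph <- export_alignment_graph(res$table, "circular")
  write_tsv_commented(graph, file.path(dir, "alignment_graph.tsv"))
  manifest <- data.frame(file = list.files(dir), stringsAsFactors = FALSE)
  write_tsv_commented(manifest, file.path(dir, "MANIFEST.tsv"))
  invisible(dir)
}

#' Export dotplot data for a pair of genomes
#'
#' One record per collinear gene pair: local and genome-wide rank
#' coordinates on both axes, Ks, block id, and a colour key (the event
#' window containing the pair's Ks, when windows are given).  Chromosome
#' boundary guides are attached as attributes `boundaries_a` /
#' `boundaries_b`.
#'
#' @param blocks An annotated `wgd_blocks`.
#' @param genome_a,genome_b The two genomes.
#' @param windows Optional [ks_windows()] used as the colour binning.
#' @return data.frame of dotplot records.
#' @export
export_dotplot <- function(blocks, genome_a, genome_b, windows = NULL) {
  p <- blocks$pairs
  off <- function(genome) {
    n <- genome$chromosomes$n_genes
    setNames(cumsum(c(0, n[-length(n)])), genome$chromosomes$chrom)
  }
  offa <- off(genome_a); offb <- off(genome_b)
  bl <- blocks$blocks[match(p$block_id, blocks$blocks$block_id), ]
  out <- data.frame(
    chrom_a = bl$chrom_a, rank_a = p$rank_a,
    gx = unname(offa[bl$chrom_a]) + p$rank_a,
    chrom_b = bl$chrom_b, rank_b = p$rank_b,
    gy = unname(offb[bl$chrom_b]) + p$rank_b,
    ks = p$ks, block_id = p$block_id,
    color = rep("unbinned", nrow(p)), stringsAsFactors = FALSE)
  if (!is.null(windows)) {
    for (i in seq_len(nrow(windows))) {
      sel <- !is.na(out$ks) & out$ks >= windows$low[i] &
        out$ks <= windows$high[i]
      out$color[sel] <- windows$event[i]
    }
  }
  attr(out, "boundaries_a") <- offa
  attr(out, "boundaries_b") <- offb
  out
}
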