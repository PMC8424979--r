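## synthetic_data: a three-genome evolution simulator with known ground
## truth.  The emulated history: an ancestral diploid undergoes a shared
## hexaploidy (three subgenomes); the lineage then speciates twice (V splits
## first, then T and A); the A lineage doubles again (tetraploidy), so A
## carries 3 x 2 = 6 subgenomes while V and T carry 3.  Each terminal
## subgenome is fractionated by geometric-length deletion runs, sequences
## diverge along the branches with lineage-specific rates, and homology hit
## tables are emitted from the true gene genealogy.

#' Simulation configuration
#'
#' Event ages are expressed in units of synonymous distance per site under
#' the slowest lineage's clock, halved (so a within-genome paralog pair born
#' at age `a` in a rate-1 lineage shows Ks `2a`).  Defaults emulate a
#' grape-like slow reference (`V`), a moderately faster diploid (`T`), and a
#' fast-evolving tetraploid (`A`).  The default chronology keeps the real
#' trio's relative event spacing (speciations at 0.69 and 0.59 of the
#' hexaploidy's age, the tetraploidy at 0.55) but places the hexaploidy at
#' Ks ~0.52 in the slow genome -- inside the range where the NG86 +
#' Jukes-Cantor estimator is close to unbiased, so that estimator
#' saturation does not masquerade as pipeline error in truth comparisons
#' (see the methods vignette).  Deeper, saturation-affected histories can
#' be configured explicitly.
#'
#' @param seed Integer RNG seed; every draw derives from it.
#' @param ancestral_genes Genes in the pre-hexaploidy genome (default 2000).
#' @param ancestral_chromosomes Ancestral chromosome count (default 4).
#' @param codons_per_gene CDS length in codons (default 300).
#' @param tags Species tags: slow diploid, second diploid, tetraploid.
#' @param rates Terminal-branch rate multipliers per species (slowest = 1).
#' @param ages Event ages, decreasing: `hexaploidy`, `speciation_1` (V
#'   splits), `speciation_2` (T/A split), `tetraploidy` (A only).
#' @param loss List `p` (geometric extension parameter of deletion run
#'   lengths) and `retention` (surviving fraction per terminal subgenome).
#' @param ka_ks_ratio Nonsynonymous/synonymous target ratio per branch.
#' @param ks_log_sd Log-scale standard deviation of the per-gene, per-branch
#'   rate jitter (lognormal, mean 1).
#' @param translocation_rate Fraction of surviving genes relocated to a
#'   random genomic position (default 0.02).
#' @param hit_dropout Fraction of true homolog pairs missing from the hit
#'   tables (search sensitivity noise).
#' @param hit_spurious Spurious random hit pairs, as a fraction of the true
#'   pair count.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       ancestral_genes = 2000,
                       ancestral_chromosomes = 4,
                       codons_per_gene = 300,
                       tags = c("V", "T", "A"),
                       rates = c(V = 1.0, T = 1.23, A = 1.50),
                       ages = c(hexaploidy = 0.26, speciation_1 = 0.179,
                                speciation_2 = 0.1534, tetraploidy = 0.1428),
                       loss = list(p = 0.4, retention = 0.35),
                       ka_ks_ratio = 0.2,
                       ks_log_sd = 0.25,
                       translocation_rate = 0.02,
                       hit_dropout = 0.02,
                       hit_spurious = 0.02) {
  cfg <- list(seed = seed, ancestral_genes = ancestral_genes,
              ancestral_chromosomes = ancestral_chromosomes,
              codons_per_gene = codons_per_gene, tags = tags,
              rates = setNames(as.numeric(rates), tags),
              ages = ages, loss = loss, ka_ks_ratio = ka_ks_ratio,
              ks_log_sd = ks_log_sd,
              translocation_rate = translocation_rate,
              hit_dropout = hit_dropout, hit_spurious = hit_spurious)
  stopifnot(length(tags) == 3, length(cfg$rates) == 3,
            all(diff(unname(ages)) < 0),
            loss$p > 0, loss$p <= 1,
              loss$retention > 0, loss$retention <= 1)
  if (loss$retention < 1) {
    mean_keep <- loss$retention / (loss$p * (1 - loss$retention))
    if (mean_keep < 1) {
      stop("unreachable retention target: with extension parameter p = ",
           loss$p, " the deepest reachable loss is ",
           round(1 / (1 + loss$p), 3))
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

## Apply substitutions to a codon-index vector: `ks` (`ka`) expected
## synonymous (nonsynonymous) substitutions per synonymous (nonsynonymous)
## site.  Substitution events pick a codon with probability proportional to
## its site count and move to a random sense neighbour; multiple hits are
## allowed (a downstream Jukes-Cantor correction recovers the distance).
mutate_idx <- function(idx, ks, ka = 0) {
  menu <- codon_mutation_menu()
  syn_w <- syn_sites_per_codon()[idx]
  ms <- round(sum(syn_w) * ks)
  if (ms > 0) {
    pos <- sample.int(length(idx), ms, replace = TRUE, prob = syn_w)
    for (p in pos) {
      opts <- menu$syn[[idx[p]]]
      if (length(opts)) idx[p] <- sample1(opts)
    }
  }
  if (ka > 0) {
    non_w <- 3 - syn_sites_per_codon()[idx]
    mn <- round(sum(non_w) * ka)
    if (mn > 0) {
      pos <- sample.int(length(idx), mn, replace = TRUE, prob = non_w)
      for (p in pos) {
        opts <- menu$nonsyn[[idx[p]]]
        if (length(opts)) idx[p] <- sample1(opts)
      }
    }
  }
  idx
}

#' Mutate a CDS to a target synonymous (and nonsynonymous) distance
#'
#' Applies the expected number of random synonymous / nonsynonymous
#' substitutions for the requested distances (multiple hits allowed; the
#' NG86 + Jukes-Cantor estimator recovers the target in expectation).  Stop
#' codons are never created.
#'
#' @param cds In-frame CDS string without internal stops.
#' @param target_ks Target synonymous substitutions per synonymous site
#'   (must stay below the saturation cap of 2.5).
#' @param target_ka Target nonsynonymous distance (default 0).
#' @param seed Optional seed for reproducibility of this single call.
#' @return The mutated CDS string.
#' @export
mutate_cds <- function(cds, target_ks, target_ka = 0, seed = NULL) {
  if (target_ks > 2.5 || target_ka > 2.5) {
    stop("target beyond saturation: keep targets below 2.5")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- cds_to_codon_idx(cds)
  if (anyNA(idx)) stop("non-ACGT codon in CDS")
  if (any(codon_table()$is_stop[idx])) stop("internal stop codon in CDS")
  codon_idx_to_cds(mutate_idx(idx, target_ks, target_ka))
}

## Fractionation of one chromosome: alternating keep / delete runs, both
## geometric, tuned so the expected surviving fraction equals `retention`.
## Returns list(keep = logical vector, runs = realized deletion run lengths).
fractionate_chrom <- function(n, p, retention) {
  if (retention >= 1) return(list(keep = rep(TRUE, n), runs = integer(0)))
  mean_keep <- retention / (p * (1 - retention))
  q_keep <- 1 / mean_keep
  keep <- logical(n)
  runs <- integer(0)
  i <- 1L
  state <- runif(1) < retention
  while (i <= n) {
    if (state) {
      len <- 1L + rgeom(1, q_keep)
      keep[i:min(n, i + len - 1L)] <- TRUE
    } else {
      len <- 1L + rgeom(1, p)
      real <- min(n, i + len - 1L) - i + 1L
      runs <- c(runs, real)
    }
    i <- i + len
    state <- !state
  }
  list(keep = keep, runs = runs)
}

random_ancestral_cds <- function(n_codons) {
  tab <- codon_table()
  sense <- which(!tab$is_stop)
  sample(sense, n_codons, replace = TRUE)
}

#' Simulate a three-genome bundle with known history
#'
#' See [sim_config()] for the emulated history.  Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_bundle`: `genomes` (named list of
#'   `wgd_genome` with CDS), `hits` (named list of hit data.frames, keys
#'   like `"V-V"`, `"V-A"`), `truth` (gene table, pair table with event
#'   labels and true Ks, retention, deletion run draws, expected event Ks
#'   means) and `config`.
#' @export
simulate_history <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$ancestral_genes
  nchrom <- config$ancestral_chromosomes
  tags <- config$tags
  tV <- tags[1]; tT <- tags[2]; tA <- tags[3]
  r <- config$rates
  a <- config$ages
  ## per-branch expected Ks lengths (one-sided)
  r0 <- min(r)
  rTA <- mean(c(r[[tT]], r[[tA]]))
  blen <- list(stem = r0 * (a[["hexaploidy"]] - a[["speciation_1"]]),
               V = r[[tV]] * a[["speciation_1"]],
               TA = rTA * (a[["speciation_1"]] - a[["speciation_2"]]),
               T = r[[tT]] * a[["speciation_2"]],
               A1 = r[[tA]] * (a[["speciation_2"]] - a[["tetraploidy"]]),
               A2 = r[[tA]] * a[["tetraploidy"]])

  anc_chrom <- rep(seq_len(nchrom), length.out = G)
  anc_chrom <- sort(anc_chrom)
  anc_pos <- as.integer(stats::ave(seq_len(G), anc_chrom, FUN = seq_along))

  ## presence per terminal subgenome, with realized deletion runs
  ret <- config$loss$retention
  p_loss <- config$loss$p
  presence <- list()
  run_draws <- list()
  subgenomes <- c(setNames(rep(3L, 2), c(tV, tT)), setNames(6L, tA))
  for (sp in names(subgenomes)) {
    keep <- matrix(FALSE, G, subgenomes[[sp]])
    for (k in seq_len(subgenomes[[sp]])) {
      runs_k <- integer(0)
      for (cc in seq_len(nchrom)) {
        sel <- which(anc_chrom == cc)
        fr <- fractionate_chrom(length(sel), p_loss, ret)
        keep[sel, k] <- fr$keep
        runs_k <- c(runs_k, fr$runs)
      }
      if (length(runs_k)) {
        run_draws[[length(run_draws) + 1L]] <- data.frame(
          species = sp, subgenome = k, length = runs_k,
          stringsAsFactors = FALSE)
      }
    }
    presence[[sp]] <- keep
  }
  run_draws <- if (length(run_draws)) do.call(rbind, run_draws) else
    data.frame(species = character(0), subgenome = integer(0),
               length = integer(0), stringsAsFactors = FALSE)

  ## realized branch lengths: per gene x hexaploidy copy (x tetraploidy copy)
  jit <- function(n) exp(stats::rnorm(n, -config$ks_log_sd^2 / 2,
                                      config$ks_log_sd))
  B <- list(stem = matrix(blen$stem * jit(G * 3), G, 3),
            V = matrix(blen$V * jit(G * 3), G, 3),
            TA = matrix(blen$TA * jit(G * 3), G, 3),
            T = matrix(blen$T * jit(G * 3), G, 3),
            A1 = matrix(blen$A1 * jit(G * 3), G, 3),
            A2 = array(blen$A2 * jit(G * 6), c(G, 3, 2)))

  ## sequences: evolve each gene family down the copy tree, storing only
  ## retained tips
  kr <- config$ka_ks_ratio
  cds <- list()
  cds[[tV]] <- vector("list", G * 3); dim(cds[[tV]]) <- c(G, 3)
  cds[[tT]] <- vector("list", G * 3); dim(cds[[tT]]) <- c(G, 3)
  cds[[tA]] <- vector("list", G * 6); dim(cds[[tA]]) <- c(G, 3, 2)
  pres_A <- array(presence[[tA]], c(G, 3, 2))
  for (g in seq_len(G)) {
    anc <- random_ancestral_cds(config$codons_per_gene)
    for (j in 1:3) {
      needV <- presence[[tV]][g, j]
      needT <- presence[[tT]][g, j]
      needA <- pres_A[g, j, 1] || pres_A[g, j, 2]
      if (!(needV || needT || needA)) next
      at_split1 <- mutate_idx(anc, B$stem[g, j], B$stem[g, j] * kr)
      if (needV) {
        cds[[tV]][[g, j]] <- mutate_idx(at_split1, B$V[g, j],
                                        B$V[g, j] * kr)
      }
      if (needT || needA) {
        at_split2 <- mutate_idx(at_split1, B$TA[g, j], B$TA[g, j] * kr)
        if (needT) {
          cds[[tT]][[g, j]] <- mutate_idx(at_split2, B$T[g, j],
                                          B$T[g, j] * kr)
        }
        if (needA) {
          at_ast <- mutate_idx(at_split2, B$A1[g, j], B$A1[g, j] * kr)
          for (c2 in 1:2) {
            if (pres_A[g, j, c2]) {
              cds[[tA]][[g, j, c2]] <- mutate_idx(at_ast, B$A2[g, j, c2],
                                                  B$A2[g, j, c2] * kr)
            }
          }
        }
      }
    }
  }

  ## assemble genomes: subgenome k of species sp becomes its own set of
  ## chromosomes; translocated genes are re-homed before ranks are assigned
  gene_len <- config$codons_per_gene * 3
  id_mat <- list()
  genomes <- list()
  truth_genes <- list()
  for (sp in names(subgenomes)) {
    nk <- subgenomes[[sp]]
    ids <- matrix(NA_character_, G, nk)
    keep <- presence[[sp]]
    rows <- list()
    for (k in seq_len(nk)) {
      sel <- which(keep[, k])
      if (!length(sel)) next
      ids[sel, k] <- sprintf("%s%dg%05d", sp, k, sel)
      rows[[k]] <- data.frame(
        id = ids[sel, k],
        chrom = sprintf("%s%02d", sp, (k - 1L) * nchrom + anc_chrom[sel]),
        key = as.numeric(anc_pos[sel]),
        anc_gene = sel, subgenome = k, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    ## translocations: move to a random chromosome / position
    df$translocated <- FALSE
    if (config$translocation_rate > 0 && nrow(df) > 1) {
      nmove <- round(config$translocation_rate * nrow(df))
      if (nmove > 0) {
        mv <- sample.int(nrow(df), nmove)
        df$translocated[mv] <- TRUE
        df$chrom[mv] <- sample(unique(df$chrom), nmove, replace = TRUE)
        df$key[mv] <- runif(nmove, 0, max(anc_pos) + 1)
      }
    }
    df <- df[order(df$chrom, df$key), ]
    pos_in_chrom <- as.integer(stats::ave(seq_len(nrow(df)), df$chrom,
                                          FUN = seq_along))
    df$start <- (pos_in_chrom - 1L) * 2L * gene_len + 1L
    df$end <- df$start + gene_len - 1L
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    seqs <- if (sp == tA) {
      ## presence column k maps column-major onto (hexaploidy copy j,
      ## tetraploidy copy c): j = ((k-1) %% 3) + 1, c = ((k-1) %/% 3) + 1
      setNames(vapply(seq_len(nrow(df)), function(i) {
        k <- df$subgenome[i]
        codon_idx_to_cds(cds[[sp]][[df$anc_gene[i], ((k - 1L) %% 3L) + 1L,
                                    ((k - 1L) %/% 3L) + 1L]])
      }, character(1)), df$id)
    } else {
      setNames(vapply(seq_len(nrow(df)), function(i)
        codon_idx_to_cds(cds[[sp]][[df$anc_gene[i], df$subgenome[i]]]),
        character(1)), df$id)
    }
    genomes[[sp]] <- new_genome(df[, c("id", "chrom", "start", "end",
                                       "strand")], sp, cds = seqs)
    df$species <- sp
    truth_genes[[sp]] <- df[, c("species", "id", "chrom", "subgenome",
                                "anc_gene", "translocated")]
    id_mat[[sp]] <- ids
  }

  ## truth pairs + hit tables
  truth <- sim_truth_pairs(config, id_mat, B, tags)
  hits <- sim_hits(config, truth$pairs, genomes)

  structure(list(
    genomes = genomes, hits = hits,
    truth = list(genes = do.call(rbind, truth_genes),
                 pairs = truth$pairs,
                 presence = presence,
                 retention = data.frame(
                   species = rep(names(subgenomes), subgenomes),
                   subgenome = unlist(lapply(subgenomes, seq_len),
                                      use.names = FALSE),
                   retention = unlist(lapply(presence, colMeans),
                                      use.names = FALSE)),
                 run_draws = run_draws,
                 event_ks = sim_event_ks(blen, tags),
                 ages = a),
    config = config), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle>",
      paste(vapply(x$genomes, function(g) paste0(g$species, ":",
                                                 nrow(g$genes)),
                   character(1)), collapse = " "),
      "|", nrow(x$truth$pairs), "true homolog pairs\n")
  invisible(x)
}

## Expected raw Ks peak positions per comparison and event (no jitter).
sim_event_ks <- function(blen, tags) {
  tV <- tags[1]; tT <- tags[2]; tA <- tags[3]
  toV <- blen$stem + blen$V
  toT <- blen$stem + blen$TA + blen$T
  toA <- blen$stem + blen$TA + blen$A1 + blen$A2
  rbind(
    data.frame(comparison = paste0(tV, "-", tV), event = "ECH",
               mean_ks = 2 * toV),
    data.frame(comparison = paste0(tT, "-", tT), event = "ECH",
               mean_ks = 2 * toT),
    data.frame(comparison = paste0(tA, "-", tA), event = "ECH",
               mean_ks = 2 * toA),
    data.frame(comparison = paste0(tA, "-", tA), event = "AST",
               mean_ks = 2 * blen$A2),
    data.frame(comparison = paste0(tV, "-", tT),
               event = paste0("speciation:", tV, "-", tT),
               mean_ks = blen$V + blen$TA + blen$T),
    data.frame(comparison = paste0(tV, "-", tT), event = "ECH",
               mean_ks = toV + toT),
    data.frame(comparison = paste0(tV, "-", tA),
               event = paste0("speciation:", tV, "-", tA),
               mean_ks = blen$V + blen$TA + blen$A1 + blen$A2),
    data.frame(comparison = paste0(tV, "-", tA), event = "ECH",
               mean_ks = toV + toA),
    data.frame(comparison = paste0(tT, "-", tA),
               event = paste0("speciation:", tT, "-", tA),
               mean_ks = blen$T + blen$A1 + blen$A2),
    data.frame(comparison = paste0(tT, "-", tA), event = "ECH",
               mean_ks = toT + toA))
}

## Enumerate all true homolog pairs with their event label and realized Ks.
sim_truth_pairs <- function(config, id_mat, B, tags) {
  tV <- tags[1]; tT <- tags[2]; tA <- tags[3]
  G <- config$ancestral_genes
  ## cumulative realized lengths from the hexaploidy down to each tip
  cumV <- B$stem + B$V
  cumT <- B$stem + B$TA + B$T
  cumA <- array(0, c(G, 3, 2))
  for (c2 in 1:2) cumA[, , c2] <- B$stem + B$TA + B$A1 + B$A2[, , c2]
  sinceS1_V <- B$V
  sinceS1_T <- B$TA + B$T
  sinceS1_A <- array(0, c(G, 3, 2))
  for (c2 in 1:2) sinceS1_A[, , c2] <- B$TA + B$A1 + B$A2[, , c2]
  sinceS2_T <- B$T
  sinceS2_A <- array(0, c(G, 3, 2))
  for (c2 in 1:2) sinceS2_A[, , c2] <- B$A1 + B$A2[, , c2]

  idV <- id_mat[[tV]]; idT <- id_mat[[tT]]
  idA <- array(id_mat[[tA]], c(G, 3, 2))
  out <- list()
  add <- function(comparison, ga, gb, event, ks) {
    ok <- !is.na(ga) & !is.na(gb)
    if (!any(ok)) return()
    out[[length(out) + 1L]] <<- data.frame(
      comparison = comparison, gene_a = ga[ok], gene_b = gb[ok],
      event = event, true_ks = ks[ok], stringsAsFactors = FALSE)
  }
  Acols <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 1), c(3, 2))
  ## within-genome paralogs
  for (j in 1:2) for (j2 in (j + 1):3) {
    add(paste0(tV, "-", tV), idV[, j], idV[, j2], "ECH",
        cumV[, j] + cumV[, j2])
    add(paste0(tT, "-", tT), idT[, j], idT[, j2], "ECH",
        cumT[, j] + cumT[, j2])
  }
  for (i in seq_along(Acols)) {
    for (i2 in seq_along(Acols)) {
      if (i2 <= i) next
      j <- Acols[[i]][1]; c1 <- Acols[[i]][2]
      j2 <- Acols[[i2]][1]; c2 <- Acols[[i2]][2]
      if (j == j2) {
        add(paste0(tA, "-", tA), idA[, j, c1], idA[, j2, c2], "AST",
            B$A2[, j, c1] + B$A2[, j2, c2])
      } else {
        add(paste0(tA, "-", tA), idA[, j, c1], idA[, j2, c2], "ECH",
            cumA[, j, c1] + cumA[, j2, c2])
      }
    }
  }
  ## cross-genome: same hexaploidy copy = ortholog, different = outparalog
  for (j in 1:3) for (j2 in 1:3) {
    evVT <- if (j == j2) paste0("speciation:", tV, "-", tT) else "ECH"
    ksVT <- if (j == j2) sinceS1_V[, j] + sinceS1_T[, j2] else
      cumV[, j] + cumT[, j2]
    add(paste0(tV, "-", tT), idV[, j], idT[, j2], evVT, ksVT)
    for (c2 in 1:2) {
      evVA <- if (j == j2) paste0("speciation:", tV, "-", tA) else "ECH"
      ksVA <- if (j == j2) sinceS1_V[, j] + sinceS1_A[, j2, c2] else
        cumV[, j] + cumA[, j2, c2]
      add(paste0(tV, "-", tA), idV[, j], idA[, j2, c2], evVA, ksVA)
      evTA <- if (j == j2) paste0("speciation:", tT, "-", tA) else "ECH"
      ksTA <- if (j == j2) sinceS2_T[, j] + sinceS2_A[, j2, c2] else
        cumT[, j] + cumA[, j2, c2]
      add(paste0(tT, "-", tA), idT[, j], idA[, j2, c2], evTA, ksTA)
    }
  }
  list(pairs = do.call(rbind, out))
}

## Hit tables from truth pairs: bitscore/identity decay with true Ks, both
## directions emitted, with dropout and spurious-pair noise.
sim_hits <- function(config, pairs, genomes) {
  hits <- list()
  for (cmp in unique(pairs$comparison)) {
    pp <- pairs[pairs$comparison == cmp, ]
    if (config$hit_dropout > 0) {
      keep <- runif(nrow(pp)) >= config$hit_dropout
      pp <- pp[keep, , drop = FALSE]
    }
    sp <- strsplit(cmp, "-")[[1]]
    n_spur <- round(config$hit_spurious * nrow(pp))
    bit <- pmax(55, round(600 * exp(-pp$true_ks / 1.5)))
    len <- config$codons_per_gene * 3
    h <- data.frame(
      query = pp$gene_a, subject = pp$gene_b,
      pident = round(100 * exp(-pp$true_ks / 3), 1),
      length = len, mismatch = round(len * (1 - exp(-pp$true_ks / 3))),
      gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = signif(10^(-pmin(bit / 5, 180)), 3), bitscore = bit,
      stringsAsFactors = FALSE)
    if (n_spur > 0) {
      ga <- sample(genomes[[sp[1]]]$genes$id, n_spur, replace = TRUE)
      gb <- sample(genomes[[sp[2]]]$genes$id, n_spur, replace = TRUE)
      ok <- ga != gb
      if (any(ok)) {
        h <- rbind(h, data.frame(
          query = ga[ok], subject = gb[ok], pident = 30, length = len,
          mismatch = round(len * 0.7), gapopen = 0L, qstart = 1L,
          qend = len, sstart = 1L, send = len, evalue = 1e-6,
          bitscore = 55, stringsAsFactors = FALSE))
      }
    }
    ## emit both directions, as an all-vs-all search would
    rev_ <- h
    names(rev_)[c(1, 2, 7, 8, 9, 10)] <-
      c("subject", "query", "sstart", "send", "qstart", "qend")
    h <- rbind(h, rev_[, names(h)])
    hits[[cmp]] <- h
  }
  hits
}

#' Machine-readable ground truth of a simulated bundle
#'
#' @param bundle A [simulate_history()] result.
#' @return List: `event_ks` (expected raw peak mean per comparison/event),
#'   `depth_mode` (expected modal ortholog depth of the tetraploid over a
#'   diploid reference), `retention` (per terminal subgenome), `geom_p`
#'   (configured extension parameter), `run_spectrum_fit` (geometric fit of
#'   the realized deletion run draws), `adjusted_ratio` (expected
#'   rate-adjusted tetraploidy/hexaploidy peak ratio, the quantity the
#'   dating stage consumes) and `age_ratio` (configured
#'   tetraploidy/hexaploidy age ratio).
#' @export
truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "sim_bundle"))
  ek <- bundle$truth$event_ks
  tags <- bundle$config$tags
  echs <- setNames(ek$mean_ks[ek$event == "ECH" &
                                ek$comparison %in% paste0(tags, "-", tags)],
                   tags)
  ast <- ek$mean_ks[ek$event == "AST"][1]
  lambdaA <- echs[[tags[3]]] / min(echs)
  fit <- fit_geometric(bundle$truth$run_draws$length)
  ## "placeable" retention: genes present AND still at their ancestral
  ## location -- a translocated gene leaves a dot in the collinear table
  ## exactly like a lost one, so this is the quantity a collinearity
  ## pipeline can recover
  genes <- bundle$truth$genes
  placeable <- bundle$truth$retention
  placeable$placeable_retention <- NA_real_
  for (i in seq_len(nrow(placeable))) {
    sp <- placeable$species[i]; k <- placeable$subgenome[i]
    sel <- genes$species == sp & genes$subgenome == k & !genes$translocated
    placeable$placeable_retention[i] <-
      sum(sel) / bundle$config$ancestral_genes
  }
  list(event_ks = ek,
       depth_mode = 2L,
       retention = placeable,
       geom_p = bundle$config$loss$p,
       run_spectrum_fit = fit,
       adjusted_ratio = unname((ast / lambdaA) / min(echs)),
       age_ratio = unname(bundle$config$ages[["tetraploidy"]] /
                            bundle$config$ages[["hexaploidy"]]))
}

#' Ideal-recovery homology columns for a simulated bundle
#'
#' For every reference gene (in reference genome order) the ground-truth
#' content of the target species' sibling ortholog columns: a cell is
#' filled iff the reference gene sits at its ancestral location, and the
#' target copy in the corresponding subgenome survives at its ancestral
#' location (translocated genes leave dots, as in the pipeline's table).
#' This is the best any collinearity-based table builder could do, and the
#' comparator for retention and run-length recovery tests.
#'
#' @param bundle A `sim_bundle`.
#' @param reference,target Species tags (default: first and third).
#' @return data.frame: `row_gene`, `chrom`, and one column per target
#'   sibling (`sib1`, `sib2` for the tetraploid; `sib1` for a diploid),
#'   holding gene ids or `"."`.
#' @export
truth_table_columns <- function(bundle,
                                reference = bundle$config$tags[1],
                                target = bundle$config$tags[3]) {
  genes <- bundle$truth$genes
  refg <- bundle$genomes[[reference]]$genes
  info <- genes[match(refg$id, genes$id), ]
  tg <- genes[genes$species == target, ]
  n_sib <- if (target == bundle$config$tags[3]) 2L else 1L
  out <- data.frame(row_gene = refg$id, chrom = refg$chrom,
                    stringsAsFactors = FALSE)
  for (c2 in seq_len(n_sib)) {
    ## reference subgenome j pairs with target subgenome (c2 - 1) * 3 + j
    tsub <- (c2 - 1L) * 3L + info$subgenome
    key <- paste(tsub, info$anc_gene)
    tkey <- paste(tg$subgenome, tg$anc_gene)
    hit <- match(key, tkey)
    cell <- ifelse(!info$translocated & !is.na(hit) & !tg$translocated[hit],
                   tg$id[hit], ".")
    out[[paste0("sib", c2)]] <- cell
  }
  out
}

#' Write a simulated bundle as the file formats the pipeline consumes
#'
#' Per species: `<tag>.gff3` (gene features), `<tag>.cds.fasta`; per genome
#' pair: `<a>-<b>.hits.tsv` (12-column tabular); plus `truth.json`.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in bundle$genomes) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$genes$chrom,
      ranges = IRanges::IRanges(g$genes$start, g$genes$end),
      strand = ifelse(g$genes$strand %in% c("+", "-"), g$genes$strand, "*"))
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- g$genes$id
    rtracklayer::export(gr, file.path(dir, paste0(g$species, ".gff3")),
                        format = "gff3")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(g$cds)),
      file.path(dir, paste0(g$species, ".cds.fasta")))
  }
  for (cmp in names(bundle$hits)) {
    write.table(bundle$hits[[cmp]], file.path(dir, paste0(cmp, ".hits.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  tr <- truth_report(bundle)
  tr$run_spectrum_fit <- unclass(tr$run_spectrum_fit)[c("p", "r2")]
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
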