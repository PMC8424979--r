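test_that("bundles are deterministic given the seed", {
  cfg <- sim_config(seed = 77, ancestral_genes = 120,
                    ancestral_chromosomes = 2, codons_per_gene = 60)
  b1 <- simulate_history(cfg)
  b2 <- simulate_history(cfg)
  expect_identical(b1$genomes$A$genes, b2$genomes$A$genes)
  expect_identical(b1$genomes$V$cds, b2$genomes$V$cds)
  expect_identical(b1$truth$pairs, b2$truth$pairs)
  expect_identical(b1$hits, b2$hits)
})

test_that("gene counts follow the expected retention arithmetic", {
  b <- sim_small()  # 500 ancestral genes, retention 0.35
  expected_tetra <- 500 * 3 * (2 * 0.35)
  expect_lt(abs(nrow(b$genomes$A$genes) - expected_tetra) / expected_tetra,
            0.1)
  expected_diploid <- 500 * 3 * 0.35
  expect_lt(abs(nrow(b$genomes$V$genes) - expected_diploid) /
              expected_diploid, 0.1)
})

test_that("full retention leaves no gaps and no deletion runs", {
  cfg <- sim_config(seed = 5, ancestral_genes = 100,
                    ancestral_chromosomes = 2, codons_per_gene = 60,
                    loss = list(p = 0.4, retention = 1),
                    translocation_rate = 0)
  b <- simulate_history(cfg)
  expect_true(all(unlist(b$truth$presence)))
  expect_equal(nrow(b$truth$run_draws), 0)
  expect_equal(nrow(b$genomes$A$genes), 600)
})

test_that("unreachable retention targets are rejected before generation", {
  expect_error(sim_config(loss = list(p = 0.1, retention = 0.05)),
               "unreachable retention")
})

test_that("mutate_cds hits its target distance and guards saturation", {
  set.seed(61)
  cds <- random_cds(500)
  expect_identical(mutate_cds(cds, 0), cds)
  mut <- mutate_cds(cds, 0.2, 0.02, seed = 8)
  r <- ng86(codon_align(cds, mut))
  expect_true(r$ks >= 0.15 && r$ks <= 0.25)
  expect_true(r$ka >= 0.005 && r$ka <= 0.04)
  expect_error(mutate_cds(cds, 5), "beyond saturation")
})

test_that("every gene traces to one ancestral gene and subgenomes partition", {
  b <- sim_small()
  g <- b$truth$genes
  expect_equal(anyDuplicated(g$id), 0L)
  expect_true(all(g$anc_gene >= 1 & g$anc_gene <= 500))
  ## subgenome labels partition each genome's genes
  for (sp in names(b$genomes)) {
    ids <- b$genomes[[sp]]$genes$id
    expect_setequal(ids, g$id[g$species == sp])
  }
  ## a (subgenome, ancestral gene) slot is occupied at most once
  key <- paste(g$species, g$subgenome, g$anc_gene)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("truth pairs carry consistent event labels and additive Ks", {
  b <- sim_small()
  tp <- b$truth$pairs
  ek <- b$truth$event_ks
  for (cmp in c("V-V", "A-A", "V-A")) {
    for (ev in unique(tp$event[tp$comparison == cmp])) {
      sel <- tp$comparison == cmp & tp$event == ev
      expected <- ek$mean_ks[ek$comparison == cmp & ek$event == ev]
      ## lognormal jitter has mean 1, so pair means sit near the expectation
      expect_lt(abs(mean(tp$true_ks[sel]) - expected) / expected, 0.1)
    }
  }
  ## AST pairs join the two tetraploid subgenome copies of one hexaploidy copy
  ast <- tp[tp$comparison == "A-A" & tp$event == "AST", ]
  g <- b$truth$genes
  ja <- g$subgenome[match(ast$gene_a, g$id)]
  jb <- g$subgenome[match(ast$gene_b, g$id)]
  expect_true(all((ja - 1) %% 3 == (jb - 1) %% 3))
  expect_true(all(ja != jb))
})

test_that("the truth report's run-length draws refit the configured parameter", {
  b <- sim_small()
  tr <- truth_report(b)
  expect_equal(tr$depth_mode, 2L)
  expect_gt(nrow(b$truth$run_draws), 500)
  expect_lt(abs(tr$run_spectrum_fit$p - 0.4), 0.02)
  ## truth retention does its own accounting
  expect_equal(tr$retention$retention,
               unname(unlist(lapply(b$truth$presence, colMeans))))
  expect_true(all(tr$retention$placeable_retention <=
                    tr$retention$retention))
})

test_that("bundles round-trip through the on-disk formats", {
  cfg <- sim_config(seed = 9, ancestral_genes = 80,
                    ancestral_chromosomes = 2, codons_per_gene = 60)
  b <- simulate_history(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  v <- load_genome(file.path(dir, "V.gff3"), file.path(dir, "V.cds.fasta"),
                   species_tag = "V")
  expect_equal(v$genes[, c("id", "chrom", "start", "end", "rank")],
               b$genomes$V$genes[, c("id", "chrom", "start", "end", "rank")])
  expect_identical(v$cds[names(b$genomes$V$cds)], b$genomes$V$cds)
  h <- load_hits(file.path(dir, "V-A.hits.tsv"))
  expect_true(all(c("query", "subject", "evalue", "bitscore") %in% names(h)))
  expect_gt(nrow(h), 0)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
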