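test_that("the trio fixture builds the 12-column table with one sibling loss", {
  fx <- trio_fixture()
  spec <- table_spec("V", c("T", "A"), c(1, 2))
  expect_equal(length(spec$columns), 12)
  tab <- build_table(spec, fx$V, fx$blocks)
  expect_equal(dim(tab$table), c(18L, 12L))
  rows_v1 <- which(tab$ref_genes$chrom == "v1")
  m <- tab$table[rows_v1, ]
  ## reference paralog columns carry the two hexaploidy siblings
  expect_setequal(as.vector(m[, c("V-p1", "V-p2")]),
                  c(paste0("P", 1:6), paste0("Q", 1:6)))
  ## diploid orthologs: T for the v1 genes, U/W for their paralogs
  expect_equal(m[, "T-o"], paste0("T", 1:6))
  expect_setequal(as.vector(m[, c("T-p1", "T-p2")]),
                  c(paste0("U", 1:6), paste0("W", 1:6)))
  ## tetraploid sibling columns: X and Y in the two slots, Y4 missing
  sib <- as.vector(m[, c("A-o1", "A-o2")])
  expect_setequal(sib, c(paste0("X", 1:6), paste0("Y", c(1:3, 5:6)), "."))
  expect_equal(sum(m[, c("A-o1", "A-o2")] == "."), 1)
  ## each row holds one X and one Y (or the dot)
  for (i in 1:6) {
    expect_setequal(substr(m[i, c("A-o1", "A-o2")], 1, 1),
                    if (i == 4) c("X", ".") else c("X", "Y"))
  }
  ## AST-linked sibling genes land in different columns
  expect_false(any(substr(m[, "A-o1"], 1, 1) == substr(m[, "A-o2"], 1, 1)))
})

test_that("a target gene fills at most one cell per column and totals conserve", {
  fx <- trio_fixture()
  tab <- build_table(table_spec("V", c("T", "A"), c(1, 2)), fx$V, fx$blocks)
  for (col in colnames(tab$table)) {
    vals <- tab$table[, col]
    vals <- vals[vals != "."]
    expect_equal(anyDuplicated(vals), 0L, info = col)
  }
  ## conservation: every placed cell of a species' columns is one of that
  ## species' block genes (one cell per reference-column anchor, so a gene
  ## may recur across -- never within -- columns)
  block_genes <- unique(unlist(lapply(fx$blocks, function(b)
    if (b$genome_b == "A") c(b$pairs$gene_b, if (b$genome_a == "A")
      b$pairs$gene_a) else NULL)))
  for (col in grep("^A-", colnames(tab$table), value = TRUE)) {
    vals <- tab$table[, col]
    expect_true(all(vals[vals != "."] %in% block_genes), info = col)
  }
})

test_that("empty block input yields an all-dot table except the reference column", {
  fx <- trio_fixture()
  empty <- lapply(fx$blocks, function(b) {
    b$blocks <- b$blocks[0, ]; b$pairs <- b$pairs[0, ]; b
  })
  tab <- build_table(table_spec("V", c("T", "A"), c(1, 2)), fx$V, empty)
  expect_equal(tab$table[, "V"], fx$V$genes$id)
  expect_true(all(tab$table[, -1] == "."))
})

test_that("column stats report retention and sibling co-retention", {
  fx <- trio_fixture()
  tab <- build_table(table_spec("V", c("T", "A"), c(1, 2)), fx$V, fx$blocks)
  st <- column_stats(tab)
  expect_equal(st$stats$retention[st$stats$column == "V"], 1)
  expect_equal(st$stats$filled[st$stats$column == "T-o"], 18)
  ## sibling ortholog columns: 35 of 36 anchor cells filled (one loss)
  ao <- st$stats$filled[st$stats$column %in% c("A-o1", "A-o2")]
  expect_equal(sum(ao), 35)
  v1 <- tab$table[tab$ref_genes$chrom == "v1", c("A-o1", "A-o2")]
  expect_equal(sum(v1 != "."), 11)
  expect_true(all(st$co_retention >= 0 & st$co_retention <= 1))
})

test_that("alignment graph ticks equal the filled cells, on both layouts", {
  fx <- trio_fixture()
  tab <- build_table(table_spec("V", c("T", "A"), c(1, 2)), fx$V, fx$blocks)
  st <- column_stats(tab)$stats
  chroms <- do.call(rbind, lapply(list(fx$V, fx$T, fx$A), function(g)
    g$genes[, c("id", "chrom")]))
  lookup <- setNames(chroms$chrom, chroms$id)
  for (layout in c("circular", "linear")) {
    gr <- export_alignment_graph(tab, layout, gene_chrom = lookup)
    ticks <- table(factor(gr$column, levels = st$column))
    expect_equal(as.integer(ticks), st$filled)
    expect_false(anyNA(gr$cell_chrom))
  }
})

test_that("the second-reference table anchors genes the first cannot", {
  ## a T gene with A orthologs but no V counterpart: only the T-referenced
  ## table can place its tetraploid pair
  fx <- trio_fixture()
  T2 <- toy_genome(list(t1 = c(paste0("T", 1:6), "Textra")), "T")
  A2 <- toy_genome(list(a1x = c(paste0("X", 1:6), "Xextra"),
                        a1y = c(paste0("Y", 1:6), "Yextra")), "A")
  ta <- detect_blocks(rbind(
    diag_hits(c(paste0("T", 1:6), "Textra"), c(paste0("X", 1:6), "Xextra")),
    diag_hits(c(paste0("T", 1:6), "Textra"), c(paste0("Y", 1:6), "Yextra"))),
    T2, A2)
  ta$blocks$event <- "speciation:T-A"
  aa <- detect_blocks(
    diag_hits(c(paste0("X", 1:6), "Xextra"), c(paste0("Y", 1:6), "Yextra")),
    A2, A2)
  aa$blocks$event <- "AST"
  tabT <- build_table(table_spec("T", "A", 2), T2, list(ta, aa))
  rowx <- which(tabT$table[, "T"] == "Textra")
  expect_setequal(tabT$table[rowx, c("A-o1", "A-o2")], c("Xextra", "Yextra"))
  ## the V-referenced fixture table never mentions these genes
  tabV <- build_table(table_spec("V", c("T", "A"), c(1, 2)), fx$V, fx$blocks)
  expect_false(any(c("Xextra", "Yextra") %in% tabV$table))
})
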