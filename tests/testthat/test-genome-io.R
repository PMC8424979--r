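test_that("gene ranks are dense, 0-based, and order-invariant", {
  df <- data.frame(id = c("g1", "g2", "g3"), chrom = c("c1", "c1", "c2"),
                   start = c(100, 300, 50), end = c(200, 400, 80))
  g <- new_genome(df, "X")
  expect_equal(g$genes$rank[match(c("g1", "g2", "g3"), g$genes$id)],
               c(0L, 1L, 0L))
  ## reversed input order gives identical ranks
  g2 <- new_genome(df[3:1, ], "X")
  expect_equal(g$genes, g2$genes)
  ## rank density per chromosome
  for (ch in unique(g$genes$chrom)) {
    r <- sort(g$genes$rank[g$genes$chrom == ch])
    expect_equal(r, seq_along(r) - 1L)
  }
})

test_that("duplicate gene ids and inverted coordinates are hard errors", {
  df <- data.frame(id = c("g1", "g1"), chrom = "c1",
                   start = c(1, 10), end = c(5, 20))
  expect_error(new_genome(df, "X"), "duplicate gene id")
  expect_error(new_genome(data.frame(id = "g1", chrom = "c1",
                                     start = 10, end = 5), "X"),
               "start > end")
})

test_that("gene-bed and GFF3 loaders agree and round-trip through writers", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  writeLines(c("g2\tc1\t300\t400", "g1\tc1\t100\t200", "g3\tc2\t50\t80"),
             bed)
  g <- load_genome(bed, species_tag = "X")
  expect_equal(nrow(g$genes), 3)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "c1\ttest\tgene\t100\t200\t.\t+\t.\tID=g1",
               "c1\ttest\tgene\t300\t400\t.\t-\t.\tID=g2",
               "c2\ttest\tgene\t50\t80\t.\t+\t.\tID=g3"), gff)
  g2 <- load_genome(gff, species_tag = "X")
  expect_equal(g2$genes[, c("id", "chrom", "start", "end", "rank")],
               g$genes[, c("id", "chrom", "start", "end", "rank")])
  out <- file.path(dir, "genes.tsv")
  write_genome(g, out)
  g3 <- load_genome(out, species_tag = "X")
  expect_equal(g3$genes[, c("id", "chrom", "start", "end", "rank")],
               g$genes[, c("id", "chrom", "start", "end", "rank")])
})

test_that("CDS trimming policy trims overhangs and flags internal stops", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  writeLines(c("g1\tc1\t1\t100", "g2\tc1\t200\t300"), bed)
  fa <- file.path(dir, "cds.fa")
  writeLines(c(">g1", paste0(strrep("ATG", 5), "AT"),   # 17 nt -> trim 2
               ">g2", paste0("ATG", "TAA", "ATG")), fa) # internal stop
  g <- suppressMessages(load_genome(bed, fa, species_tag = "X"))
  expect_equal(nchar(g$cds[["g1"]]), 15)
  expect_true(g$genes$ks_valid[g$genes$id == "g1"])
  expect_false(g$genes$ks_valid[g$genes$id == "g2"])
})

test_that("hit filtering honours the E-value cutoff, top-n and idempotence", {
  set.seed(1)
  hits <- data.frame(
    query = c("a", "a", "b", rep("q", 7)),
    subject = c("b", "a", "x", paste0("s", 1:7)),
    evalue = c(1e-6, 1e-30, 1e-4, rep(1e-10, 7)),
    bitscore = c(100, 500, 90, c(50, 80, 20, 95, 60, 70, 10)),
    stringsAsFactors = FALSE)
  f <- filter_hits(hits, evalue_cutoff = 1e-5, top_n = 5)
  ## (a,b) kept at 1e-6; self-hit (a,a) removed; (b,x) above cutoff removed
  expect_true(any(f$query == "a" & f$subject == "b"))
  expect_false(any(f$query == f$subject))
  expect_false(any(f$evalue > 1e-5))
  ## top-5 of q's 7 subjects, by bitscore (sort-and-slice oracle)
  qs <- f[f$query == "q", ]
  expect_equal(nrow(qs), 5)
  expect_setequal(qs$bitscore, sort(c(50, 80, 20, 95, 60, 70, 10),
                                    decreasing = TRUE)[1:5])
  expect_equal(filter_hits(f, evalue_cutoff = 1e-5, top_n = 5), f)
  ## round-trip through the writer/reader pair
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hits.tsv")
  write_hits(f, path)
  f2 <- load_hits(path, evalue_cutoff = 1e-5, top_n = 5)
  expect_equal(f2[order(f2$query, f2$subject), c("query", "subject")],
               f[order(f$query, f$subject), c("query", "subject")],
               ignore_attr = TRUE)
})

test_that("malformed hit rows are skipped with a warning", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  writeLines(c("a\tb\t1e-10\t100", "x\ty\tnot_a_number\t50"), path)
  expect_warning(h <- load_hits(path), "malformed")
  expect_equal(nrow(h), 1)
})
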