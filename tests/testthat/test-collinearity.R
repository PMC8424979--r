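test_that("perfect diagonals chain into a single block of the right sign", {
  ga <- toy_genome(list(c1 = paste0("a", 0:4)), "X")
  gb <- toy_genome(list(d1 = paste0("b", 0:4)), "Y")
  fwd <- detect_blocks(diag_hits(paste0("a", 0:4), paste0("b", 0:4)),
                       ga, gb)
  expect_equal(nrow(fwd$blocks), 1)
  expect_equal(fwd$blocks$n_pairs, 5)
  expect_equal(fwd$blocks$orientation, "+")
  rev_ <- detect_blocks(diag_hits(paste0("a", 0:4), paste0("b", 4:0)),
                        ga, gb)
  expect_equal(rev_$blocks$orientation, "-")
  expect_equal(rev_$blocks$n_pairs, 5)
})

test_that("the gap rule splits distant clusters into separate blocks", {
  ## 4 hits at ranks 0-3 and 4 at ranks 60-63: no single chain can bridge
  ## the 56-gene gap under max_gap = 50 (confirmed by brute-force
  ## enumeration below)
  ids_a <- paste0("a", c(0:3, 60:63))
  ids_b <- paste0("b", c(0:3, 60:63))
  ga <- toy_genome(list(c1 = paste0("a", 0:63)), "X")
  gb <- toy_genome(list(d1 = paste0("b", 0:63)), "Y")
  hits <- diag_hits(ids_a, ids_b)
  bl <- detect_blocks(hits, ga, gb, max_gap = 50, min_pairs = 4)
  expect_equal(nrow(bl$blocks), 2)
  expect_equal(sort(bl$blocks$n_pairs), c(4, 4))
  expect_equal(brute_max_chain(c(0:3, 60:63), c(0:3, 60:63), 50), 4)
})

test_that("greedy chaining matches exhaustive enumeration on random instances", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(5:12, 1)
    ra <- sample(0:30, n)
    rb <- sample(0:30, n)
    gap <- sample(c(3, 10, 50), 1)
    ga <- toy_genome(list(c1 = paste0("a", 0:30)), "X")
    gb <- toy_genome(list(d1 = paste0("b", 0:30)), "Y")
    hits <- data.frame(query = paste0("a", ra), subject = paste0("b", rb),
                       evalue = 1e-20, bitscore = 100)
    bl <- detect_blocks(hits, ga, gb, max_gap = gap, min_pairs = 1)
    expect_equal(max(bl$blocks$n_pairs), brute_max_chain(ra, rb, gap),
                 info = paste("seed", seed))
  }
})

test_that("detection is symmetric and deterministic", {
  set.seed(7)
  ra <- sample(0:40, 12); rb <- sample(0:40, 12)
  ga <- toy_genome(list(c1 = paste0("a", 0:40)), "X")
  gb <- toy_genome(list(d1 = paste0("b", 0:40)), "Y")
  h_ab <- data.frame(query = paste0("a", ra), subject = paste0("b", rb),
                     evalue = 1e-20, bitscore = 100)
  h_ba <- data.frame(query = paste0("b", rb), subject = paste0("a", ra),
                     evalue = 1e-20, bitscore = 100)
  ab <- detect_blocks(h_ab, ga, gb, min_pairs = 2)
  ba <- detect_blocks(h_ba, gb, ga, min_pairs = 2)
  key <- function(x, swap = FALSE) {
    p <- if (swap) paste(x$pairs$gene_b, x$pairs$gene_a) else
      paste(x$pairs$gene_a, x$pairs$gene_b)
    sort(p)
  }
  expect_equal(key(ab), key(ba, swap = TRUE))
  ab2 <- detect_blocks(h_ab, ga, gb, min_pairs = 2)
  expect_identical(ab, ab2)
})

test_that("self-comparison drops the trivial diagonal and mirror duplicates", {
  ids <- paste0("g", 0:9)
  g <- toy_genome(list(c1 = ids[1:5], c2 = ids[6:10]), "X")
  ## paralogous run c1 vs c2, reported in both directions plus self-hits
  h <- rbind(diag_hits(ids[1:5], ids[6:10]),
             diag_hits(ids[6:10], ids[1:5]),
             data.frame(query = ids, subject = ids, evalue = 1e-50,
                        bitscore = 400))
  bl <- detect_blocks(h, g, g, min_pairs = 4)
  expect_equal(nrow(bl$blocks), 1)
  expect_equal(bl$blocks$n_pairs, 5)
  expect_true(bl$blocks$chrom_a < bl$blocks$chrom_b)
})

test_that("block tallies and means follow the threshold contract", {
  b1 <- list(blocks = data.frame(n_pairs = 10))
  s <- summarize_blocks(b1$blocks, thresholds = c(4, 10, 20))
  expect_equal(s$n_blocks, c(1, 1, 0))
  expect_equal(s$n_pairs, c(10, 10, 0))
  expect_equal(s$mean_pairs_per_block, c(10, 10, NA))
})

test_that("block output survives a write/re-read of the pair rows", {
  ga <- toy_genome(list(c1 = paste0("a", 0:4)), "X")
  gb <- toy_genome(list(d1 = paste0("b", 0:4)), "Y")
  bl <- detect_blocks(diag_hits(paste0("a", 0:4), paste0("b", 0:4)), ga, gb)
  path <- file.path(withr::local_tempdir(), "blocks.tsv")
  write_blocks(bl, path)
  reread <- read.delim(path, header = FALSE, comment.char = "#")
  expect_equal(nrow(reread), 5)
  expect_equal(as.character(reread$V2), paste0("a", 0:4))
})
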