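test_that("NG86 site counting and JC correction match hand-computed values", {
  ## identical Phe codons: 1/3 synonymous site each, no differences
  a <- strrep("TTT", 10)
  r0 <- ng86(codon_align(a, a))
  expect_equal(r0$s_sites, 10 / 3)
  expect_equal(r0$n_sites, 30 - 10 / 3)
  expect_equal(r0$ks, 0)
  expect_equal(r0$ka, 0)
  ## one synonymous third-position change: ps = 0.3, Ks = -0.75 log(0.6)
  b <- paste0(strrep("TTT", 9), "TTC")
  r1 <- ng86(codon_align(a, b))
  expect_equal(r1$sd, 1)
  expect_equal(r1$ks, -0.75 * log(0.6))
  expect_equal(r1$ka, 0)
})

test_that("ng86 is symmetric in its two sequences", {
  set.seed(5)
  for (i in 1:5) {
    pa <- wgdkit:::cds_to_codon_idx(random_cds(40))
    pb <- wgdkit:::cds_to_codon_idx(random_cds(40))
    expect_equal(unclass(ng86(cbind(pa, pb))), unclass(ng86(cbind(pb, pa))))
  }
})

test_that("sites are conserved: S + N = 3 x aligned codons", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    r <- ng86(cbind(wgdkit:::cds_to_codon_idx(random_cds(n)),
                    wgdkit:::cds_to_codon_idx(random_cds(n))))
    expect_equal(r$s_sites + r$n_sites, 3 * n, tolerance = 1e-9)
  }
})

test_that("pathway averaging matches recursive enumeration on sampled codon pairs", {
  tab <- wgdkit:::codon_table()
  mats <- wgdkit:::path_count_matrices()
  sense <- tab$codon[!tab$is_stop]
  set.seed(9)
  pairs <- cbind(sample(sense, 150, TRUE), sample(sense, 150, TRUE))
  for (i in seq_len(nrow(pairs))) {
    o <- oracle_path_counts(pairs[i, 1], pairs[i, 2])
    expect_equal(mats$SD[pairs[i, 1], pairs[i, 2]], unname(o["sd"]),
                 tolerance = 1e-12, info = paste(pairs[i, ], collapse = "/"))
    expect_equal(mats$ND[pairs[i, 1], pairs[i, 2]], unname(o["nd"]),
                 tolerance = 1e-12, info = paste(pairs[i, ], collapse = "/"))
  }
})

test_that("codon alignment drops in-frame insertions and rejects bad input", {
  base <- random_cds(10)
  ## insert one extra codon after the 4th: 10 aligned pairs survive
  ins <- paste0(substr(base, 1, 12), "GCT", substr(base, 13, 30))
  al <- codon_align(base, ins)
  expect_equal(nrow(al), 10)
  expect_equal(al[, "codon_a"], al[, "codon_b"])
  ## internal stop is an error; empty sequence is an error
  stopcds <- paste0(substr(base, 1, 9), "TAA", substr(base, 13, 30))
  expect_error(codon_align(stopcds, base), "internal stop")
  expect_error(codon_align("", base), "empty CDS")
  ## terminal stop codons are tolerated and stripped
  al2 <- codon_align(paste0(base, "TGA"), base)
  expect_equal(nrow(al2), 10)
})

test_that("ks is monotone in the number of synonymous changes until saturation", {
  set.seed(11)
  cds <- random_cds(200)
  idx <- wgdkit:::cds_to_codon_idx(cds)
  last <- -1
  for (target in c(0.05, 0.2, 0.5, 1.0)) {
    mut <- wgdkit:::mutate_idx(idx, target, 0)
    r <- ng86(cbind(idx, mut))
    expect_gt(r$ks, last)
    last <- r$ks
  }
})

test_that("saturated pairs yield a marker, not an error", {
  ## two maximally scrambled sequences of 4-fold degenerate codons
  a <- strrep("GGT", 30)
  b <- strrep("GGG", 30)
  ## force direct pairing (equal length, same amino acids)
  r <- ng86(codon_align(a, b))
  expect_identical(r$status, "saturated")
  expect_true(is.na(r$ks))
})

test_that("block Ks annotation fills medians and flags mostly-bad blocks", {
  set.seed(21)
  n <- 6
  cds_a <- setNames(replicate(n, random_cds(120)), paste0("a", 0:(n - 1)))
  cds_b <- setNames(vapply(cds_a, function(x)
    mutate_cds(x, 0.3, 0.05), character(1)), paste0("b", 0:(n - 1)))
  ga <- toy_genome(list(c1 = names(cds_a)), "X", cds = cds_a)
  gb <- toy_genome(list(d1 = names(cds_b)), "Y", cds = cds_b)
  bl <- detect_blocks(diag_hits(names(cds_a), names(cds_b)), ga, gb)
  bl <- annotate_block_ks(bl, ga, gb)
  expect_true(all(bl$pairs$status == "ok"))
  expect_equal(bl$blocks$median_ks, median(bl$pairs$ks))
  expect_false(bl$blocks$flagged)
  ## simulated Ks recovery on an aggregate of pairs at target 0.5
  ks20 <- replicate(20, {
    x <- random_cds(300)
    ng86(codon_align(x, mutate_cds(x, 0.5)))$ks
  })
  expect_true(abs(median(ks20) - 0.5) < 0.05)
})
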