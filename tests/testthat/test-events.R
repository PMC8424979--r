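fake_blocks <- function(medians, flagged = rep(FALSE, length(medians))) {
  b <- wgdkit:::empty_blocks_df()
  for (i in seq_along(medians)) {
    b[i, ] <- list(i, "X", "X", "c1", "c2", 10L, "+", 0L, 9L, 0L, 9L,
                   medians[i], flagged[i], NA_character_)
  }
  wgdkit:::new_blocks(b, wgdkit:::empty_pairs_df(), "X", "X")
}

test_that("blocks are labelled by the unique window holding their median", {
  w <- ks_windows(c("AST", "ECH"), c(0.4, 1.4), c(1.2, 2.6))
  bl <- partition_blocks(fake_blocks(c(0.6, 0.7, 1.3, 1.8, NA),
                                     flagged = c(rep(FALSE, 4), TRUE)), w)
  expect_equal(bl$blocks$event, c("AST", "AST", "unassigned", "ECH",
                                  "unassigned"))
  ## partition completeness: exactly one label each
  expect_true(all(!is.na(bl$blocks$event)))
  expect_error(ks_windows(c("a", "b"), c(0, 0.5), c(1, 1.5)), "overlap")
})

test_that("mixture window suggestion recovers two separated waves", {
  set.seed(31)
  med <- c(rnorm(100, 0.7, 0.1), rnorm(100, 1.9, 0.3))
  w <- suggest_windows(med, n_components = 2)
  mu <- attr(w, "means")
  expect_equal(length(mu), 2)
  expect_lt(abs(mu[1] - 0.7), 0.1)
  expect_lt(abs(mu[2] - 1.9), 0.1)
  ## >= 90% of blocks labelled to their true wave
  truth <- rep(c("w1", "w2"), each = 100)
  w$event <- c("w1", "w2")
  bl <- partition_blocks(fake_blocks(med), w)
  expect_gt(mean(bl$blocks$event == truth), 0.9)
})

test_that("degenerate and collapsing mixtures are handled", {
  expect_error(suggest_windows(rep(1, 5)), ">= 10")
  w <- suggest_windows(rep(1, 20))
  expect_equal(nrow(w), 1)
  set.seed(32)
  expect_warning(suggest_windows(rnorm(200, 1, 0.02), n_components = 2),
                 "collapse")
})

test_that("ortholog depth counts distinct block footprints per window", {
  ref <- toy_genome(list(r1 = paste0("g", 0:199)), "R")
  mk <- function(ids, los, his, event = "speciation:R-S") {
    b <- wgdkit:::empty_blocks_df()
    for (i in seq_along(ids)) {
      b[i, ] <- list(ids[i], "R", "S", "r1", paste0("s", i), 10L, "+",
                     los[i], his[i], 0L, 9L, 0.5, FALSE, event)
    }
    wgdkit:::new_blocks(b, wgdkit:::empty_pairs_df(), "R", "S")
  }
  ## two full-length footprints everywhere -> depth 2 in every window
  bl <- mk(1:2, c(0, 0), c(199, 199))
  prof <- depth_profile(ref, bl, event = "speciation:R-S",
                        window_genes = 50)
  expect_equal(prof$depth, rep(2L, 4))
  ## a third, small footprint lifts exactly its window to 3
  bl3 <- mk(1:3, c(0, 0, 60), c(199, 199, 70))
  prof3 <- depth_profile(ref, bl3, event = "speciation:R-S",
                         window_genes = 50)
  expect_equal(prof3$depth, c(2L, 3L, 2L, 2L))
  ## depth is invariant under reversing the reference coordinate direction
  rev_ref <- toy_genome(list(r1 = paste0("g", 199:0)), "R")
  bl_rev <- mk(1:3, c(0, 0, 199 - 70), c(199, 199, 199 - 60))
  prof_rev <- depth_profile(rev_ref, bl_rev, event = "speciation:R-S",
                            window_genes = 50)
  expect_equal(sort(prof_rev$depth), sort(prof3$depth))
})

test_that("multiplicity is the modal nonzero depth with its support", {
  prof <- data.frame(chrom = "r1", win_start = 0, win_end = 1,
                     depth = c(rep(2L, 80), rep(1L, 15), rep(3L, 5)))
  call <- infer_ploidy(prof)
  expect_equal(call$multiplicity, 2)
  expect_equal(call$support, 0.8)
  expect_match(call$interpretation, "tetraploidization")
  all1 <- infer_ploidy(data.frame(depth = rep(1L, 20)))
  expect_equal(all1$multiplicity, 1)
  expect_match(all1$interpretation, "no extra polyploidy")
  expect_error(infer_ploidy(data.frame(depth = rep(0L, 20))), "nonzero")
})

test_that("simulated tetraploid target shows modal depth 2 over the diploid reference", {
  bundle <- sim_small()
  hits <- filter_hits(bundle$hits[["V-A"]])
  bl <- detect_blocks(hits, bundle$genomes$V, bundle$genomes$A)
  ## label blocks straight from truth (classification is tested elsewhere)
  tp <- bundle$truth$pairs[bundle$truth$pairs$comparison == "V-A", ]
  ev <- tp$event[match(paste(bl$pairs$gene_a, bl$pairs$gene_b),
                       paste(tp$gene_a, tp$gene_b))]
  med_ev <- vapply(split(ev, bl$pairs$block_id), function(x)
    names(sort(-table(x)))[1], character(1))
  bl$blocks$event <- med_ev[as.character(bl$blocks$block_id)]
  prof <- depth_profile(bundle$genomes$V, bl, event = "speciation:V-A",
                        window_genes = 50)
  expect_equal(infer_ploidy(prof)$multiplicity, 2)
})
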