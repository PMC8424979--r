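## A hand-built trio: reference V with one chromosome triple related by the
## shared hexaploidy (v1/v2/v3), diploid T with one ortholog chromosome per
## reference chromosome, tetraploid A with two sibling ortholog chromosomes
## per reference chromosome (one gene lost from one sibling).
trio_fixture <- function(lose = "Y4") {
  V <- toy_genome(list(v1 = paste0("V", 1:6), v2 = paste0("P", 1:6),
                       v3 = paste0("Q", 1:6)), "V")
  T_ <- toy_genome(list(t1 = paste0("T", 1:6), t2 = paste0("U", 1:6),
                        t3 = paste0("W", 1:6)), "T")
  A <- toy_genome(list(a1x = paste0("X", 1:6),
                       a1y = setdiff(paste0("Y", 1:6), lose),
                       a2x = paste0("XX", 1:6), a2y = paste0("YY", 1:6),
                       a3x = paste0("ZX", 1:6), a3y = paste0("ZY", 1:6)),
                  "A")
  lab <- function(bl, event) { bl$blocks$event <- event; bl }
  vv <- lab(detect_blocks(rbind(
    diag_hits(paste0("V", 1:6), paste0("P", 1:6)),
    diag_hits(paste0("V", 1:6), paste0("Q", 1:6)),
    diag_hits(paste0("P", 1:6), paste0("Q", 1:6))), V, V), "ECH")
  vt <- lab(detect_blocks(rbind(
    diag_hits(paste0("V", 1:6), paste0("T", 1:6)),
    diag_hits(paste0("P", 1:6), paste0("U", 1:6)),
    diag_hits(paste0("Q", 1:6), paste0("W", 1:6))), V, T_),
    "speciation:V-T")
  keepY <- setdiff(1:6, as.integer(sub("Y", "", lose)))
  va <- lab(detect_blocks(rbind(
    diag_hits(paste0("V", 1:6), paste0("X", 1:6)),
    diag_hits(paste0("V", keepY), paste0("Y", keepY)),
    diag_hits(paste0("P", 1:6), paste0("XX", 1:6)),
    diag_hits(paste0("P", 1:6), paste0("YY", 1:6)),
    diag_hits(paste0("Q", 1:6), paste0("ZX", 1:6)),
    diag_hits(paste0("Q", 1:6), paste0("ZY", 1:6))), V, A),
    "speciation:V-A")
  aa <- lab(detect_blocks(rbind(
    diag_hits(paste0("X", keepY), paste0("Y", keepY)),
    diag_hits(paste0("XX", 1:6), paste0("YY", 1:6)),
    diag_hits(paste0("ZX", 1:6), paste0("ZY", 1:6))), A, A), "AST")
  list(V = V, T = T_, A = A, blocks = list(vv, vt, va, aa))
}

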