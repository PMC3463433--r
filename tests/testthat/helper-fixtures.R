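# shared fixtures: paths to the bundled annotation tables and programmatic
# constructors for tRNA cloverleaves and small genomes

tr_table <- function() {
  read_feature_table(system.file("extdata", "thitarodes_renzhiensis.features.tsv",
                                 package = "mitoarch"), id = "T_renzhiensis")
}

ty_table <- function() {
  read_feature_table(system.file("extdata", "thitarodes_yunnanensis.features.tsv",
                                 package = "mitoarch"), id = "T_yunnanensis")
}

# build a cloverleaf trna_structure with known pair content.
# stems: acceptor 7, DHU 4, anticodon 5, TpsiC 5. Pairs default to A-T;
# `overrides` is a list of list(arm =, index =, bases = c(b5, b3)) entries.
make_cloverleaf <- function(gene = "trnToy", anticodon = "TCT",
                            overrides = list()) {
  sizes <- c(acc = 7L, dhu = 4L, dhu_loop = 5L, ac = 5L, ac_loop = 7L,
             var = 4L, tpc = 5L, tpc_loop = 5L, disc = 1L)
  n <- sizes[["acc"]] * 2 + sizes[["dhu"]] * 2 + sizes[["dhu_loop"]] +
    sizes[["ac"]] * 2 + sizes[["ac_loop"]] + sizes[["var"]] +
    sizes[["tpc"]] * 2 + sizes[["tpc_loop"]] + sizes[["disc"]]
  x <- rep("A", n)

  pos <- 1L
  seg <- function(k) { out <- pos:(pos + k - 1L); pos <<- pos + k; out }
  acc5 <- seg(sizes[["acc"]])
  dhu5 <- seg(sizes[["dhu"]]); dhu_loop <- seg(sizes[["dhu_loop"]])
  dhu3 <- seg(sizes[["dhu"]])
  ac5 <- seg(sizes[["ac"]]); ac_loop <- seg(sizes[["ac_loop"]])
  ac3 <- seg(sizes[["ac"]])
  var <- seg(sizes[["var"]])
  tpc5 <- seg(sizes[["tpc"]]); tpc_loop <- seg(sizes[["tpc_loop"]])
  tpc3 <- seg(sizes[["tpc"]])
  acc3 <- seg(sizes[["acc"]])

  pair_up <- function(p5, p3) Map(c, p5, rev(p3))
  arms <- list(acceptor = pair_up(acc5, acc3), DHU = pair_up(dhu5, dhu3),
               anticodon = pair_up(ac5, ac3), TpsiC = pair_up(tpc5, tpc3))
  for (arm in names(arms)) {
    for (p in arms[[arm]]) { x[p[1]] <- "A"; x[p[2]] <- "T" }
  }
  for (ov in overrides) {
    p <- arms[[ov$arm]][[ov$index]]
    x[p[1]] <- ov$bases[1]; x[p[2]] <- ov$bases[2]
  }
  mid <- ac_loop[ceiling(length(ac_loop) / 2)]
  apos <- (mid - 1L):(mid + 1L)
  x[apos] <- strsplit(anticodon, "")[[1]]
  trna_structure(gene, paste(x, collapse = ""), arms,
                 anticodon_positions = apos)
}

# dot-bracket text for the same cloverleaf geometry (6 segments)
cloverleaf_dot_bracket <- function() {
  paste0("(((((((", ",", "((((.....))))", ",", "(((((.......)))))",
         ",", "....", ",", "(((((.....)))))", ",", "))))))).")
}

random_dna <- function(n, at = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
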