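test_that("pairwise gaps are signed and handle the circular origin", {
  expect_equal(pairwise_gap(1292, 1285), -8)   # trnW / trnC overlap
  expect_equal(pairwise_gap(10, 11), 0)        # contiguous
  expect_equal(pairwise_gap(67, 95), 27)       # trnI / trnQ spacer
  expect_equal(pairwise_gap(16173, 1, genome_length = 16173, wrap = TRUE), 0)
})

test_that("overlap reports reproduce the three printed locations", {
  for (rec in list(tr_table(), ty_table())) {
    ov <- find_overlaps(rec)
    expect_equal(nrow(ov), 3)
    expect_equal(sum(ov$length), 16)
    expect_equal(ov$length[ov$upstream == "trnW"], 8)
    expect_equal(ov$length[ov$upstream == "atp8"], 7)
    expect_equal(ov$length[ov$upstream == "trnK"], 1)
  }
  disjoint <- tibble::tibble(gene = c("trnI", "trnQ"), class = "tRNA",
                             strand = "J", start = c(1L, 80L), end = c(65L, 148L))
  expect_equal(nrow(find_overlaps(disjoint, genome_length = 200)), 0)
})

test_that("overlap totals agree with a brute-force adjacent-pair scan", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    starts <- sort(sample(1:400, n))
    ends <- starts + sample(10:60, n, replace = TRUE)
    feats <- tibble::tibble(gene = paste0("trn", LETTERS[1:n]), class = "tRNA",
                            strand = "J", start = starts, end = ends)
    L <- max(ends) + 50L
    got <- find_overlaps(feats, genome_length = L)
    brute <- 0L
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      ov <- if (k == n) 0L else max(0L, ends[k] - starts[k2] + 1L)
      brute <- brute + ov
    }
    expect_equal(sum(got$length), brute)
  }
})

test_that("spacer reports reproduce the printed noncoding totals", {
  sp_tr <- find_intergenic_spacers(tr_table())
  expect_equal(sum(sp_tr$length), 49)
  sp_ty <- find_intergenic_spacers(ty_table())
  expect_equal(sum(sp_ty$length), 81)
  expect_equal(sp_ty$length[sp_ty$upstream == "trnI"], 27)
  expect_equal(sp_ty$length[sp_ty$upstream == "trnS(UCN)"], 15)
  expect_equal(sp_tr$length[sp_tr$upstream == "trnS(UCN)"], 15)
  # wall-to-wall features leave no spacer
  wall <- tibble::tibble(gene = c("trnI", "trnQ"), class = "tRNA", strand = "J",
                         start = c(1L, 66L), end = c(65L, 120L))
  expect_equal(nrow(find_intergenic_spacers(wall, genome_length = 120)), 0)
})

test_that("spacer sequences are attached when a sequence is present", {
  sim <- simulate_mitogenome(sim_spec(seed = 17))
  sp <- find_intergenic_spacers(sim$record)
  expect_true("sequence" %in% names(sp))
  expect_equal(nchar(sp$sequence), sp$length)
  one <- sp[1, ]
  expect_equal(one$sequence,
               feature_sequence(sim$record, one$start, one$end, "J"))
})

test_that("the conservation identity holds on printed tables and generated genomes", {
  expect_equal(architecture_checksum(tr_table()), 16173)
  expect_equal(architecture_checksum(ty_table()), 15816)
  for (s in c(2, 19)) {
    rec <- simulate_mitogenome(sim_spec(seed = s))$record
    expect_equal(architecture_checksum(rec), genome_length(rec))
  }
})

test_that("gene orders extract, rotate and compare circularly", {
  ord <- extract_gene_order(tr_table())
  expect_equal(nrow(ord), 37)
  anc <- ref_gene_order("ancestral")
  expect_equal(ord, anc)
  # a rotated record yields an order that compares equal circularly
  rot <- dplyr::bind_rows(ord[10:37, ], ord[1:9, ])
  expect_equal(nrow(classify_rearrangements(rot, anc)), 0)
  dup <- dplyr::bind_rows(tr_table()$features, tr_table()$features[2, ])
  expect_error(extract_gene_order(dup), "duplicate")
})

test_that("the reference orders differ only in the trnI/trnQ/trnM block", {
  anc <- ref_gene_order("ancestral")
  dit <- ref_gene_order("ditrysian")
  expect_setequal(anc$gene, dit$gene)
  keep <- !anc$gene %in% c("trnI", "trnQ", "trnM")
  anc_rest <- anc[anc$gene %in% anc$gene[keep], ]
  dit_rest <- dit[dit$gene %in% anc$gene[keep], ]
  expect_equal(nrow(classify_rearrangements(dit_rest, anc_rest)), 0)
})

test_that("rearrangement classification covers the three event kinds", {
  anc <- ref_gene_order("ancestral")
  # identical orders: no events
  expect_equal(nrow(classify_rearrangements(anc, anc)), 0)
  # the ditrysian order is one trnM translocation away from ancestral
  ev <- classify_rearrangements(ref_gene_order("ditrysian"), anc)
  expect_equal(ev$gene, "trnM")
  expect_equal(ev$kind, "translocation")
  # strand flip in place is a local inversion
  flip <- anc
  flip$strand[flip$gene == "trnC"] <- "J"
  ev2 <- classify_rearrangements(flip, anc)
  expect_equal(ev2$gene, "trnC")
  expect_equal(ev2$kind, "local_inversion")
  # moved and strand-flipped is a remote inversion
  remote <- anc[anc$gene != "trnC", ]
  moved <- tibble::tibble(gene = "trnC", strand = "J")
  remote <- dplyr::bind_rows(remote[1:20, ], moved, remote[21:36, ])
  ev3 <- classify_rearrangements(remote, anc)
  expect_equal(ev3$gene, "trnC")
  expect_equal(ev3$kind, "remote_inversion")
  # mismatched gene sets error informatively
  expect_error(classify_rearrangements(anc[-1, ], anc), "trnI")
})

test_that("event lists are invariant under rotation of either order", {
  anc <- ref_gene_order("ancestral")
  dit <- ref_gene_order("ditrysian")
  ev <- classify_rearrangements(dit, anc)
  for (r in c(5, 20)) {
    rot <- dplyr::bind_rows(dit[r:37, ], dit[1:(r - 1), ])
    expect_equal(classify_rearrangements(rot, anc)[, c("gene", "kind")],
                 ev[, c("gene", "kind")])
    rot_ref <- dplyr::bind_rows(anc[r:37, ], anc[1:(r - 1), ])
    expect_equal(classify_rearrangements(dit, rot_ref)[, c("gene", "kind")],
                 ev[, c("gene", "kind")])
  }
})

test_that("the minimal mover set matches exhaustive search on small orders", {
  base <- tibble::tibble(gene = paste0("g", 1:7), strand = "J")
  set.seed(3)
  for (i in 1:8) {
    obs <- base
    mover <- sample(7, 1)
    rest <- obs[-mover, ]
    at <- sample(6, 1)
    obs <- dplyr::bind_rows(rest[seq_len(at), ], base[mover, ],
                            rest[setdiff(seq_len(6), seq_len(at)), ])
    ev <- classify_rearrangements(obs, base)
    # exhaustive check: minimal mover count by brute force over removals
    equal0 <- nrow(classify_rearrangements(obs, base)) == 0
    ok1 <- vapply(base$gene, function(g) {
      a <- obs[obs$gene != g, ]; b <- base[base$gene != g, ]
      nrow(classify_rearrangements(a, b)) == 0
    }, logical(1))
    if (equal0) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_true(any(ok1))          # a single mover suffices by construction
      expect_equal(nrow(ev), 1)      # and the classifier reports exactly one
      expect_true(ok1[[ev$gene]])    # whose removal reconciles the orders
    }
  }
})
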