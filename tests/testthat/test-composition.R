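test_that("base composition and skews follow their definitions", {
  expect_equal(base_composition("AATT")$AT_skew, 0)
  expect_equal(base_composition("GGCC")$GC_skew, 0)
  expect_equal(base_composition("AAAT")$AT_skew, 0.5)   # (3 - 1)/(3 + 1)
  comp <- base_composition("AACG")
  expect_equal(comp$AT_content, 50)
  expect_equal(comp$A + comp$C + comp$G + comp$T, 100)
  # undefined denominators are NaN, never zero
  expect_true(is.nan(base_composition("AT")$GC_skew))
  expect_true(is.nan(base_composition("GC")$AT_skew))
  expect_error(base_composition(""), "nonempty")
  # N residues are excluded from denominators
  expect_equal(base_composition("AANN")$A, 100)
  expect_equal(base_composition("AANN")$n, 2)
})

test_that("reverse-complementing negates both skews exactly", {
  set.seed(31)
  for (i in 1:10) {
    s <- random_dna(500, at = runif(1, 0.3, 0.9))
    a <- base_composition(s)
    b <- base_composition(reverse_complement(s))
    expect_equal(a$AT_skew, -b$AT_skew)
    expect_equal(a$GC_skew, -b$GC_skew)
    expect_equal(a$AT_content, b$AT_content)
  }
})

test_that("codon-position composition matches a brute-force per-position tally", {
  expect_equal(composition_by_codon_position(c(x = "ATAATA"))$A[1], 100)
  set.seed(8)
  seqs <- c(a = random_dna(300), b = random_dna(150))
  got <- composition_by_codon_position(seqs)
  concat <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  for (p in 1:3) {
    chars <- concat[seq(p, length(concat), by = 3)]
    expect_equal(got$A[p], 100 * mean(chars == "A"), tolerance = 1e-12)
    expect_equal(got$T[p], 100 * mean(chars == "T"), tolerance = 1e-12)
  }
  expect_error(composition_by_codon_position(c(bad = "ATAAT")), "bad")
})

test_that("RSCU follows its definition within synonymous families", {
  tab <- codon_families()
  expect_equal(nrow(tab), 62)
  expect_setequal(unique(tab$family[tab$amino_acid == "L"]), c("Leu(UUR)", "Leu(CUN)"))
  expect_setequal(unique(tab$family[tab$amino_acid == "S"]), c("Ser(UCN)", "Ser(AGN)"))
  expect_equal(tab$family_size[tab$codon == "TTA"], 2)
  expect_equal(tab$family_size[tab$codon == "CTA"], 4)

  # uniform usage within a 4-codon family -> all RSCU = 1
  val <- codon_usage(strrep("CCACCGCCTCCC", 5))
  pro <- val[val$family == "P", ]
  expect_equal(pro$rscu, rep(1, 4))
  # counts (4, 0, 0, 0) -> RSCU (4, 0, 0, 0)
  val2 <- codon_usage(strrep("GGA", 4))
  gly <- val2[val2$family == "G", ]
  expect_equal(sort(gly$rscu, decreasing = TRUE), c(4, 0, 0, 0))
  # zero-count families are NaN
  expect_true(all(is.nan(val2$rscu[val2$family == "P"])))
})

test_that("codon usage totals, per-thousand and absent codons are coherent", {
  sim <- simulate_mitogenome(sim_spec(seed = 6))
  cu <- codon_usage(sim$record)
  expect_equal(sum(cu$count), count_codons(sim$record))
  expect_equal(sum(cu$per_thousand), 1000, tolerance = 0.01)
  fam <- cu |>
    dplyr::filter(count > 0 | !is.nan(rscu)) |>
    dplyr::group_by(family) |>
    dplyr::summarise(s = sum(rscu), n = dplyr::first(family_size))
  nz <- fam[!is.nan(fam$s), ]
  expect_equal(nz$s, as.numeric(nz$n))
  expect_setequal(absent_codons(cu), cu$codon_rna[cu$count == 0])
  expect_error(codon_usage("TAATAA"), "internal stop")
})

test_that("composition summary rows sum to 100 and use sense sequences", {
  sim <- simulate_mitogenome(sim_spec(seed = 16))
  comp <- composition_summary(sim$record)
  expect_true(all(abs(comp$A + comp$C + comp$G + comp$T - 100) < 0.01))
  expect_setequal(
    comp$region,
    c("whole_genome", "PCGs", paste0("codon_position_", 1:3), "tRNAs",
      "rrnL", "rrnS", "at_rich_region"))
  # PCG row equals composition of the concatenated stop-trimmed sense genes
  sense <- paste(pcg_sense_sequences(sim$record), collapse = "")
  expect_equal(comp$AT_content[comp$region == "PCGs"],
               base_composition(sense)$AT_content)
})

test_that("skew scatter points equal per-genome base compositions", {
  sims <- lapply(c(21, 22), function(s) simulate_mitogenome(sim_spec(seed = s))$record)
  pts <- skew_scatter(sims)
  expect_equal(nrow(pts), 2)
  for (i in 1:2) {
    comp <- base_composition(sims[[i]]$sequence)
    expect_equal(pts$AT_skew[i], comp$AT_skew)
    expect_equal(pts$GC_skew[i], comp$GC_skew)
  }
  expect_equal(skew_scatter(c(g = "GGGG"))$GC_skew, 1)
  # swapping strands negates both skews
  rc <- vapply(sims, function(r) reverse_complement(r$sequence), "")
  pts_rc <- skew_scatter(stats::setNames(rc, c("a", "b")))
  expect_equal(pts_rc$AT_skew, -pts$AT_skew)
  expect_equal(pts_rc$GC_skew, -pts$GC_skew)
})
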