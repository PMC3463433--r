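test_that("the invertebrate mitochondrial code has its table-5 reassignments", {
  code <- genetic_code()
  expect_equal(unname(code$map[c("AGA", "AGG")]), c("S", "S"))
  expect_equal(unname(code$map["TGA"]), "W")
  expect_equal(unname(code$map["ATA"]), "M")
  expect_setequal(code$stops, c("TAA", "TAG"))
  expect_setequal(code$starts, c("ATA", "ATT", "ATC", "ATG", "GTG", "TTG", "GTT"))
  expect_equal(code$overrides$cox1, "CGA")
})

test_that("find_start takes the first legitimate codon in the window", {
  expect_equal(find_start("ATGAAACCC", c(0, 6)), list(offset = 0L, codon = "ATG"))
  # brute-force scan: first legitimate hit across the window
  expect_equal(find_start("CCCTTGAAA", c(0, 6)), list(offset = 3L, codon = "TTG"))
  expect_equal(find_start("CCCCGAAAA", c(0, 6), overrides = "CGA")$codon, "CGA")
  expect_error(find_start("CCCCCCCCC", c(0, 6)), "no start found")
  # independently verify against a brute-force scan on random sequences
  set.seed(42)
  legit <- genetic_code()$starts
  for (i in 1:20) {
    s <- random_dna(30)
    hits <- which(vapply(1:28, function(o) substr(s, o, o + 2) %in% legit, TRUE))
    if (length(hits) == 0) {
      expect_error(find_start(s, c(0, 27)), "no start found")
    } else {
      expect_equal(find_start(s, c(0, 27))$offset, hits[1] - 1L)
    }
  }
})

test_that("find_stop returns full stops and truncates against downstream genes", {
  expect_equal(find_stop("ATGAAATAA", 0), list(end_offset = 8, stop = "TAA"))
  # stop would lie inside the downstream gene starting at position 8 -> T--
  # gene: ATGAAAT | downstream from position 8
  expect_equal(find_stop("ATGAAATGGGTAACC", 0, downstream_gene_boundary = 8),
               list(end_offset = 6L, stop = "T--"))
  # remainder of 2 spelling TA -> TA-
  expect_equal(find_stop("ATGAAATACCCTAACC", 0, downstream_gene_boundary = 9),
               list(end_offset = 7L, stop = "TA-"))
  # a full stop ending immediately before the boundary wins over truncation
  expect_equal(find_stop("ATGAAATAACCC", 0, downstream_gene_boundary = 10),
               list(end_offset = 8, stop = "TAA"))
  # remainder does not spell T/TA and the full stop overlaps the downstream
  # gene: the full stop stands (the atp8/atp6 configuration)
  expect_equal(find_stop("ATGAAACCGTAA", 0, downstream_gene_boundary = 9),
               list(end_offset = 11, stop = "TAA"))
  # a whole-codon remainder cannot truncate either
  expect_equal(find_stop("ATGAAACCCTAA", 0, downstream_gene_boundary = 10),
               list(end_offset = 11, stop = "TAA"))
  expect_error(find_stop("ATGAAAAAA", 0), "open ORF")
})

test_that("count_codons reproduces printed totals from coordinates and stop tokens", {
  expect_equal(count_codons(tr_table()), 3720)
  expect_equal(count_codons(ty_table()), 3720)
  single <- tibble::tibble(gene = "nad2", class = "PCG", strand = "J",
                           start = 1L, end = 9L, stop_codon = "TAA")
  expect_equal(count_codons(single, genome_length = 100), 2)
  expect_error(count_codons(dplyr::mutate(single, end = 10L), genome_length = 100),
               "divisible by 3.*nad2")
  expect_error(count_codons(dplyr::mutate(single, stop_codon = NA_character_),
                            genome_length = 100),
               "missing stop codon")
})

test_that("annotate_pcgs requires a sequence and reports per-gene failures", {
  expect_error(annotate_pcgs(tr_table()), "sequence required")
  sim <- simulate_mitogenome(sim_spec(seed = 11))
  # wipe out nad3's whole start window: that gene fails, the others resolve
  rec <- sim$record
  nad3 <- dplyr::filter(rec$features, gene == "nad3")
  seq <- rec$sequence
  substr(seq, nad3$start, nad3$start + 32) <- strrep("C", 33)
  rec2 <- mito_genome(rec$features, sequence = seq, id = "corrupt")
  calls <- annotate_pcgs(rec2)
  expect_equal(nrow(calls), 13)
  expect_false(is.na(calls$note[calls$gene == "nad3"]))
  expect_true(sum(is.na(calls$note)) >= 11)
})

test_that("annotate_pcgs recovers generator truth exactly, including jittered hints", {
  sim <- simulate_mitogenome(sim_spec(seed = 4))
  rec <- sim$record
  truth <- dplyr::filter(sim$truth, class == "PCG")
  calls <- annotate_pcgs(rec)
  m <- dplyr::inner_join(calls, truth, by = "gene", suffix = c("", ".t"))
  expect_equal(m$start, m$start.t)
  expect_equal(m$end, m$end.t)
  expect_equal(m$start_codon, m$start_codon.t)
  expect_equal(m$stop_codon, m$stop_codon.t)
  expect_equal(sum(calls$codon_count), count_codons(rec))

  # hints jittered inside the search window still recover the boundaries
  # (downstream start jitter: the scan reaches back half a window, which
  # then still lies inside the region the generator keeps ambiguity-free)
  set.seed(7)
  hints <- truth
  j5 <- sample(0:15, nrow(hints), replace = TRUE)   # 5'-inward jitter
  j3 <- sample(-10:10, nrow(hints), replace = TRUE) # 3'-side jitter
  is_j <- hints$strand == "J"
  hints$start[is_j] <- hints$start[is_j] + j5[is_j]
  hints$end[is_j] <- hints$end[is_j] + j3[is_j]
  hints$end[!is_j] <- hints$end[!is_j] - j5[!is_j]
  hints$start[!is_j] <- hints$start[!is_j] + j3[!is_j]
  calls2 <- annotate_pcgs(rec, hints = hints)
  m2 <- dplyr::inner_join(calls2, truth, by = "gene", suffix = c("", ".t"))
  expect_equal(m2$start, m2$start.t)
  expect_equal(m2$end, m2$end.t)
})

test_that("translated PCG calls contain no internal stop", {
  sim <- simulate_mitogenome(sim_spec(seed = 9))
  rec <- sim$record
  sense <- pcg_sense_sequences(rec, stop_trimmed = TRUE)
  for (s in sense) {
    expect_false(grepl("\\*", translate_sense(s)))
  }
})

test_that("count_codons is invariant under re-linearization", {
  sim <- simulate_mitogenome(sim_spec(seed = 13))
  rec <- sim$record
  # rotate the circle so nad2 becomes the origin gene
  rot <- relinearize(rec, origin_gene = "trnM")
  expect_equal(count_codons(rot), count_codons(rec))
  expect_equal(architecture_checksum(rot), genome_length(rot))
})
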