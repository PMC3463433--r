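test_that("feature tables read with inferred genome length and validate", {
  tr <- tr_table()
  expect_s3_class(tr, "mito_genome")
  expect_equal(nrow(tr$features), 38)
  expect_equal(genome_length(tr), 16173)
  expect_equal(genome_length(ty_table()), 15816)
  # class inferred from names where not given
  expect_equal(infer_feature_class(c("trnI", "rrnL", "nad2", "at_rich_region")),
               c("tRNA", "rRNA", "PCG", "control"))
})

test_that("empty and malformed tables are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tclass\tstrand\tstart\tend\tstart_codon\tstop_codon\tanticodon", f)
  empty <- read_feature_table(f)
  expect_equal(nrow(empty$features), 0)

  writeLines(c("gene\tclass\tstrand\tstart\tend\tstart_codon\tstop_codon\tanticodon",
               "trnI\ttRNA\tJ\tone\t65\t\t\t"), f)
  expect_error(read_feature_table(f), "line 2")

  writeLines(c("gene\tclass\tstrand\tstart\tend\tstart_codon\tstop_codon\tanticodon",
               "trnI\ttRNA\tX\t1\t65\t\t\t"), f)
  expect_error(read_feature_table(f), "strand")
})

test_that("validation enforces the annotation contract", {
  base <- tibble::tibble(gene = "nad2", class = "PCG", strand = "J",
                         start = 1L, end = 9L)
  expect_silent(validate_features(base))
  expect_error(validate_features(dplyr::mutate(base, stop_codon = "TG-")), "stop codon")
  expect_error(validate_features(dplyr::mutate(base, class = "tRNA", stop_codon = "TAA")),
               "only valid on PCG")
  expect_error(validate_features(dplyr::mutate(base, anticodon = "CAT")),
               "only valid on tRNA")
  expect_error(validate_features(base, genome_length = 5), "exceed")
})

test_that("feature lengths handle inclusive and origin-spanning coordinates", {
  expect_equal(feature_length(12628, 13962), 1335)   # rrnL
  expect_equal(feature_length(14062, 14838), 777)    # rrnS
  expect_equal(feature_length(16170, 4, 16173), 8)   # wraps the origin
  expect_equal(feature_length(14807, 16173), 1367)   # A+T-rich region
  expect_error(feature_length(10, 2), "genome_length")
})

test_that("feature table round trips are bit-exact", {
  tr <- tr_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tr, f)
  back <- read_feature_table(f)
  expect_equal(back$features, tr$features)
  orig <- readLines(system.file("extdata", "thitarodes_renzhiensis.features.tsv",
                                package = "mitoarch"))
  expect_identical(readLines(f), orig)
  # truncated stop tokens keep their trailing hyphens
  expect_true(any(grepl("\tT--", readLines(f), fixed = TRUE)))
})

test_that("FASTA round trips and normalizes case", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy test", "acgtacgtNN", "ACGT"), f)
  rec <- read_fasta(f)
  expect_equal(rec$sequence, "ACGTACGTNNACGT")
  expect_equal(rec$id, "toy")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rec, f2)
  expect_equal(read_fasta(f2)$sequence, rec$sequence)
  expect_error(mito_genome(tibble::tibble(gene = character(), class = character(),
                                          strand = character(), start = integer(),
                                          end = integer()),
                           sequence = "ACGT7"), "non-IUPAC")
})

test_that("GenBank features map to classes and strands", {
  gb <- withr::local_tempfile(fileext = ".gb")
  seq_lines <- vapply(seq(1, 300, by = 30), function(i) {
    paste0(sprintf("%9d", i), " ", paste(rep("aacgtacgta", 3), collapse = " "))
  }, "")
  writeLines(c(
    "LOCUS       TOY0001     300 bp    DNA     circular INV 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..65",
    "                     /gene=\"trnI\"",
    "     tRNA            complement(66..134)",
    "                     /gene=\"trnQ\"",
    "     CDS             140..250",
    "                     /gene=\"nad2\"",
    "     D-loop          251..300",
    "ORIGIN",
    seq_lines,
    "//"), gb)
  rec <- read_genbank(gb)
  expect_equal(rec$length, 300)
  f <- rec$features
  expect_equal(f$strand[f$gene == "trnQ"], "N")
  expect_equal(f$start[f$gene == "trnQ"], 66)
  expect_equal(f$end[f$gene == "trnQ"], 134)
  expect_equal(f$class[f$gene == "nad2"], "PCG")
  expect_equal(f$class[f$gene == "at_rich_region"], "control")
})

test_that("relinearize rotates the origin to trnI", {
  feats <- tibble::tibble(
    gene = c("at_rich_region", "trnI", "nad2"),
    class = c("control", "tRNA", "PCG"),
    strand = "J", start = c(1L, 51L, 120L), end = c(50L, 119L, 200L))
  seq <- random_dna(200, seed = 1)
  rec <- relinearize(mito_genome(feats, sequence = seq, id = "rot"))
  expect_equal(rec$features$start[rec$features$gene == "trnI"], 1)
  expect_equal(genome_length(rec), 200)
  # rotating back-to-front preserves the sequence content circularly
  expect_equal(sort(strsplit(rec$sequence, "")[[1]]), sort(strsplit(seq, "")[[1]]))
  expect_equal(rec$sequence, paste0(substr(seq, 51, 200), substr(seq, 1, 50)))
})

test_that("tidy and glance expose the tabular views", {
  tr <- tr_table()
  expect_equal(tidy(tr), tr$features)
  g <- glance(tr)
  expect_equal(g$n_pcg, 13)
  expect_equal(g$n_trna, 22)
  expect_equal(g$n_rrna, 2)
  expect_false(g$has_sequence)
})
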