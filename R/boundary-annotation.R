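# PCG boundary determination under the invertebrate mitochondrial code
# (translation table 5), including truncated stop-codon designation.

#' The invertebrate mitochondrial genetic code
#'
#' Translation table 5: AGA/AGG encode Ser (not stop), TGA Trp, ATA Met; the
#' only stop codons are TAA and TAG. The legitimate start-codon set defaults
#' to `{ATA, ATT, ATC, ATG, GTG, TTG, GTT}` (ATN plus GTG, TTG and GTT), with
#' per-gene overrides for atypical starts — by default cox1 may start with
#' CGA, the designation conventional in Lepidoptera.
#'
#' @param start_codons Character vector of legitimate start codons.
#' @param overrides Named list mapping gene names to extra start codons
#'   accepted for that gene only.
#' @return An object of class `genetic_code`: `map` (codon to amino acid,
#'   `*` for stop), `stops`, `starts`, `overrides`.
#' @export
genetic_code <- function(start_codons = c("ATA", "ATT", "ATC", "ATG",
                                          "GTG", "TTG", "GTT"),
                         overrides = list(cox1 = "CGA")) {
  map <- Biostrings::getGeneticCode("5")
  structure(
    list(map = map, stops = names(map)[map == "*"],
         starts = toupper(start_codons), overrides = overrides),
    class = "genetic_code"
  )
}

#' Translate a sense nucleotide sequence under a genetic code
#'
#' @param sense_sequence In-frame nucleotide string (length a multiple of 3).
#' @param code A [genetic_code()].
#' @return Amino-acid string (`*` marks stops).
#' @export
translate_sense <- function(sense_sequence, code = genetic_code()) {
  n <- nchar(sense_sequence)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3")
  codons <- substring(sense_sequence, seq(1, n, 3), seq(3, n, 3))
  paste(code$map[codons], collapse = "")
}

#' Locate the first legitimate start codon in a search window
#'
#' Scans the window offsets in increasing order and returns the first
#' position whose triplet is a legitimate start (or a configured per-gene
#' override codon).
#'
#' @param sense_sequence Sense-strand nucleotide string.
#' @param search_window Integer vector of candidate 0-based offsets, or
#'   `c(from, to)` giving an inclusive offset range.
#' @param code A [genetic_code()].
#' @param overrides Extra start codons accepted here (e.g. `"CGA"` for cox1).
#' @return A list with `offset` (0-based) and `codon`, or an error when no
#'   legitimate start lies in the window.
#' @examples
#' find_start("CCCTTGAAA", c(0, 6))   # offset 3, TTG
#' @export
find_start <- function(sense_sequence, search_window, code = genetic_code(),
                       overrides = NULL) {
  offsets <- if (length(search_window) == 2 && search_window[2] >= search_window[1] &&
                 search_window[2] - search_window[1] > 1) {
    seq(search_window[1], search_window[2])
  } else {
    search_window
  }
  legit <- c(code$starts, toupper(overrides))
  for (o in offsets) {
    if (o < 0 || o + 3 > nchar(sense_sequence)) next
    codon <- substr(sense_sequence, o + 1, o + 3)
    if (codon %in% legit) return(list(offset = o, codon = codon))
  }
  abort("no start found: no legitimate start codon in the search window")
}

#' Determine a gene's stop codon, truncating against a downstream gene
#'
#' Walks in frame from the start and takes the first TAA/TAG. When that stop
#' lies (even partially) within a downstream gene on the same strand, the
#' gene is instead ended immediately before the downstream gene's first base
#' and the 1- or 2-base remainder must read `T` / `TA` — the truncated stop
#' completed to TAA by post-transcriptional polyadenylation. If the remainder
#' does not spell a truncated stop the full stop stands, which is how the
#' canonical atp8/atp6 overlap arises: atp8's in-frame TAA lies inside atp6
#' yet no truncation is possible, so atp8 keeps its complete stop.
#'
#' @param sense_sequence Sense-strand nucleotide string.
#' @param start_offset 0-based offset of the start codon.
#' @param downstream_gene_boundary 1-based position (within
#'   `sense_sequence`) of the first base of the next same-strand gene, or
#'   `NULL` when there is none.
#' @param code A [genetic_code()].
#' @return A list with `end_offset` (0-based offset of the gene's final
#'   base) and `stop` (one of `TAA`, `TAG`, `TA-`, `T--`).
#' @examples
#' find_stop("ATGAAATAA", 0)   # end_offset 8, "TAA"
#' @export
find_stop <- function(sense_sequence, start_offset,
                      downstream_gene_boundary = NULL, code = genetic_code()) {
  n <- nchar(sense_sequence)
  full <- NULL
  i <- start_offset
  while (i + 3 <= n) {
    codon <- substr(sense_sequence, i + 1, i + 3)
    if (codon %in% code$stops) {
      full <- list(end_offset = i + 2, stop = codon)
      break
    }
    i <- i + 3
  }
  ds <- downstream_gene_boundary
  stop_clear <- !is.null(full) &&
    (is.null(ds) || full$end_offset + 1 < ds)  # last base strictly upstream of ds
  if (stop_clear) return(full)
  if (!is.null(ds)) {
    trunc <- truncated_stop(sense_sequence, start_offset, ds)
    if (!is.null(trunc)) return(trunc)
  }
  if (!is.null(full)) return(full)
  abort("open ORF: neither a full nor a truncated stop codon is constructible")
}

truncated_stop <- function(sense_sequence, start_offset, ds) {
  end1 <- ds - 1L                         # 1-based last base before downstream gene
  len <- end1 - (start_offset + 1L) + 1L
  if (len < 3) return(NULL)
  r <- len %% 3L
  if (r == 1L && substr(sense_sequence, end1, end1) == "T") {
    return(list(end_offset = end1 - 1L, stop = "T--"))
  }
  if (r == 2L && substr(sense_sequence, end1 - 1L, end1) == "TA") {
    return(list(end_offset = end1 - 1L, stop = "TA-"))
  }
  NULL
}

#' Refine protein-coding gene boundaries on an annotated genome
#'
#' For each PCG hint (by default the record's own PCG features, which may be
#' approximate), finds the first legitimate in-frame start codon not located
#' inside an upstream same-strand gene, extends the reading frame to the
#' first in-frame stop, and applies the truncated-stop rule against the next
#' same-strand gene (see [find_stop()]). Minority-strand genes are processed
#' on the reverse complement.
#'
#' @param record A `mito_genome` with a sequence and feature annotations
#'   (non-PCG features supply the boundaries truncation is tested against).
#' @param code A [genetic_code()].
#' @param window Search-window width in bp: candidate starts are scanned from
#'   `window/2` bp upstream to `window/2` bp downstream of each hint start.
#' @param hints Optional feature table of approximate PCG regions overriding
#'   the record's PCG rows.
#' @return A tibble of PCG calls: `gene`, `strand`, `start`, `end` (genome
#'   coordinates), `start_codon`, `stop_codon`, `codon_count` (sense codons,
#'   stop excluded), and `note` (`NA` on success, the failure message
#'   otherwise — unresolved genes are reported, not fatal).
#' @export
annotate_pcgs <- function(record, code = genetic_code(), window = 60,
                          hints = NULL) {
  seq <- require_sequence(record)
  L <- record$length
  feats <- record$features
  if (is.null(hints)) hints <- dplyr::filter(feats, .data$class == "PCG")
  hints <- validate_features(hints, L)
  if (nrow(hints) == 0) abort("no PCG hints to annotate")
  rc <- reverse_complement(seq)
  half <- as.integer(window %/% 2)

  call_one <- function(gene, strand, hstart, hend) {
    # transform to sense coordinates: N-strand genes analysed on the
    # reverse complement, position p -> L - p + 1
    if (strand == "J") {
      sseq <- seq; s1 <- hstart; s2 <- hend
      same <- feats[feats$strand == "J" & feats$gene != gene, ]
      starts_same <- same$start
    } else {
      sseq <- rc; s1 <- L - hend + 1L; s2 <- L - hstart + 1L
      same <- feats[feats$strand == "N" & feats$gene != gene, ]
      starts_same <- L - same$end + 1L
    }
    # search may not reach into a strictly upstream same-strand gene (an
    # upstream gene overlapping the hinted start does not cap the scan: the
    # canonical atp6 start lies inside atp8)
    lo <- pcg_scan_lo(feats, L, gene, strand, s1, half)
    hi <- min(s1 + half, nchar(sseq) - 2L)
    # next same-strand gene downstream of the hinted start
    down_starts <- starts_same[starts_same > s1]
    ds_genome <- if (length(down_starts)) min(down_starts) else NULL

    offsets <- seq(lo, hi) - lo          # 0-based within the slice
    slice_end <- min(nchar(sseq),
                     max(s2, if (is.null(ds_genome)) 0L else ds_genome) + 600L)
    slice <- substr(sseq, lo, slice_end)
    ds <- if (is.null(ds_genome)) NULL else ds_genome - lo + 1L
    over <- code$overrides[[gene]]
    for (o in offsets) {
      codon <- substr(slice, o + 1, o + 3)
      if (!codon %in% c(code$starts, over)) next
      stop_call <- tryCatch(find_stop(slice, o, ds, code), error = function(e) NULL)
      if (is.null(stop_call)) next
      # the ORF must span the hinted region, otherwise the hit is spurious
      if (stop_call$end_offset + lo < s2 - window) next
      sense_start <- lo + o
      sense_end <- lo + stop_call$end_offset
      if (strand == "J") {
        gstart <- sense_start; gend <- sense_end
      } else {
        gstart <- L - sense_end + 1L; gend <- L - sense_start + 1L
      }
      len <- sense_end - sense_start + 1L
      return(tibble(gene = gene, strand = strand,
                    start = as.integer(gstart), end = as.integer(gend),
                    start_codon = codon, stop_codon = stop_call$stop,
                    codon_count = (len - stop_token_length(stop_call$stop)) %/% 3L,
                    note = NA_character_))
    }
    abort("no legitimate start opens a reading frame spanning the hinted region")
  }

  dplyr::bind_rows(purrr::pmap(
    list(hints$gene, hints$strand, hints$start, hints$end),
    function(g, st, s, e) {
      tryCatch(call_one(g, st, s, e), error = function(err) {
        tibble(gene = g, strand = st, start = NA_integer_, end = NA_integer_,
               start_codon = NA_character_, stop_codon = NA_character_,
               codon_count = NA_integer_, note = conditionMessage(err))
      })
    }))
}

#' Total sense codons over the protein-coding genes
#'
#' Sums `(length - stop_length) / 3` over all PCGs, where the stop length is
#' 3 for TAA/TAG, 2 for TA- and 1 for T--. Works directly from a printed
#' annotation table: coordinates plus stop tokens suffice, no sequence is
#' needed.
#'
#' @param x A `mito_genome`, a feature table with PCG rows, or the output of
#'   [annotate_pcgs()].
#' @param genome_length Needed only for origin-spanning genes in a bare
#'   table.
#' @return Integer count of sense codons, stop codons excluded.
#' @export
count_codons <- function(x, genome_length = NULL) {
  if (inherits(x, "mito_genome")) {
    genome_length <- x$length
    x <- x$features
  }
  x <- as_tibble(x)
  pcgs <- if ("class" %in% names(x)) dplyr::filter(x, .data$class == "PCG") else x
  if (anyNA(pcgs$stop_codon)) {
    abort(paste0("missing stop codon for: ",
                 paste(pcgs$gene[is.na(pcgs$stop_codon)], collapse = ", ")))
  }
  len <- feature_length(pcgs$start, pcgs$end, genome_length)
  sense <- len - stop_token_length(pcgs$stop_codon)
  bad <- sense %% 3L != 0L
  if (any(bad)) {
    abort(paste0("sense length not divisible by 3 for: ",
                 paste(pcgs$gene[bad], collapse = ", ")))
  }
  sum(sense %/% 3L)
}
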