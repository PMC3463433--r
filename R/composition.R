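# Nucleotide composition, strand skews, codon usage and RSCU.

#' Base composition and strand skews of a sequence
#'
#' Percentages of A/C/G/T, A+T content, and the strand asymmetry statistics
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C). `N` and other
#' ambiguity codes are excluded from all denominators so percentages stay
#' comparable across assemblies of different completeness. Undefined skews
#' (zero denominator) are reported as `NaN`, never as zero.
#'
#' @param sequence Nucleotide string.
#' @param region Label for the output row.
#' @return A one-row tibble: `region`, `n` (unambiguous bases), `A`, `C`,
#'   `G`, `T`, `AT_content` (percent), `AT_skew`, `GC_skew`.
#' @examples
#' base_composition("AAAT")$AT_skew   # (3 - 1)/(3 + 1) = 0.5
#' @export
base_composition <- function(sequence, region = "sequence") {
  if (is.null(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0) {
    abort("base_composition requires a nonempty sequence")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  a <- sum(chars == "A"); c_ <- sum(chars == "C")
  g <- sum(chars == "G"); t <- sum(chars == "T")
  n <- a + c_ + g + t
  if (n == 0) abort("sequence has no unambiguous A/C/G/T residues")
  skew <- function(x, y) if (x + y == 0) NaN else (x - y) / (x + y)
  tibble(
    region = region, n = n,
    A = 100 * a / n, C = 100 * c_ / n, G = 100 * g / n, T = 100 * t / n,
    AT_content = 100 * (a + t) / n,
    AT_skew = skew(a, t), GC_skew = skew(g, c_)
  )
}

#' Sense sequences of the protein-coding genes
#'
#' Extracts each PCG's sense-strand sequence (reverse-complemented for
#' minority-strand genes), optionally trimmed of its stop codon according to
#' the annotated stop token (3 bases for TAA/TAG, 2 for TA-, 1 for T--).
#'
#' @param record A `mito_genome` with a sequence and PCG annotations.
#' @param stop_trimmed Trim annotated stop codons?
#' @return Named character vector of sense sequences in annotation order.
#' @export
pcg_sense_sequences <- function(record, stop_trimmed = TRUE) {
  seq <- require_sequence(record)
  pcgs <- dplyr::filter(record$features, .data$class == "PCG")
  out <- purrr::pmap_chr(pcgs[c("gene", "strand", "start", "end", "stop_codon")],
    function(gene, strand, start, end, stop_codon) {
      s <- feature_sequence(record, start, end, strand)
      if (stop_trimmed) {
        if (is.na(stop_codon)) {
          abort(paste0("gene ", gene, " has no annotated stop codon to trim"))
        }
        s <- substr(s, 1, nchar(s) - stop_token_length(stop_codon))
      }
      s
    })
  stats::setNames(out, pcgs$gene)
}

stop_token_length <- function(token) {
  len <- c(TAA = 3L, TAG = 3L, `TA-` = 2L, `T--` = 1L)[token]
  if (anyNA(len)) abort(paste0("unknown stop token: ", paste(token[is.na(len)], collapse = ", ")))
  unname(len)
}

#' Composition at each codon position
#'
#' Concatenates stop-trimmed sense coding sequences and computes
#' [base_composition()] separately over the 1st, 2nd and 3rd position of
#' every codon.
#'
#' @param sense_seqs Named character vector of stop-trimmed sense sequences
#'   (e.g. from [pcg_sense_sequences()]), or a `mito_genome` from which they
#'   are extracted.
#' @return A three-row tibble, one per codon position.
#' @export
composition_by_codon_position <- function(sense_seqs) {
  if (inherits(sense_seqs, "mito_genome")) sense_seqs <- pcg_sense_sequences(sense_seqs)
  bad <- nchar(sense_seqs) %% 3 != 0
  if (any(bad)) {
    abort(paste0("coding length not divisible by 3 for: ",
                 paste(names(sense_seqs)[bad], collapse = ", ")))
  }
  chars <- strsplit(paste(sense_seqs, collapse = ""), "")[[1]]
  pos <- rep_len(1:3, length(chars))
  dplyr::bind_rows(lapply(1:3, function(p) {
    base_composition(paste(chars[pos == p], collapse = ""),
                     region = paste0("codon_position_", p))
  }))
}

#' Table-style composition summary of a genome
#'
#' Reproduces the customary per-region composition table for an annotated
#' mitogenome: whole genome (majority strand), protein-coding genes (sense
#' sequences, stops excluded), the three codon positions, tRNA genes, each
#' rRNA gene, and the A+T-rich region.
#'
#' @param record An annotated `mito_genome` with a sequence.
#' @return A tibble with one [base_composition()] row per region.
#' @export
composition_summary <- function(record) {
  seq <- require_sequence(record)
  feats <- record$features
  seq_of <- function(rows) {
    paste(purrr::pmap_chr(rows[c("start", "end", "strand")],
                          function(start, end, strand)
                            feature_sequence(record, start, end, strand)),
          collapse = "")
  }
  sense <- pcg_sense_sequences(record, stop_trimmed = TRUE)
  rows <- list(
    base_composition(seq, "whole_genome"),
    base_composition(paste(sense, collapse = ""), "PCGs"),
    composition_by_codon_position(sense)
  )
  trnas <- dplyr::filter(feats, .data$class == "tRNA")
  if (nrow(trnas) > 0) rows <- c(rows, list(base_composition(seq_of(trnas), "tRNAs")))
  for (r in c("rrnL", "rrnS")) {
    row <- dplyr::filter(feats, .data$gene == r)
    if (nrow(row) == 1) rows <- c(rows, list(base_composition(seq_of(row), r)))
  }
  ctrl <- dplyr::filter(feats, .data$class == "control")
  if (nrow(ctrl) == 1) rows <- c(rows, list(base_composition(seq_of(ctrl), "at_rich_region")))
  dplyr::bind_rows(rows)
}

# codon usage -----------------------------------------------------------------

#' Sense codons of the invertebrate mitochondrial code, with families
#'
#' The 62 sense codons of translation table 5 (TAA/TAG are the only stops;
#' AGA/AGG encode Ser, TGA Trp, ATA Met). Synonymous families follow the
#' customary mitochondrial presentation with Leu and Ser each split in two:
#' Leu(UUR), Leu(CUN), Ser(UCN), Ser(AGN).
#'
#' @return A tibble: `codon` (DNA), `codon_rna`, `amino_acid`, `family`,
#'   `family_size`.
#' @export
codon_families <- function() {
  code <- genetic_code()
  codons <- names(code$map)[!names(code$map) %in% code$stops]
  aa <- unname(code$map[codons])
  family <- dplyr::case_when(
    codons %in% c("TTA", "TTG") ~ "Leu(UUR)",
    substr(codons, 1, 2) == "CT" ~ "Leu(CUN)",
    substr(codons, 1, 2) == "TC" ~ "Ser(UCN)",
    substr(codons, 1, 2) == "AG" ~ "Ser(AGN)",
    TRUE ~ aa
  )
  out <- tibble(codon = codons, codon_rna = gsub("T", "U", codons),
                amino_acid = aa, family = family)
  out |>
    dplyr::add_count(.data$family, name = "family_size") |>
    dplyr::arrange(.data$family, .data$codon)
}

#' Codon usage of the protein-coding genes
#'
#' Counts every sense codon over stop-trimmed sense coding sequences and
#' attaches codons-per-thousand and RSCU. Internal stop codons (which a
#' correctly annotated gene set cannot contain) raise an error naming the
#' offending count.
#'
#' @param x A `mito_genome`, or a character vector of stop-trimmed sense
#'   sequences whose lengths are multiples of 3.
#' @return A [codon_families()] tibble with `count`, `per_thousand` and
#'   `rscu` columns; codons absent from the input have `count` 0 (see
#'   [absent_codons()]).
#' @export
codon_usage <- function(x) {
  if (inherits(x, "mito_genome")) x <- pcg_sense_sequences(x)
  bad <- nchar(x) %% 3 != 0
  if (any(bad)) {
    abort(paste0("coding length not divisible by 3 for: ",
                 paste(if (is.null(names(x))) which(bad) else names(x)[bad], collapse = ", ")))
  }
  concat <- paste(x, collapse = "")
  codons <- substring(concat, seq(1, nchar(concat), by = 3), seq(3, nchar(concat), by = 3))
  counts <- table(codons)
  tab <- codon_families()
  stops_seen <- intersect(names(counts), genetic_code()$stops)
  if (length(stops_seen) > 0) {
    abort(paste0("internal stop codon(s) in coding sequence: ",
                 paste(stops_seen, collapse = ", ")))
  }
  tab$count <- as.integer(counts[tab$codon])
  tab$count[is.na(tab$count)] <- 0L
  tab$per_thousand <- 1000 * tab$count / sum(tab$count)
  rscu(tab)
}

#' Relative synonymous codon usage
#'
#' RSCU(codon) = count(codon) x family_size / sum of counts in the codon's
#' synonymous family: the observed count relative to the expectation under
#' uniform usage within the family. Zero-count families yield `NaN`.
#'
#' @param table A codon table with `codon`, `family`, `family_size`, `count`.
#' @return The table with an `rscu` column (re)computed.
#' @export
rscu <- function(table) {
  table |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(rscu = if (sum(.data$count) == 0) NaN else
                    .data$count * .data$family_size / sum(.data$count)) |>
    dplyr::ungroup()
}

#' @rdname codon_usage
#' @param table A codon usage table.
#' @export
absent_codons <- function(table) table$codon_rna[table$count == 0]

#' AT/GC skew pairs for a set of genomes
#'
#' One `(AT_skew, GC_skew)` point per genome, computed from each genome's
#' majority-strand sequence — the coordinates of the classic skew scatter
#' plot used to compare mitogenomes across taxa.
#'
#' @param genomes A list of `mito_genome` objects (or a named character
#'   vector of sequences).
#' @return A tibble: `id`, `AT_skew`, `GC_skew`, `AT_content`.
#' @export
skew_scatter <- function(genomes) {
  if (is.character(genomes)) {
    ids <- if (is.null(names(genomes))) as.character(seq_along(genomes)) else names(genomes)
    seqs <- unname(genomes)
  } else {
    if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
    ids <- purrr::map_chr(genomes, "id")
    seqs <- purrr::map_chr(genomes, require_sequence)
  }
  dplyr::bind_rows(purrr::map2(seqs, ids, function(s, id) {
    comp <- base_composition(s, id)
    tibble(id = id, AT_skew = comp$AT_skew, GC_skew = comp$GC_skew,
           AT_content = comp$AT_content)
  }))
}

#' Skew scatter plot
#'
#' @param data Output of [skew_scatter()].
#' @param label Label points with genome ids?
#' @return A ggplot.
#' @export
plot_skew_scatter <- function(data, label = TRUE) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$AT_skew, y = .data$GC_skew)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "AT-skew = (A - T)/(A + T)", y = "GC-skew = (G - C)/(G + C)")
  if (label) p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$id),
                                         vjust = -0.8, size = 3)
  p
}

#' RSCU bar plot by synonymous family
#'
#' @param table Output of [codon_usage()].
#' @return A ggplot faceted by codon family.
#' @export
plot_rscu <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$codon_rna, y = .data$rscu)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
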