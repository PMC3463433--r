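# Combined per-genome analysis report: annotation table, composition,
# overlap/spacer accounting, gene order vs a reference, control-region
# repeats and motifs, codon usage.

#' Run the full architecture report for one genome
#'
#' Composes the package's analyses into a single report object. With only a
#' feature table (coordinate-only mode) the architecture sections are
#' computed and all sequence-dependent sections are marked skipped; with a
#' sequence, every section is populated. The report contains nothing that
#' the individual functions do not themselves compute.
#'
#' @param table Path to a feature-table TSV, or a `mito_genome`.
#' @param fasta Optional path to the genome FASTA.
#' @param reference Reference gene order for rearrangement classification:
#'   `"ancestral"`, `"ditrysian"`, a gene-order tibble, or `NULL` to skip.
#' @param out_dir Optional directory; when given, every section is written
#'   as TSV plus a JSON mirror of the whole report.
#' @param motif Control-region motif searched (with up to 1 mismatch), and
#' @param polyt_min minimum poly-T run, both from the conserved ditrysian
#'   control-region signature.
#' @return An object of class `mito_report`: a list of tibbles (or the
#'   string `"skipped"` for unavailable sections) plus a `summary` row.
#' @export
run_full_report <- function(table, fasta = NULL, reference = "ancestral",
                            out_dir = NULL, motif = "ATAGA", polyt_min = 16) {
  record <- if (inherits(table, "mito_genome")) table else read_feature_table(table)
  if (!is.null(fasta)) {
    seq_rec <- read_fasta(fasta)
    if (genome_length(seq_rec) != record$length) {
      abort(paste0("FASTA length ", genome_length(seq_rec),
                   " does not match feature-table genome length ", record$length))
    }
    record <- mito_genome(record$features, sequence = seq_rec$sequence,
                          id = record$id)
  }
  has_seq <- !is.null(record$sequence)

  overlaps <- find_overlaps(record)
  spacers <- find_intergenic_spacers(record)
  order <- extract_gene_order(record)
  events <- if (is.null(reference)) "skipped" else {
    ref <- if (is.character(reference)) ref_gene_order(reference) else as_tibble(reference)
    classify_rearrangements(order, ref)
  }
  ctrl <- dplyr::filter(record$features, .data$class == "control")
  cr_seq <- if (has_seq && nrow(ctrl) == 1) {
    feature_sequence(record, ctrl$start[1], ctrl$end[1], ctrl$strand[1])
  } else NULL

  report <- structure(list(
    id = record$id,
    features = record$features,
    composition = if (has_seq) composition_summary(record) else "skipped",
    codon_usage = if (has_seq) codon_usage(record) else "skipped",
    overlaps = overlaps,
    spacers = spacers,
    gene_order = order,
    rearrangements = events,
    repeats = if (!is.null(cr_seq)) find_tandem_repeats(cr_seq) else "skipped",
    motifs = if (!is.null(cr_seq)) {
      dplyr::bind_rows(find_motif(cr_seq, motif, max_mismatch = 1),
                       find_poly_t(cr_seq, polyt_min))
    } else "skipped",
    summary = tibble(
      id = record$id, genome_length = record$length,
      n_features = nrow(record$features),
      overlap_total = sum(overlaps$length),
      spacer_total = sum(spacers$length),
      n_rearrangements = if (is.character(events)) NA_integer_ else nrow(events),
      checksum_ok = architecture_checksum(record) == record$length
    )
  ), class = "mito_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sections <- c("features", "composition", "codon_usage", "overlaps",
                "spacers", "gene_order", "rearrangements", "repeats",
                "motifs", "summary")
  json <- list(id = report$id)
  for (s in sections) {
    x <- report[[s]]
    if (is.character(x) && length(x) == 1) { json[[s]] <- x; next }
    if (identical(s, "features")) {
      write_feature_table(x, file.path(out_dir, "features.tsv"))
    } else {
      utils::write.table(x, file.path(out_dir, paste0(s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
    json[[s]] <- x
  }
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

#' @export
print.mito_report <- function(x, ...) {
  cat("<mito_report> ", x$id, "\n", sep = "")
  print(x$summary)
  if (!is.character(x$rearrangements) && nrow(x$rearrangements) > 0) {
    cat("rearrangements vs reference:\n"); print(x$rearrangements)
  }
  invisible(x)
}

#' @method tidy mito_report
#' @export
tidy.mito_report <- function(x, ...) x$features

#' @method glance mito_report
#' @export
glance.mito_report <- function(x, ...) x$summary

#' Map of a genome's feature architecture
#'
#' Linear map of the annotated features coloured by class, majority-strand
#' genes above the axis and minority-strand genes below.
#'
#' @param object A `mito_genome`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mito_genome
#' @export
autoplot.mito_genome <- function(object, ...) {
  feats <- feature_lengths(object) |>
    dplyr::mutate(ymin = ifelse(.data$strand == "J", 0.05, -0.95),
                  ymax = ifelse(.data$strand == "J", 0.95, -0.05))
  ggplot2::ggplot(feats) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$class)) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_y_continuous(breaks = c(-0.5, 0.5), labels = c("N", "J"),
                                limits = c(-1, 1)) +
    ggplot2::labs(x = "position (bp)", y = "strand", fill = NULL,
                  title = object$id)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
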