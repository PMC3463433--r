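#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# canonical gene vocabulary ---------------------------------------------------

PCG_GENES <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
               "nad5", "nad4", "nad4L", "nad6", "cob", "nad1")

TRNA_GENES <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL(UUR)",
                "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS(AGN)",
                "trnE", "trnF", "trnH", "trnT", "trnP", "trnS(UCN)",
                "trnL(CUN)", "trnV")

RRNA_GENES <- c("rrnL", "rrnS")

CONTROL_NAMES <- c("at_rich_region", "A+T-rich region", "D-loop", "control_region")

FEATURE_COLS <- c("gene", "class", "strand", "start", "end",
                  "start_codon", "stop_codon", "anticodon")

STOP_TOKENS <- c("TAA", "TAG", "TA-", "T--")

#' Infer the feature class from a canonical gene name
#'
#' `trn*` names map to `"tRNA"`, `rrn*` to `"rRNA"`, control-region aliases to
#' `"control"`, and the 13 canonical protein-coding gene names to `"PCG"`.
#'
#' @param gene Character vector of gene names.
#' @return Character vector of classes (`NA` for unrecognised names).
#' @export
infer_feature_class <- function(gene) {
  dplyr::case_when(
    gene %in% CONTROL_NAMES ~ "control",
    grepl("^trn", gene) ~ "tRNA",
    grepl("^rrn", gene) ~ "rRNA",
    gene %in% PCG_GENES ~ "PCG",
    TRUE ~ NA_character_
  )
}

# feature tibble validation ---------------------------------------------------

empty_features <- function() {
  tibble(gene = character(), class = character(), strand = character(),
         start = integer(), end = integer(), start_codon = character(),
         stop_codon = character(), anticodon = character())
}

#' Validate a feature annotation table
#'
#' Checks the column contract used throughout the package: canonical columns,
#' strand in `{J, N}`, class in `{PCG, tRNA, rRNA, control}`, coordinates
#' inside `[1, genome_length]`, start/stop codons only on PCG rows and
#' anticodons only on tRNA rows. Stop codons must be one of `TAA`, `TAG`,
#' `TA-`, `T--`.
#'
#' @param features A data frame of feature annotations.
#' @param genome_length Genome length in bp, or `NULL` to skip range checks.
#' @return The features as a tibble (invisibly usable in pipes), with columns
#'   coerced to their canonical types.
#' @export
validate_features <- function(features, genome_length = NULL) {
  features <- as_tibble(features)
  missing_cols <- setdiff(c("gene", "strand", "start", "end"), names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(FEATURE_COLS, names(features))) {
    features[[col]] <- if (col == "class") infer_feature_class(features$gene) else NA_character_
  }
  features <- features[FEATURE_COLS]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    features[[col]] <- as.character(features[[col]])
    features[[col]][!is.na(features[[col]]) & features[[col]] == ""] <- NA_character_
  }
  features$class[is.na(features$class)] <- infer_feature_class(features$gene[is.na(features$class)])

  check_rows <- function(bad, what) {
    if (any(bad)) {
      abort(paste0("invalid feature table: ", what,
                   " in row(s) ", paste(which(bad), collapse = ", ")))
    }
  }
  check_rows(is.na(features$gene) | features$gene == "", "missing gene name")
  check_rows(!features$strand %in% c("J", "N"), "strand must be 'J' or 'N'")
  check_rows(!features$class %in% c("PCG", "tRNA", "rRNA", "control"),
             "class must be one of PCG, tRNA, rRNA, control")
  check_rows(is.na(features$start) | is.na(features$end) |
               features$start < 1 | features$end < 1,
             "coordinates must be positive integers")
  if (!is.null(genome_length)) {
    check_rows(features$start > genome_length | features$end > genome_length,
               paste0("coordinates exceed genome length ", genome_length))
  }
  check_rows(!is.na(features$stop_codon) & !features$stop_codon %in% STOP_TOKENS,
             "stop codon must be TAA, TAG, TA- or T--")
  check_rows((!is.na(features$start_codon) | !is.na(features$stop_codon)) &
               features$class != "PCG",
             "start/stop codons are only valid on PCG rows")
  check_rows(!is.na(features$anticodon) & features$class != "tRNA",
             "anticodons are only valid on tRNA rows")
  features
}

# the genome record -----------------------------------------------------------

#' Build a circular mitogenome record
#'
#' A `mito_genome` bundles an (optional) majority-strand sequence with an
#' ordered feature table. Features may exist without a sequence
#' (coordinate-only mode, e.g. when working from a published annotation table
#' alone). Coordinates are 1-based inclusive throughout; a feature with
#' `end < start` wraps the circular origin.
#'
#' @param features Feature table (see [validate_features()]).
#' @param sequence Majority-strand nucleotide string over `A,C,G,T,N`, or
#'   `NULL` for coordinate-only records.
#' @param id Genome identifier.
#' @param genome_length Length in bp. Defaults to `nchar(sequence)` when a
#'   sequence is given, otherwise to `max(end)` over the features.
#' @param circular Logical flag; complete mitogenomes are circular.
#' @return An object of class `mito_genome`.
#' @examples
#' feats <- tibble::tibble(gene = c("trnI", "trnQ"), strand = c("J", "N"),
#'                         start = c(1L, 66L), end = c(65L, 134L))
#' g <- mito_genome(feats, id = "toy")
#' genome_length(g)
#' @export
mito_genome <- function(features, sequence = NULL, id = "genome",
                        genome_length = NULL, circular = TRUE) {
  if (!is.null(sequence)) {
    sequence <- normalize_sequence(sequence)
    if (is.null(genome_length)) genome_length <- nchar(sequence)
    if (genome_length != nchar(sequence)) {
      abort("genome_length does not equal the sequence length")
    }
  }
  features <- validate_features(features, genome_length)
  if (is.null(genome_length)) {
    genome_length <- if (nrow(features) > 0) max(features$end) else 0L
    features <- validate_features(features, genome_length)
  }
  # linearized order: non-wrapping features by start; origin-spanning last
  wraps <- features$end < features$start
  features <- dplyr::bind_rows(
    dplyr::arrange(features[!wraps, ], .data$start),
    features[wraps, ]
  )
  structure(
    list(id = id, sequence = sequence, length = as.integer(genome_length),
         circular = circular, features = features),
    class = "mito_genome"
  )
}

normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", sequence)
  if (nchar(bad) > 0) {
    abort(paste0("sequence contains non-IUPAC residues: ",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  sequence
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$id, ": ", x$length, " bp",
      if (x$circular) " (circular)", ", ",
      nrow(x$features), " features",
      if (is.null(x$sequence)) ", coordinate-only", "\n", sep = "")
  if (nrow(x$features) > 0) print(x$features, n = 5)
  invisible(x)
}

#' @export
genome_length <- function(x) UseMethod("genome_length")

#' @export
genome_length.mito_genome <- function(x) x$length

#' Extract the feature table of a genome record
#'
#' @param x A `mito_genome`.
#' @param ... Unused.
#' @return The feature tibble.
#' @method tidy mito_genome
#' @export
tidy.mito_genome <- function(x, ...) x$features

#' One-row summary of a genome record
#'
#' @param x A `mito_genome`.
#' @param ... Unused.
#' @method glance mito_genome
#' @export
glance.mito_genome <- function(x, ...) {
  tibble(
    id = x$id,
    length = x$length,
    circular = x$circular,
    has_sequence = !is.null(x$sequence),
    n_features = nrow(x$features),
    n_pcg = sum(x$features$class == "PCG"),
    n_trna = sum(x$features$class == "tRNA"),
    n_rrna = sum(x$features$class == "rRNA")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# coordinate arithmetic -------------------------------------------------------

#' Inclusive length of a feature on a circular genome
#'
#' For ordinary features this is `end - start + 1`; a feature with
#' `end < start` spans the origin and has length
#' `(genome_length - start + 1) + end`.
#'
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @param genome_length Genome length in bp (required for origin-spanning
#'   features).
#' @return Integer vector of lengths in bp.
#' @examples
#' feature_length(12628, 13962)           # 1335
#' feature_length(16170, 4, 16173)        # 8, wraps the origin
#' @export
feature_length <- function(start, end, genome_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  wraps <- end < start
  if (any(wraps) && is.null(genome_length)) {
    abort("genome_length is required for origin-spanning features")
  }
  out <- end - start + 1L
  if (any(wraps)) out[wraps] <- (genome_length - start[wraps] + 1L) + end[wraps]
  out
}

#' Per-feature lengths of a record's annotations
#'
#' @param x A `mito_genome` or a feature table.
#' @param genome_length Required when `x` is a bare table containing
#'   origin-spanning features.
#' @return The feature tibble with a `length` column appended.
#' @export
feature_lengths <- function(x, genome_length = NULL) {
  if (inherits(x, "mito_genome")) {
    genome_length <- x$length
    x <- x$features
  }
  x <- as_tibble(x)
  dplyr::mutate(x, length = feature_length(.data$start, .data$end, genome_length))
}

# sequence helpers ------------------------------------------------------------

#' Reverse complement of a nucleotide string
#' @param sequence Nucleotide string.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Extract a feature's majority-strand or sense sequence
#'
#' @param record A `mito_genome` carrying a sequence.
#' @param start,end 1-based inclusive coordinates; `end < start` wraps the
#'   origin.
#' @param strand `"J"` returns the majority-strand slice; `"N"` returns its
#'   reverse complement (the gene's sense sequence).
#' @return Nucleotide string.
#' @export
feature_sequence <- function(record, start, end, strand = "J") {
  seq <- require_sequence(record)
  s <- if (end >= start) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, record$length), substr(seq, 1, end))
  }
  if (strand == "N") reverse_complement(s) else s
}

require_sequence <- function(record) {
  if (is.null(record$sequence)) abort("sequence required: this record is coordinate-only")
  record$sequence
}

#' Rotate a circular genome so a chosen gene starts at position 1
#'
#' Published insect mitogenome annotations conventionally linearize the circle
#' at the first base of `trnI`. Records annotated from a different origin (or
#' whose control region wraps the origin) are rotated so coordinates match
#' that convention.
#'
#' @param record A `mito_genome` with a sequence.
#' @param origin_gene Gene whose first base becomes position 1.
#' @return A new `mito_genome`.
#' @export
relinearize <- function(record, origin_gene = "trnI") {
  seq <- require_sequence(record)
  feats <- record$features
  idx <- which(feats$gene == origin_gene)
  if (length(idx) != 1) abort(paste0("origin gene '", origin_gene, "' not found exactly once"))
  shift <- feats$start[idx] - 1L
  if (shift == 0L) return(record)
  L <- record$length
  new_seq <- paste0(substr(seq, shift + 1L, L), substr(seq, 1L, shift))
  rot <- function(p) ((p - 1L - shift) %% L) + 1L
  feats$start <- rot(feats$start)
  feats$end <- rot(feats$end)
  mito_genome(feats, sequence = new_seq, id = record$id, circular = record$circular)
}
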