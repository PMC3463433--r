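# Readers and writers for the feature-table TSV, FASTA, and GenBank flat files.

#' Read a gene feature table
#'
#' The interchange format is a UTF-8 tab-separated file with header
#' `gene  class  strand  start  end  start_codon  stop_codon  anticodon`;
#' optional cells may be empty. Truncated stop codons are written with
#' trailing hyphens exactly as `TA-` and `T--`. Strand uses the majority (J)
#' / minority (N) vocabulary of insect mitogenomics.
#'
#' @param path Path to the TSV file.
#' @param genome_length Genome length in bp; when `NULL` it is inferred as
#'   `max(end)` over the features (for complete annotations whose last
#'   feature, conventionally the A+T-rich region, reaches the final base).
#' @param id Genome identifier; defaults to the file name.
#' @return A coordinate-only [mito_genome()].
#' @export
read_feature_table <- function(path, genome_length = NULL, id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) abort(paste0("empty file (no header): ", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!all(c("gene", "strand", "start", "end") %in% header)) {
    abort("feature table header must contain at least gene, strand, start, end")
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    length(cells) <- length(header)  # pad trailing empties
    if (sum(!is.na(cells) & cells != "") == 0) return(NULL)
    row <- as.list(cells)
    names(row) <- header
    for (col in c("start", "end")) {
      v <- suppressWarnings(as.integer(row[[col]]))
      if (is.na(v)) {
        abort(paste0("malformed row at line ", i, " of ", basename(path),
                     ": '", col, "' is not an integer"))
      }
      row[[col]] <- v
    }
    as_tibble(row)
  })
  features <- dplyr::bind_rows(rows)
  if (nrow(features) == 0) features <- empty_features()
  mito_genome(features, id = id, genome_length = genome_length)
}

#' Write a gene feature table
#'
#' Inverse of [read_feature_table()]: bit-exact round trips, with empty
#' strings for absent optional cells and truncated stops spelled `TA-`/`T--`.
#'
#' @param x A `mito_genome` or a feature tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  features <- if (inherits(x, "mito_genome")) x$features else validate_features(x)
  out <- features[FEATURE_COLS]
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  rows <- sub("\t+$", "", apply(out, 1, paste, collapse = "\t"))
  lines <- c(paste(FEATURE_COLS, collapse = "\t"), rows)
  writeLines(lines, path, useBytes = TRUE)
  invisible(x)
}

#' Read a genome sequence from FASTA
#'
#' @param path FASTA file with a single record. Lowercase residues are
#'   uppercased on load; residues outside the IUPAC alphabet are rejected.
#' @param id Identifier override; defaults to the FASTA header word.
#' @return A `mito_genome` with a sequence and no features.
#' @export
read_fasta <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1) abort(paste0("expected a single FASTA record in ", path))
  if (is.null(id)) id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  mito_genome(empty_features(), sequence = as.character(set[[1]]), id = id)
}

#' Write a genome sequence to FASTA
#'
#' @param record A `mito_genome` with a sequence.
#' @param path Output path.
#' @export
write_fasta <- function(record, path) {
  seq <- require_sequence(record)
  set <- Biostrings::DNAStringSet(seq)
  names(set) <- record$id
  Biostrings::writeXStringSet(set, path)
  invisible(record)
}

# GenBank flat file (read-only) ----------------------------------------------

#' Read a GenBank flat file into a genome record
#'
#' A minimal reader for single-record GenBank flat files as distributed for
#' mitochondrial genomes: `CDS`, `tRNA`, `rRNA` and `misc_feature`/`D_loop`
#' features are mapped to the package's PCG/tRNA/rRNA/control classes,
#' `complement(a..b)` locations become strand `N`, and a two-segment
#' `join(a..L,1..b)` is read as an origin-spanning feature. Gene names are
#' taken from the `/gene` qualifier (falling back to `/product`). Records
#' whose annotation origin is not the first base of `trnI` are rotated to
#' that convention when a sequence is present.
#'
#' @param path GenBank flat file.
#' @param relinearize_at Gene rotated to position 1 on load (`NULL` to keep
#'   the file's own origin).
#' @return A `mito_genome`.
#' @export
read_genbank <- function(path, relinearize_at = "trnI") {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  gb_length <- if (length(locus) > 0) {
    as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1]))
  } else NULL
  id <- if (length(locus) > 0) strsplit(locus[1], "\\s+")[[1]][2] else "genbank"

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  sequence <- NULL
  if (length(origin_start) == 1 && origin_start < length(lines)) {
    seq_lines <- lines[(origin_start + 1):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) == 0) sequence <- NULL
  }

  features <- empty_features()
  if (length(feat_start) == 1) {
    end_block <- if (length(origin_start) == 1) origin_start - 1 else length(lines)
    block <- lines[(feat_start + 1):end_block]
    features <- parse_genbank_features(block)
  }
  record <- mito_genome(features, sequence = sequence, id = id,
                        genome_length = if (is.null(sequence)) gb_length else NULL)
  if (!is.null(relinearize_at) && !is.null(sequence) &&
      relinearize_at %in% record$features$gene &&
      record$features$start[record$features$gene == relinearize_at] != 1L) {
    record <- relinearize(record, relinearize_at)
  }
  record
}

parse_genbank_features <- function(block) {
  # a feature key starts at column 6; qualifier/continuation lines at column 22
  key_lines <- grep("^ {5}\\S", block)
  keep_keys <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                 misc_feature = "control", D_loop = "control",
                 D.loop = "control")
  rows <- list()
  for (k in seq_along(key_lines)) {
    i <- key_lines[k]
    j <- if (k < length(key_lines)) key_lines[k + 1] - 1 else length(block)
    fields <- strsplit(sub("^\\s+", "", block[i]), "\\s+")[[1]]
    key <- fields[1]
    if (!key %in% names(keep_keys) && !identical(key, "D-loop")) next
    class <- if (identical(key, "D-loop")) "control" else keep_keys[[key]]
    chunk <- paste(sub("^\\s+", "", block[i:j]), collapse = " ")
    loc_text <- sub(paste0("^", gsub("([()])", "\\\\\\1", key), "\\s+"), "", sub("\\s*/.*$", "", chunk))
    loc <- parse_genbank_location(loc_text)
    if (is.null(loc)) next
    gene <- genbank_qualifier(chunk, "gene")
    if (is.na(gene)) gene <- genbank_qualifier(chunk, "product")
    if (is.na(gene)) gene <- key
    if (class == "control") gene <- "at_rich_region"
    rows[[length(rows) + 1]] <- tibble(
      gene = gene, class = class, strand = loc$strand,
      start = loc$start, end = loc$end,
      start_codon = NA_character_, stop_codon = NA_character_,
      anticodon = NA_character_
    )
  }
  feats <- dplyr::bind_rows(rows)
  if (nrow(feats) == 0) empty_features() else feats
}

parse_genbank_location <- function(text) {
  text <- gsub("[<>\\s]", "", text)
  strand <- "J"
  if (grepl("^complement\\(", text)) {
    strand <- "N"
    text <- sub("^complement\\((.*)\\)$", "\\1", text)
  }
  if (grepl("^join\\(", text)) {
    segs <- strsplit(sub("^join\\((.*)\\)$", "\\1", text), ",")[[1]]
    bounds <- lapply(segs, function(s) as.integer(strsplit(s, "\\.\\.")[[1]]))
    return(list(strand = strand, start = bounds[[1]][1],
                end = bounds[[length(bounds)]][2]))
  }
  parts <- suppressWarnings(as.integer(strsplit(text, "\\.\\.")[[1]]))
  if (length(parts) == 1 && !is.na(parts)) parts <- c(parts, parts)
  if (length(parts) != 2 || anyNA(parts)) return(NULL)
  list(strand = strand, start = parts[1], end = parts[2])
}

genbank_qualifier <- function(chunk, name) {
  pat <- paste0("/", name, "=\"([^\"]*)\"")
  m <- regmatches(chunk, regexec(pat, chunk))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}
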