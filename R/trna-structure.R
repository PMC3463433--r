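# tRNA cloverleaf stem accounting. Structures are consumed as input (they
# come from external predictors plus manual curation), via a plain-text
# sequence + dot-bracket interchange format.

ARM_NAMES <- c("acceptor", "DHU", "anticodon", "TpsiC")

#' Construct a tRNA cloverleaf structure
#'
#' @param gene tRNA gene name.
#' @param sequence Nucleotide string (DNA alphabet; reports use RNA).
#' @param arms Named list over `acceptor`, `DHU`, `anticodon`, `TpsiC`; each
#'   element a two-column matrix (or list of length-2 vectors) of 1-based
#'   paired position indices, 5' partner first. Arms may be empty (the DHU
#'   arm of trnS(AGN) is reduced to an unpaired loop in many arthropods).
#' @param anticodon_positions Integer triplet of the anticodon's positions.
#' @param dhu_replaced_by_loop Flag for the trnS(AGN)-style missing DHU stem.
#' @return An object of class `trna_structure`.
#' @export
trna_structure <- function(gene, sequence, arms, anticodon_positions = NULL,
                           dhu_replaced_by_loop = FALSE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  arms <- lapply(stats::setNames(ARM_NAMES, ARM_NAMES), function(a) {
    m <- arms[[a]]
    if (is.null(m) || length(m) == 0) return(matrix(integer(), ncol = 2))
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.integer(m), ncol = 2)
    if (any(m < 1 | m > n)) abort(paste0(gene, ": paired index out of bounds in ", a, " arm"))
    m
  })
  all_idx <- unlist(lapply(arms, as.integer))
  if (anyDuplicated(all_idx)) abort(paste0(gene, ": paired positions are not disjoint across arms"))
  if (!is.null(anticodon_positions)) {
    anticodon_positions <- as.integer(anticodon_positions)
    if (length(anticodon_positions) != 3 ||
        any(anticodon_positions < 1 | anticodon_positions > n)) {
      abort(paste0(gene, ": anticodon_positions must be three in-bounds indices"))
    }
    if (any(anticodon_positions %in% all_idx)) {
      abort(paste0(gene, ": anticodon positions must be unpaired"))
    }
  }
  structure(list(gene = gene, sequence = sequence, arms = arms,
                 anticodon_positions = anticodon_positions,
                 dhu_replaced_by_loop = dhu_replaced_by_loop),
            class = "trna_structure")
}

#' @export
print.trna_structure <- function(x, ...) {
  cat("<trna_structure> ", x$gene, ": ", nchar(x$sequence), " nt, ",
      sum(vapply(x$arms, nrow, 0L)), " pairs",
      if (x$dhu_replaced_by_loop) ", DHU arm replaced by loop", "\n", sep = "")
  invisible(x)
}

#' Read tRNA structures from a sequence + dot-bracket file
#'
#' Each record is three lines: a `>name` header, the sequence, and a
#' dot-bracket line of the same length with commas delimiting the arms in
#' cloverleaf order — acceptor 5' half, DHU arm, anticodon arm, (optional
#' variable region,) TψC arm, acceptor 3' half. Brackets pair by the usual
#' nesting; pairs opening and closing inside one internal segment belong to
#' that segment's stem, pairs spanning the first and last segments form the
#' acceptor stem. An all-dot DHU segment marks the DHU-arm-replaced-by-loop
#' configuration. The anticodon is the central triplet of the anticodon
#' loop.
#'
#' @param path Path to the structure file.
#' @return A named list of [trna_structure()] objects.
#' @export
read_trna_structures <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort(paste0("no '>' records in ", path))
  out <- list()
  for (h in heads) {
    if (h + 2 > length(lines)) abort("truncated record at end of structure file")
    gene <- sub("^>\\s*", "", strsplit(lines[h], "\\s+")[[1]][1])
    gene <- sub("^>", "", gene)
    out[[gene]] <- parse_dot_bracket(gene, lines[h + 1], lines[h + 2])
  }
  out
}

parse_dot_bracket <- function(gene, sequence, structure_line) {
  sequence <- toupper(gsub("\\s", "", sequence))
  segs <- strsplit(gsub("\\s", "", structure_line), ",", fixed = TRUE)[[1]]
  db <- paste(segs, collapse = "")
  if (nchar(db) != nchar(sequence)) {
    abort(paste0(gene, ": dot-bracket length ", nchar(db),
                 " does not match sequence length ", nchar(sequence)))
  }
  n_seg <- length(segs)
  if (n_seg < 5 || n_seg > 6) {
    abort(paste0(gene, ": expected 5 or 6 comma-delimited arm segments, got ", n_seg))
  }
  seg_of <- rep(seq_len(n_seg), times = nchar(segs))
  internal <- if (n_seg == 6) c("2" = "DHU", "3" = "anticodon", "5" = "TpsiC")
              else c("2" = "DHU", "3" = "anticodon", "4" = "TpsiC")

  chars <- strsplit(db, "")[[1]]
  stack <- integer()
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) abort(paste0(gene, ": unbalanced brackets"))
      pairs[[length(pairs) + 1]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    } else if (chars[i] != ".") {
      abort(paste0(gene, ": unexpected character '", chars[i], "' in dot-bracket line"))
    }
  }
  if (length(stack) > 0) abort(paste0(gene, ": unbalanced brackets"))

  arms <- stats::setNames(vector("list", 4), ARM_NAMES)
  for (p in pairs) {
    s1 <- seg_of[p[1]]; s2 <- seg_of[p[2]]
    arm <- if (s1 == s2) internal[as.character(s1)] else "acceptor"
    if (is.na(arm)) abort(paste0(gene, ": pair in unexpected segment ", s1))
    arms[[arm]] <- c(arms[[arm]], list(p))
  }

  # anticodon: middle triplet of the unpaired loop inside the anticodon segment
  ac_seg <- if (n_seg == 6) 3L else 3L
  anticodon_positions <- NULL
  idx <- which(seg_of == ac_seg & chars == ".")
  if (length(idx) >= 3) {
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    loop <- runs[[which.max(lengths(runs))]]
    mid <- loop[ceiling(length(loop) / 2)]
    anticodon_positions <- (mid - 1L):(mid + 1L)
  }
  dhu_seg <- 2L
  dhu_loop <- all(chars[seg_of == dhu_seg] == ".") && any(seg_of == dhu_seg)
  trna_structure(gene, sequence, arms, anticodon_positions,
                 dhu_replaced_by_loop = dhu_loop)
}

#' Classify stem base pairs as Watson-Crick, wobble or mismatch
#'
#' Watson-Crick pairs are `{A:U, U:A, G:C, C:G}`, wobble pairs `{G:U, U:G}`;
#' everything else is a mismatch, tallied by unordered identity (`A-C` and
#' `C-A` are the same class) in the RNA alphabet.
#'
#' @param structures A `trna_structure` or a list of them (counts pooled).
#' @return A list of class `pair_classification`: `$by_arm` — a tibble with
#'   one row per arm plus a `total` row (`watson_crick`, `wobble`,
#'   `mismatch`, `n_pairs`); `$mismatch_identities` — a tibble of mismatch
#'   identity counts.
#' @examples
#' s <- trna_structure("toy", "AUGCAU", list(acceptor = list(c(1, 6), c(2, 5))))
#' classify_pairs(s)$by_arm
#' @export
classify_pairs <- function(structures) {
  if (inherits(structures, "trna_structure")) structures <- list(structures)
  wc <- c("A-U", "C-G")
  wob <- "G-U"
  rows <- list()
  idents <- character()
  for (st in structures) {
    chars <- gsub("T", "U", strsplit(st$sequence, "")[[1]], fixed = TRUE)
    for (arm in ARM_NAMES) {
      m <- st$arms[[arm]]
      if (nrow(m) == 0) {
        rows[[length(rows) + 1]] <- tibble(arm = arm, watson_crick = 0L,
                                           wobble = 0L, mismatch = 0L)
        next
      }
      ids <- apply(m, 1, function(p) paste(sort(chars[p]), collapse = "-"))
      is_wc <- ids %in% wc
      is_wob <- ids %in% wob
      idents <- c(idents, ids[!is_wc & !is_wob])
      rows[[length(rows) + 1]] <- tibble(arm = arm,
                                         watson_crick = sum(is_wc),
                                         wobble = sum(is_wob),
                                         mismatch = sum(!is_wc & !is_wob))
    }
  }
  by_arm <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop") |>
    dplyr::arrange(match(.data$arm, ARM_NAMES)) |>
    dplyr::mutate(n_pairs = .data$watson_crick + .data$wobble + .data$mismatch)
  total <- by_arm |>
    dplyr::summarise(arm = "total", dplyr::across(dplyr::where(is.numeric), sum))
  mism <- if (length(idents) > 0) {
    as_tibble(table(identity = idents), n = "count") |> dplyr::arrange(.data$identity)
  } else {
    tibble(identity = character(), count = integer())
  }
  structure(list(by_arm = dplyr::bind_rows(by_arm, total),
                 mismatch_identities = mism),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  print(x$by_arm)
  if (nrow(x$mismatch_identities) > 0) {
    cat("mismatch identities:\n"); print(x$mismatch_identities)
  }
  invisible(x)
}

#' @method tidy pair_classification
#' @export
tidy.pair_classification <- function(x, ...) x$by_arm

#' Read a tRNA's anticodon off its structure
#'
#' The triplet at the structure's anticodon positions, read 5' to 3' from
#' the tRNA sense sequence.
#'
#' @param structure A [trna_structure()] with `anticodon_positions` set.
#' @param as_rna Report in the RNA alphabet?
#' @return Three-letter anticodon string.
#' @export
extract_anticodon <- function(structure, as_rna = FALSE) {
  pos <- structure$anticodon_positions
  if (is.null(pos)) abort(paste0(structure$gene, ": anticodon positions are not set"))
  chars <- strsplit(structure$sequence, "")[[1]]
  out <- paste(chars[pos], collapse = "")
  if (as_rna) gsub("T", "U", out, fixed = TRUE) else out
}
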