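# Genome architecture: intergenic spacers, gene overlaps, gene order and
# rearrangement classification against reference arrangements.

#' Signed gap between two consecutive features
#'
#' `start(f2) - end(f1) - 1` in the linearized order: positive values are
#' intergenic spacers, negative values overlaps of `|gap|` bp, zero means the
#' features abut. The pair closing the circle (last feature back to the
#' first) wraps through the origin.
#'
#' @param end1 End coordinate of the upstream feature.
#' @param start2 Start coordinate of the downstream feature.
#' @param genome_length Genome length, used when the pair wraps the origin.
#' @param wrap Logical; set `TRUE` for the circle-closing pair.
#' @return Signed gap in bp.
#' @export
pairwise_gap <- function(end1, start2, genome_length = NULL, wrap = FALSE) {
  gap <- as.integer(start2) - as.integer(end1) - 1L
  if (any(wrap)) {
    if (is.null(genome_length)) abort("genome_length required for the origin-closing pair")
    gap[wrap] <- gap[wrap] + genome_length
  }
  gap
}

#' Gaps between all consecutive feature pairs in circular order
#'
#' @param x A `mito_genome` or feature table (linearized order).
#' @param genome_length Needed for the circle-closing pair when `x` is a bare
#'   table.
#' @return A tibble with one row per adjacent pair: `upstream`, `downstream`,
#'   `upstream_end`, `downstream_start`, `gap` (signed bp).
#' @export
consecutive_gaps <- function(x, genome_length = NULL) {
  if (inherits(x, "mito_genome")) {
    genome_length <- x$length
    x <- x$features
  }
  x <- as_tibble(x)
  n <- nrow(x)
  if (n < 2) {
    return(tibble(upstream = character(), downstream = character(),
                  upstream_end = integer(), downstream_start = integer(),
                  gap = integer()))
  }
  nxt <- c(2:n, 1L)
  tibble(
    upstream = x$gene,
    downstream = x$gene[nxt],
    upstream_end = x$end,
    downstream_start = x$start[nxt],
    gap = pairwise_gap(x$end, x$start[nxt], genome_length,
                       wrap = seq_len(n) == n)
  )
}

#' Overlaps between adjacent genes
#'
#' Reports every consecutive-pair overlap in circular order. Insect
#' mitogenomes typically carry a handful of short overlaps (the 7-bp
#' atp8/atp6 overlap is near-universal in Lepidoptera).
#'
#' @inheritParams consecutive_gaps
#' @return A tibble of overlapping pairs with `length` in bp, carrying the
#'   grand total in attribute `"total"` (also via [overlap_total()]).
#' @examples
#' tr <- read_feature_table(system.file("extdata",
#'   "thitarodes_renzhiensis.features.tsv", package = "mitoarch"))
#' find_overlaps(tr)   # trnW/trnC 8, atp8/atp6 7, trnK/trnD 1
#' @export
find_overlaps <- function(x, genome_length = NULL) {
  gaps <- consecutive_gaps(x, genome_length)
  out <- gaps |>
    dplyr::filter(.data$gap < 0) |>
    dplyr::transmute(upstream = .data$upstream, downstream = .data$downstream,
                     length = -.data$gap)
  attr(out, "total") <- sum(out$length)
  out
}

#' Intergenic spacers between adjacent genes
#'
#' All strictly positive gaps between consecutive features in circular order.
#' The control region must be present as a feature so that its interior is
#' never counted as spacer; the reported total is the genome's noncoding
#' content excluding the A+T-rich region.
#'
#' @inheritParams consecutive_gaps
#' @param record Optional `mito_genome` with a sequence, used to attach each
#'   spacer's nucleotide sequence.
#' @return A tibble of spacers with `length` and (when a sequence is
#'   available) `sequence`; total via attribute `"total"` or
#'   [spacer_total()].
#' @export
find_intergenic_spacers <- function(x, genome_length = NULL, record = NULL) {
  if (inherits(x, "mito_genome") && is.null(record) && !is.null(x$sequence)) record <- x
  gaps <- consecutive_gaps(x, genome_length)
  out <- gaps |>
    dplyr::filter(.data$gap > 0) |>
    dplyr::transmute(upstream = .data$upstream, downstream = .data$downstream,
                     start = .data$upstream_end + 1L,
                     end = .data$downstream_start - 1L,
                     length = .data$gap)
  if (!is.null(record) && !is.null(record$sequence) && nrow(out) > 0) {
    out$sequence <- purrr::map2_chr(out$start, out$end, function(s, e) {
      L <- record$length
      s <- ((s - 1L) %% L) + 1L; e <- ((e - 1L) %% L) + 1L
      feature_sequence(record, s, e, "J")
    })
  }
  attr(out, "total") <- sum(out$length)
  out
}

#' @rdname find_overlaps
#' @export
overlap_total <- function(x, genome_length = NULL) {
  sum(find_overlaps(x, genome_length)$length)
}

#' @rdname find_intergenic_spacers
#' @export
spacer_total <- function(x, genome_length = NULL) {
  sum(find_intergenic_spacers(x, genome_length)$length)
}

#' Architecture conservation identity
#'
#' For a complete circular annotation,
#' sum(feature lengths) + sum(spacers) - sum(overlaps) = genome length.
#' Returns the left-hand side so callers can assert it against the genome
#' length.
#'
#' @param x A `mito_genome`.
#' @return Integer bp.
#' @export
architecture_checksum <- function(x) {
  sum(feature_lengths(x)$length) + spacer_total(x) - overlap_total(x)
}

# gene order ------------------------------------------------------------------

#' Extract the circular gene order of a record
#'
#' @param x A `mito_genome` or feature table in linearized order.
#' @param drop_control Drop the control region (gene orders are conventionally
#'   compared over the 37 genes)?
#' @return A tibble with columns `gene`, `strand`, in genomic order; circular
#'   comparisons treat rotations as equal.
#' @export
extract_gene_order <- function(x, drop_control = TRUE) {
  if (inherits(x, "mito_genome")) x <- x$features
  x <- as_tibble(x)
  if (drop_control && "class" %in% names(x)) x <- dplyr::filter(x, .data$class != "control")
  if (anyDuplicated(x$gene)) {
    abort(paste0("duplicate gene name(s): ",
                 paste(unique(x$gene[duplicated(x$gene)]), collapse = ", ")))
  }
  tibble(gene = x$gene, strand = x$strand)
}

#' Reference mitochondrial gene orders
#'
#' `"ancestral"` is the arrangement of *Drosophila yakuba*, inferred ancestral
#' for Insecta, with trnI-trnQ-trnM between the control region and nad2.
#' `"ditrysian"` is the arrangement shared by all ditrysian Lepidoptera
#' sequenced to date, which differs only by the translocation of trnM to the
#' front of the trnI-trnQ block.
#'
#' @param which `"ancestral"` or `"ditrysian"`.
#' @return A gene-order tibble (`gene`, `strand`), linearized at trnI
#'   (ancestral) or trnM (ditrysian), control region excluded.
#' @export
ref_gene_order <- function(which = c("ancestral", "ditrysian")) {
  which <- match.arg(which)
  anc <- tibble(
    gene = c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY", "cox1",
             "trnL(UUR)", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3",
             "trnG", "nad3", "trnA", "trnR", "trnN", "trnS(AGN)", "trnE",
             "trnF", "nad5", "trnH", "nad4", "nad4L", "trnT", "trnP", "nad6",
             "cob", "trnS(UCN)", "nad1", "trnL(CUN)", "rrnL", "trnV", "rrnS"),
    strand = c("J", "N", "J", "J", "J", "N", "N", "J",
               "J", "J", "J", "J", "J", "J", "J",
               "J", "J", "J", "J", "J", "J", "J",
               "N", "N", "N", "N", "N", "J", "N", "J",
               "J", "J", "N", "N", "N", "N", "N")
  )
  if (which == "ancestral") return(anc)
  idx <- match(c("trnM", "trnI", "trnQ"), anc$gene)
  dplyr::bind_rows(anc[idx, ], anc[-idx, ])
}

order_tokens <- function(order) paste(order$gene, order$strand, sep = "/")

circular_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0) return(TRUE)
  ta <- order_tokens(a); tb <- order_tokens(b)
  any(vapply(seq_along(tb), function(r) {
    identical(ta, tb[c(r:length(tb), seq_len(r - 1))[seq_along(tb)]])
  }, logical(1)))
}

rotate_to <- function(order, gene) {
  i <- match(gene, order$gene)
  if (is.na(i)) return(order)
  order[c(i:nrow(order), seq_len(i - 1))[seq_len(nrow(order))], ]
}

neighbor_context <- function(order, gene) {
  n <- nrow(order)
  i <- match(gene, order$gene)
  list(left = order_tokens(order)[((i - 2) %% n) + 1],
       right = order_tokens(order)[(i %% n) + 1])
}

#' Classify gene rearrangements against a reference order
#'
#' Finds the smallest set of "mover" genes whose removal makes the observed
#' and reference circular orders identical, and classifies each mover by the
#' standard taxonomy: `local_inversion` (same neighbours, strand flipped),
#' `translocation` (new neighbours, strand kept), `remote_inversion` (new
#' neighbours and strand flipped). Ties between equally small mover sets are
#' broken in favour of tRNA movers, the common movers in insect mitogenomes.
#'
#' @param observed,reference Gene-order tibbles over the same gene set (see
#'   [extract_gene_order()], [ref_gene_order()]).
#' @param max_movers Search depth for the minimal mover set.
#' @return A tibble with one row per rearranged gene: `gene`, `kind`,
#'   `from_left`, `from_right` (reference context), `to_left`, `to_right`
#'   (observed context). Zero rows when the orders are circularly identical.
#' @examples
#' classify_rearrangements(ref_gene_order("ditrysian"), ref_gene_order("ancestral"))
#' @export
classify_rearrangements <- function(observed, reference, max_movers = 4) {
  observed <- as_tibble(observed); reference <- as_tibble(reference)
  sym <- c(setdiff(observed$gene, reference$gene), setdiff(reference$gene, observed$gene))
  if (length(sym) > 0) {
    abort(paste0("gene sets differ: ", paste(sym, collapse = ", ")))
  }
  if (circular_equal(observed, reference)) return(rearrangement_events(character(), observed, reference))

  # candidate movers: genes whose (left, right, strand) context differs after
  # aligning both orders on cox1 (unmoved in all known lepidopteran orders)
  strand_of <- function(o, g) o$strand[match(g, o$gene)]
  changed <- Filter(function(g) {
    co <- neighbor_context(observed, g); cr <- neighbor_context(reference, g)
    !identical(co, cr) || !identical(strand_of(observed, g), strand_of(reference, g))
  }, observed$gene)

  drop_equal <- function(movers) {
    circular_equal(dplyr::filter(observed, !.data$gene %in% movers),
                   dplyr::filter(reference, !.data$gene %in% movers))
  }
  is_trna <- function(g) grepl("^trn", g)
  for (k in seq_len(min(max_movers, length(changed)))) {
    sets <- utils::combn(changed, k, simplify = FALSE)
    # tie-break: prefer sets with more tRNA movers
    sets <- sets[order(-vapply(sets, function(s) sum(is_trna(s)), numeric(1)))]
    for (s in sets) if (drop_equal(s)) return(rearrangement_events(s, observed, reference))
  }
  abort(paste0("orders differ by more than max_movers = ", max_movers, " genes"))
}

rearrangement_events <- function(movers, observed, reference) {
  rows <- purrr::map(movers, function(g) {
    co <- neighbor_context(observed, g)
    cr <- neighbor_context(reference, g)
    same_context <- identical(co, cr)
    flipped <- observed$strand[match(g, observed$gene)] !=
      reference$strand[match(g, reference$gene)]
    kind <- if (same_context && flipped) {
      "local_inversion"
    } else if (!same_context && !flipped) {
      "translocation"
    } else if (!same_context && flipped) {
      "remote_inversion"
    } else {
      # context identical and strand identical would mean no event at all;
      # reachable only through mover sets where a neighbour also moved
      "translocation"
    }
    tibble(gene = g, kind = kind,
           from_left = cr$left, from_right = cr$right,
           to_left = co$left, to_right = co$right)
  })
  dplyr::bind_rows(rows, tibble(gene = character(), kind = character(),
                                from_left = character(), from_right = character(),
                                to_left = character(), to_right = character()))
}
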