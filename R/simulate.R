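# Synthetic circular mitogenome generator with ground-truth annotations.
# Generated genomes carry the statistical structure the analysis modules
# assume -- gene order templates, A+T bias with strand skew, codon-usage
# bias, planned overlaps and truncated stops, and a control region with a
# planted tandem-repeat array -- so every stage can be validated against a
# known truth table.

# study-condition defaults: per-gene lengths, start/stop plans and
# anticodons of a typical hepialid mitogenome (majority-strand lengths)
default_gene_plan <- function() {
  dplyr::bind_rows(
    tibble(gene = c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY",
                    "trnL(UUR)", "trnK", "trnD", "trnG", "trnA", "trnR",
                    "trnN", "trnS(AGN)", "trnE", "trnF", "trnH", "trnT",
                    "trnP", "trnS(UCN)", "trnL(CUN)", "trnV"),
           class = "tRNA",
           length = c(65L, 69L, 70L, 66L, 67L, 67L, 69L, 71L, 65L, 66L,
                      69L, 66L, 66L, 60L, 65L, 66L, 67L, 66L, 64L, 73L,
                      71L, 65L),
           anticodon = c("GAT", "TTG", "CAT", "TCA", "GCA", "GTA", "TAA",
                         "CTT", "GTC", "TCC", "TGC", "TCG", "GTT", "TCT",
                         "TTC", "GAA", "GTG", "TGT", "TGG", "TGA", "TAG",
                         "TAC")),
    tibble(gene = c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                    "nad5", "nad4", "nad4L", "nad6", "cob", "nad1"),
           class = "PCG",
           length = c(1018L, 1531L, 682L, 162L, 677L, 789L, 352L, 1738L,
                      1341L, 293L, 524L, 1146L, 933L),
           start_codon = c("ATT", "CGA", "ATG", "ATA", "ATG", "ATG", "ATT",
                           "ATT", "ATG", "ATG", "ATA", "ATG", "TTG"),
           stop_codon = c("T--", "T--", "T--", "TAA", "TA-", "TAA", "T--",
                          "T--", "TAA", "TA-", "TA-", "TAA", "TAA")),
    tibble(gene = c("rrnL", "rrnS"), class = "rRNA", length = c(1335L, 779L))
  )
}

default_spacer_plan <- function() {
  tibble(
    upstream = c("trnQ", "trnC", "trnY", "trnL(UUR)", "cox3", "trnA",
                 "trnR", "trnE", "trnH", "nad4L", "trnP", "cob",
                 "trnS(UCN)"),
    downstream = c("trnM", "trnY", "cox1", "cox2", "trnG", "trnR", "trnN",
                   "trnF", "nad4", "trnT", "nad6", "trnS(UCN)", "nad1"),
    length = c(4L, 6L, 2L, 1L, 2L, 3L, 4L, 2L, 1L, 2L, 2L, 5L, 15L)
  )
}

#' Specification for a synthetic mitogenome
#'
#' Defaults emulate a hepialid-like lepidopteran mitogenome: the ancestral
#' insect gene order, whole-genome A+T content near 0.81 with slight A skew
#' and strong C skew, the canonical 7-bp atp8/atp6 overlap, eight PCGs with
#' truncated stops abutting their downstream genes, and a control region
#' carrying eight full copies plus a 57-bp partial of a 113-bp repeat unit.
#'
#' @param template `"ancestral"`, `"ditrysian"`, or a custom gene-order
#'   tibble (`gene`, `strand`).
#' @param at_content Target A+T fraction for non-coding/RNA sequence and the
#'   base-probability model behind the default codon weights.
#' @param at_skew,gc_skew Strand skews applied to the base probabilities.
#' @param gene_lengths Named integer vector of per-gene length overrides.
#' @param start_plan,stop_plan Named character vectors overriding per-PCG
#'   start codons / stop tokens (`TAA`, `TAG`, `TA-`, `T--`).
#' @param codon_weights Optional tibble (`codon`, `weight`) of sampling
#'   weights over the 62 sense codons; defaults to independent-base weights
#'   under the skewed base probabilities.
#' @param overlap_plan Tibble (`upstream`, `downstream`, `length`) of planned
#'   adjacent-gene overlaps.
#' @param spacer_plan Tibble (`upstream`, `downstream`, `length`) of planned
#'   intergenic spacers; unlisted adjacent pairs abut.
#' @param control_region_plan List with `unit_length`, `full_copies`,
#'   `partial_bp`, `noise` (per-base substitution rate in the repeat array),
#'   and optionally `flank_bp`, `at_content`; `NULL` for a repeat-free
#'   control region.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(template = "ancestral",
                     at_content = 0.81, at_skew = 0.011, gc_skew = -0.19,
                     gene_lengths = NULL,
                     start_plan = NULL, stop_plan = NULL,
                     codon_weights = NULL,
                     overlap_plan = tibble(upstream = "atp8",
                                           downstream = "atp6", length = 7L),
                     spacer_plan = default_spacer_plan(),
                     control_region_plan = list(unit_length = 113L,
                                                full_copies = 8L,
                                                partial_bp = 57L,
                                                noise = 0),
                     seed = 1L) {
  order <- if (is.character(template)) ref_gene_order(template) else as_tibble(template)
  plan <- default_gene_plan()
  plan <- plan[match(order$gene, plan$gene), ]
  if (anyNA(plan$gene)) {
    abort(paste0("no default plan for gene(s): ",
                 paste(order$gene[is.na(plan$gene)], collapse = ", ")))
  }
  plan$strand <- order$strand
  if (!is.null(gene_lengths)) {
    idx <- match(names(gene_lengths), plan$gene)
    plan$length[idx] <- as.integer(gene_lengths)
  }
  if (!is.null(start_plan)) plan$start_codon[match(names(start_plan), plan$gene)] <- start_plan
  if (!is.null(stop_plan)) plan$stop_codon[match(names(stop_plan), plan$gene)] <- stop_plan

  pcg <- plan[plan$class == "PCG", ]
  bad <- (pcg$length - stop_token_length(pcg$stop_codon)) %% 3L != 0L
  if (any(bad)) {
    abort(paste0("PCG length incompatible with stop token for: ",
                 paste(pcg$gene[bad], collapse = ", ")))
  }
  overlap_plan <- as_tibble(overlap_plan)
  for (i in seq_len(nrow(overlap_plan))) {
    lens <- plan$length[match(c(overlap_plan$upstream[i], overlap_plan$downstream[i]),
                              plan$gene)]
    if (anyNA(lens) || overlap_plan$length[i] >= min(lens)) {
      abort("infeasible overlap plan: overlap must be shorter than both features")
    }
  }
  if (!is.null(control_region_plan)) {
    cr <- control_region_plan
    if (cr$full_copies > 0 && cr$partial_bp >= cr$unit_length) {
      abort("infeasible control region plan: partial_bp must be < unit_length")
    }
  }
  probs <- base_probs(at_content, at_skew, gc_skew)
  if (is.null(codon_weights)) codon_weights <- default_codon_weights(probs)
  structure(
    list(order = order, plan = plan, at_content = at_content,
         at_skew = at_skew, gc_skew = gc_skew, base_probs = probs,
         codon_weights = codon_weights, overlap_plan = overlap_plan,
         spacer_plan = as_tibble(spacer_plan),
         control_region_plan = control_region_plan, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec> ", nrow(x$order), " genes, A+T target ", x$at_content,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

base_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  p <- c(A = at / 2 * (1 + at_skew), C = gc / 2 * (1 - gc_skew),
         G = gc / 2 * (1 + gc_skew), T = at / 2 * (1 - at_skew))
  p / sum(p)
}

random_bases <- function(n, probs) {
  if (n <= 0) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Default codon sampling weights under independent skewed base frequencies
#'
#' Weight of each sense codon is the product of its base probabilities,
#' normalised over the 62 sense codons; `rscu_like` rescales within each
#' synonymous family to the RSCU scale (family mean 1), the quantity
#' [codon_usage()] estimates on generated coding sequence.
#'
#' @param probs Named base probability vector (`A`, `C`, `G`, `T`).
#' @return Tibble `codon`, `weight`, `rscu_like`.
#' @export
default_codon_weights <- function(probs) {
  fam <- codon_families()
  w <- vapply(strsplit(fam$codon, ""), function(b) prod(probs[b]), numeric(1))
  fam |>
    dplyr::mutate(weight = w / sum(w)) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(rscu_like = .data$weight * .data$family_size / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "family", "family_size", "weight", "rscu_like")
}

sample_codons <- function(n, weights) {
  if (n <= 0) return(character())
  sample(weights$codon, n, replace = TRUE, prob = weights$weight)
}

build_pcg_sense <- function(len, start_codon, stop_token, weights) {
  stop_len <- stop_token_length(stop_token)
  n_cod <- (len - stop_len) %/% 3L
  stop_str <- switch(stop_token, "TAA" = "TAA", "TAG" = "TAG",
                     "TA-" = "TA", "T--" = "T")
  paste0(start_codon,
         paste(sample_codons(n_cod - 1L, weights), collapse = ""),
         stop_str)
}

#' Generate a synthetic A+T-rich control region
#'
#' A random A+T-biased repeat unit concatenated `full_copies` times plus its
#' first `partial_bp` bases, with i.i.d. substitutions at the `noise` rate,
#' embedded between non-repetitive A+T-biased flanks. The flank bases
#' adjacent to the array are chosen not to extend the repeat, so the planted
#' array span is exact. Substitution-only noise keeps unit lengths exact for
#' copy-number validation.
#'
#' @param unit_length Repeat unit length, bp.
#' @param full_copies Number of complete copies (0 for a repeat-free
#'   region).
#' @param partial_bp Length of the trailing partial copy (`< unit_length`).
#' @param noise Per-base substitution probability within the array.
#' @param seed Optional integer seed (`NULL` to use the current RNG
#'   stream).
#' @param flank_bp Length of each non-repetitive flank.
#' @param at_content A+T fraction of the region.
#' @return Nucleotide string with attributes `array_start`, `array_span`,
#'   `unit` (NULL-ish when no array is planted).
#' @examples
#' cr <- generate_control_region(113, 8, 57, 0, seed = 7)
#' find_tandem_repeats(cr)[, c("unit_length", "copies")]
#' @export
generate_control_region <- function(unit_length, full_copies, partial_bp,
                                    noise = 0, seed = NULL, flank_bp = 200,
                                    at_content = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  probs <- base_probs(at_content, 0, 0)
  flank1 <- random_bases(flank_bp, probs)
  flank2 <- random_bases(flank_bp, probs)
  if (is.null(full_copies) || full_copies < 1) {
    return(paste0(flank1, flank2))
  }
  if (partial_bp >= unit_length) abort("partial_bp must be < unit_length")
  unit <- strsplit(random_bases(unit_length, probs), "")[[1]]
  array <- c(rep(unit, full_copies), if (partial_bp > 0) unit[seq_len(partial_bp)])
  if (noise > 0) {
    hit <- which(stats::runif(length(array)) < noise)
    for (i in hit) array[i] <- sample(setdiff(c("A", "C", "G", "T"), array[i]), 1)
  }
  # junction guards: flank bases touching the array must not continue it
  guard <- function(flank, pos, avoid) {
    b <- substr(flank, pos, pos)
    if (b == avoid) {
      substr(flank, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
    }
    flank
  }
  if (flank_bp > 0) {
    flank1 <- guard(flank1, flank_bp, unit[unit_length])
    nxt <- unit[(partial_bp %% unit_length) + 1L]
    flank2 <- guard(flank2, 1L, nxt)
  }
  out <- paste0(flank1, paste(array, collapse = ""), flank2)
  attr(out, "array_start") <- flank_bp + 1L
  attr(out, "array_span") <- length(array)
  attr(out, "unit") <- paste(unit, collapse = "")
  out
}

#' Generate a synthetic mitogenome with its ground-truth annotation
#'
#' Assembles the genome gene by gene along the template order (control
#' region last, abutting the trnI origin): PCGs are open reading frames
#' under the invertebrate mitochondrial code built from the spec's codon
#' weights with the planned start codons and (possibly truncated) stop
#' tokens; tRNAs and rRNAs are A+T-biased placeholder sequences, each tRNA
#' carrying its canonical anticodon at the centre; planned overlaps and
#' spacers are laid down exactly. After assembly, upstream start-codon
#' ambiguity is removed: any spurious legitimate start triplet inside a
#' PCG's search window (in non-coding or placeholder sequence) is mutated
#' away, so [annotate_pcgs()] can recover every truth boundary exactly.
#'
#' @param spec A [sim_spec()].
#' @return A list: `record` (a `mito_genome` whose features are the truth
#'   table) and `truth` (the feature tibble).
#' @examples
#' sim <- simulate_mitogenome(sim_spec(seed = 42))
#' sim$record
#' @export
simulate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  plan <- spec$plan
  probs <- base_probs(spec$at_content, 0, 0)
  weights <- spec$codon_weights
  lookup <- function(tbl, up, down) {
    i <- which(tbl$upstream == up & tbl$downstream == down)
    if (length(i) == 1) tbl$length[i] else 0L
  }

  chunks <- character(0)
  pos <- 0L                      # current genome length
  feats <- list()
  anticodon_pos <- integer(0)    # genome positions of planted anticodons
  prev_gene <- NULL
  forced_prefix <- list()        # downstream PCG prefixes fixed by overlaps

  for (i in seq_len(nrow(plan))) {
    g <- plan[i, ]
    sp <- if (is.null(prev_gene)) 0L else lookup(spec$spacer_plan, prev_gene, g$gene)
    ov <- if (is.null(prev_gene)) 0L else lookup(spec$overlap_plan, prev_gene, g$gene)
    if (sp > 0 && ov > 0) abort("infeasible plan: a pair cannot both overlap and have a spacer")
    if (sp > 0) {
      chunks <- c(chunks, random_bases(sp, probs))
      pos <- pos + sp
    }

    if (g$class == "PCG") {
      next_g <- if (i < nrow(plan)) plan$gene[i + 1] else NULL
      ov_next <- if (!is.null(next_g)) lookup(spec$overlap_plan, g$gene, next_g) else 0L
      next_is_pcg <- !is.null(next_g) && plan$class[i + 1] == "PCG"
      if (!is.null(forced_prefix[[g$gene]])) {
        sense <- build_pcg_with_prefix(g, forced_prefix[[g$gene]], weights)
      } else {
        sense <- build_pcg_sense(g$length, g$start_codon, g$stop_codon, weights)
      }
      if (ov_next > 0 && next_is_pcg) {
        if (g$strand != "J" || plan$strand[i + 1] != "J") {
          abort("infeasible overlap plan: PCG/PCG overlaps are supported on the majority strand")
        }
        built <- constrain_overlap_tail(sense, g, plan[i + 1, ], ov_next, weights)
        sense <- built$sense
        forced_prefix[[next_g]] <- built$prefix
      }
      genome_seq <- if (g$strand == "J") sense else reverse_complement(sense)
    } else if (g$class == "tRNA") {
      sense <- random_bases(g$length, probs)
      a0 <- (g$length - 3L) %/% 2L + 1L
      substr(sense, a0, a0 + 2L) <- g$anticodon
      genome_seq <- if (g$strand == "J") sense else reverse_complement(sense)
    } else {
      genome_seq <- random_bases(g$length, probs)
      if (g$strand == "N") genome_seq <- reverse_complement(genome_seq)
    }

    if (ov > 0) {
      if (g$class == "PCG" && is.null(forced_prefix[[g$gene]])) {
        abort("infeasible overlap plan: a PCG may only overlap its upstream neighbour via a PCG/PCG plan entry")
      }
      # the genome keeps the already-emitted upstream bases; the new feature
      # simply starts ov bases earlier (for PCGs the upstream tail was
      # constructed to equal the forced prefix, so the bases agree)
      genome_seq <- substr(genome_seq, ov + 1L, nchar(genome_seq))
    }
    start <- pos - ov + 1L
    end <- start + g$length - 1L
    chunks <- c(chunks, genome_seq)
    pos <- pos + nchar(genome_seq)
    if (g$class == "tRNA") {
      a0 <- (g$length - 3L) %/% 2L + 1L
      apos <- if (g$strand == "J") (start + a0 - 1L):(start + a0 + 1L)
              else (end - a0 - 1L):(end - a0 + 1L)
      if (min(apos) <= pos - g$length + ov) {
        abort("infeasible overlap plan: overlap would swallow a planted anticodon")
      }
      anticodon_pos <- c(anticodon_pos, apos)
    }
    feats[[length(feats) + 1]] <- tibble(
      gene = g$gene, class = g$class, strand = g$strand,
      start = start, end = end,
      start_codon = if (g$class == "PCG") g$start_codon else NA_character_,
      stop_codon = if (g$class == "PCG") g$stop_codon else NA_character_,
      anticodon = if (g$class == "tRNA") g$anticodon else NA_character_
    )
    prev_gene <- g$gene
  }

  # control region last, abutting the origin
  cr <- spec$control_region_plan
  cr_seq <- if (is.null(cr)) {
    random_bases(300L, base_probs(0.9, 0, 0))
  } else {
    generate_control_region(cr$unit_length, cr$full_copies, cr$partial_bp,
                            noise = cr$noise %||% 0, seed = NULL,
                            flank_bp = cr$flank_bp %||% 200L,
                            at_content = cr$at_content %||% 0.9)
  }
  feats[[length(feats) + 1]] <- tibble(
    gene = "at_rich_region", class = "control", strand = "J",
    start = pos + 1L, end = pos + nchar(cr_seq),
    start_codon = NA_character_, stop_codon = NA_character_,
    anticodon = NA_character_
  )
  chunks <- c(chunks, as.character(cr_seq))
  seq <- paste(chunks, collapse = "")
  features <- dplyr::bind_rows(feats)

  seq <- scrub_start_ambiguity(seq, features, anticodon_pos)
  record <- mito_genome(features, sequence = seq,
                        id = paste0("sim_seed", spec$seed))
  check_truncation_feasible(record)
  list(record = record, truth = record$features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# downstream prefix forced by a PCG/PCG overlap: the upstream gene's last
# `ov` bases must spell the downstream gene's first `ov` bases while the
# upstream stop codon stays at the very end
constrain_overlap_tail <- function(sense, g_up, g_down, ov, weights) {
  if (stop_token_length(g_up$stop_codon) != 3L) {
    abort("infeasible overlap plan: the upstream PCG of an overlap needs a complete stop codon")
  }
  if (ov < 6L) abort("infeasible overlap plan: PCG/PCG overlaps shorter than 6 bp cannot host a start codon and a stop codon")
  len <- nchar(sense)
  stop_str <- substr(sense, len - 2L, len)
  ds <- len - ov + 1L
  # codons upstream of the prefix also constrain validity (truncated-stop
  # remainder, downstream-frame start scan), so the whole tail window is
  # redrawn on each attempt
  n_cod <- len %/% 3L
  c_lo <- max(1L, (max(1L, ds - 36L) - 1L) %/% 3L + 1L)
  for (attempt in 1:500) {
    cand <- sense
    for (ci in c_lo:(n_cod - 1L)) {
      substr(cand, 3L * ci - 2L, 3L * ci) <- sample_codons(1L, weights)
    }
    mid <- random_bases(ov - 6L, c(A = .25, C = .25, G = .25, T = .25))
    prefix <- paste0(g_down$start_codon, mid, stop_str)
    substr(cand, ds, len) <- prefix
    if (pcg_tail_valid(cand, len, ov)) {
      return(list(sense = cand, prefix = prefix))
    }
  }
  abort("infeasible overlap plan: could not satisfy overlap constraints")
}

# the rebuilt tail must keep every upstream codon a sense codon, must not
# leave a truncated-stop remainder (which would make the boundary ambiguous),
# and must not contain a spurious legitimate start in the downstream frame
pcg_tail_valid <- function(sense, len, ov, code = genetic_code()) {
  n_cod <- len %/% 3L                     # includes the stop codon
  first_codon <- (len - ov + 1L - 1L) %/% 3L + 1L
  for (ci in first_codon:(n_cod - 1L)) {
    codon <- substr(sense, 3L * ci - 2L, 3L * ci)
    if (codon %in% code$stops) return(FALSE)
  }
  ds <- len - ov + 1L                     # downstream gene start (in-gene coord)
  if (!is.null(truncated_stop(sense, 0L, ds))) return(FALSE)
  # downstream-frame scan across the tail region upstream of ds
  legit <- unique(c(code$starts, unlist(code$overrides)))
  for (o in seq(max(1L, ds - 33L), ds - 1L)) {
    if (o + 2L >= ds) next
    if (((ds - o) %% 3L) != 0L) next      # only the downstream reading frame
    if (substr(sense, o, o + 2L) %in% legit) return(FALSE)
  }
  TRUE
}

# build a PCG whose first nchar(prefix) bases are fixed by an upstream
# overlap; remaining codons are sampled, partial forced codons completed
# with sense codons
build_pcg_with_prefix <- function(g, prefix, weights, code = genetic_code()) {
  stop_len <- stop_token_length(g$stop_codon)
  n_cod <- (g$length - stop_len) %/% 3L
  k <- nchar(prefix)
  n_forced <- k %/% 3L
  rem <- k %% 3L
  forced_codons <- substring(prefix, seq(1, by = 3, length.out = n_forced),
                             seq(3, by = 3, length.out = n_forced))
  if (any(forced_codons %in% code$stops)) {
    abort("infeasible overlap plan: forced prefix contains a stop codon in the downstream frame")
  }
  codons <- forced_codons
  if (rem > 0) {
    stub <- substr(prefix, 3L * n_forced + 1L, k)
    for (attempt in 1:50) {
      cand <- paste0(stub, random_bases(3L - rem, c(A = .25, C = .25, G = .25, T = .25)))
      if (!cand %in% code$stops) { codons <- c(codons, cand); break }
    }
  }
  n_free <- n_cod - length(codons)
  if (n_free < 0) abort("infeasible overlap plan: overlap longer than the downstream gene's coding part")
  stop_str <- switch(g$stop_codon, "TAA" = "TAA", "TAG" = "TAG",
                     "TA-" = "TA", "T--" = "T")
  paste0(paste(codons, collapse = ""),
         paste(sample_codons(n_free, weights), collapse = ""),
         stop_str)
}

# sense-space scan bounds shared with annotate_pcgs: candidate starts are
# scanned from `half` bp upstream of the hinted start, never inside a
# strictly upstream same-strand gene
pcg_scan_lo <- function(feats, L, gene, strand, s1, half) {
  if (strand == "J") {
    same <- feats[feats$strand == "J" & feats$gene != gene, ]
    ends_same <- same$end
  } else {
    same <- feats[feats$strand == "N" & feats$gene != gene, ]
    ends_same <- L - same$start + 1L
  }
  up_ends <- ends_same[ends_same < s1]
  max(1L, s1 - half, if (length(up_ends)) max(up_ends) + 1L else 1L)
}

# remove spurious legitimate start triplets from PCG search windows; only
# non-coding / placeholder bases are touched (PCG interiors are kept clean
# by construction), and planted anticodons are preserved
scrub_start_ambiguity <- function(seq, features, anticodon_pos,
                                  code = genetic_code(), window = 60L) {
  L <- nchar(seq)
  half <- window %/% 2L
  x <- strsplit(seq, "")[[1]]
  rc <- function(v) chartr("ACGT", "TGCA", rev(v))
  pcgs <- features[features$class == "PCG", ]
  in_pcg <- rep(FALSE, L)
  for (i in seq_len(nrow(pcgs))) in_pcg[pcgs$start[i]:pcgs$end[i]] <- TRUE

  for (pass in 1:10) {
    dirty <- FALSE
    for (i in seq_len(nrow(pcgs))) {
      g <- pcgs[i, ]
      if (g$strand == "J") {
        s1 <- g$start
        to_genome <- function(p) p
        sense <- x
      } else {
        s1 <- L - g$end + 1L
        to_genome <- function(p) L - p + 1L
        sense <- rc(x)
      }
      lo <- pcg_scan_lo(features, L, g$gene, g$strand, s1, half)
      if (lo >= s1) next
      legit <- unique(c(code$starts, code$overrides[[g$gene]]))
      for (o in lo:(s1 - 1L)) {
        if (o + 2L > L) next
        tri <- paste(sense[o:(o + 2L)], collapse = "")
        if (!tri %in% legit) next
        gp <- sort(vapply(o:(o + 2L), to_genome, integer(1)))
        cand <- setdiff(gp[!in_pcg[gp]], anticodon_pos)
        if (length(cand) == 0) next
        p <- cand[ceiling(length(cand) / 2)]
        x[p] <- if (x[p] == "C") "G" else "C"
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  paste(x, collapse = "")
}

# every planned truncated stop must abut its downstream same-strand gene,
# otherwise the truncation convention cannot hold on the generated genome
check_truncation_feasible <- function(record) {
  feats <- record$features
  L <- record$length
  pcgs <- feats[feats$class == "PCG" & !is.na(feats$stop_codon) &
                  feats$stop_codon %in% c("TA-", "T--"), ]
  for (i in seq_len(nrow(pcgs))) {
    g <- pcgs[i, ]
    if (g$strand == "J") {
      nxt <- feats$start[feats$strand == "J" & feats$start > g$end]
      ok <- length(nxt) > 0 && min(nxt) == g$end + 1L
    } else {
      prv <- feats$end[feats$strand == "N" & feats$end < g$start]
      ok <- length(prv) > 0 && max(prv) == g$start - 1L
    }
    if (!ok) {
      abort(paste0("infeasible plan: truncated stop of ", g$gene,
                   " does not abut a downstream same-strand gene"))
    }
  }
  invisible(record)
}
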