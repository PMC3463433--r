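# A+T-rich (control) region characterization: tandem repeat arrays with
# fractional copy number, conserved motifs, poly-T stretches.

#' Detect tandem repeat arrays by period scan
#'
#' For every candidate unit length `u` the region is compared against itself
#' shifted by `u`. A pair of adjacent unit-sized windows agreeing within
#' `max_mismatch_frac` (Hamming) seeds an array, which is grown copy by copy
#' against the running per-column majority consensus (a slightly looser
#' per-copy tolerance is used during growth so that one noisy copy does not
#' split an array), and finally extended by partial head/tail copies using a
#' match-minus-penalised-mismatch score so the array boundary never creeps
#' into unrelated flanking sequence. Copy number is the fractional
#' `span / u` reported to one decimal: eight full copies plus a 57-bp
#' partial of a 113-bp unit report 8.5 copies.
#'
#' Overlapping calls (within and across periods) are collapsed to the
#' highest-scoring: largest `span - mismatches/max_mismatch_frac` first,
#' then smallest unit — so a perfect array is reported at its fundamental
#' period rather than at a multiple.
#'
#' The consensus unit is the per-column majority over the full copies;
#' partial copies do not vote.
#'
#' @param region Nucleotide string (typically the A+T-rich region).
#' @param min_unit,max_unit Unit-length range scanned, bp. Defaults bracket
#'   the >50 bp "macrorepeat" units typical of lepidopteran control regions.
#' @param min_copies Minimum (fractional) copy number to report.
#' @param max_mismatch_frac Per-unit Hamming mismatch tolerance.
#' @return A tibble of arrays: `unit_length`, `copies` (one decimal),
#'   `start`, `end` (1-based within the region), `span`, `consensus_unit`,
#'   `mismatch_fraction`.
#' @examples
#' find_tandem_repeats(strrep("ACGT", 3), min_unit = 4, max_unit = 6,
#'                     min_copies = 2)
#' @export
find_tandem_repeats <- function(region, min_unit = 10, max_unit = 300,
                                min_copies = 2.5, max_mismatch_frac = 0.1) {
  if (is.null(region) || nchar(region) == 0) return(empty_repeat_table())
  x <- strsplit(toupper(region), "")[[1]]
  L <- length(x)
  max_unit <- min(max_unit, L %/% 2)
  if (min_unit < 2 || min_unit > max_unit) return(empty_repeat_table())

  cands <- list()
  for (u in seq(min_unit, max_unit)) {
    tol <- floor(max_mismatch_frac * u)
    d <- x[seq_len(L - u)] != x[seq_len(L - u) + u]
    cs <- c(0L, cumsum(d))
    n_win <- L - 2L * u + 1L
    if (n_win < 1) next
    wmis <- cs[seq_len(n_win) + u] - cs[seq_len(n_win)]
    seeds <- which(wmis <= tol)
    covered_to <- 0L
    for (s in seeds) {
      if (s <= covered_to) next
      # phase refinement: a seed a few bases into the flank can still pass
      # tolerance; the true-phase window in the next unit has the fewest
      # mismatches
      grp <- seeds[seeds >= s & seeds < s + u]
      s_star <- grp[which.min(wmis[grp])]
      cand <- grow_array(x, s_star, u, max_mismatch_frac)
      covered_to <- cand$end
      if (cand$copies >= min_copies) cands[[length(cands) + 1]] <- cand
    }
  }
  if (length(cands) == 0) return(empty_repeat_table())
  cands <- dplyr::bind_rows(cands)
  # harmonic suppression: a call whose consensus unit is itself periodic is
  # a multiple of a shorter period (or a homopolymer run) and is reported
  # at its fundamental period, or not at all when that period is below
  # min_unit
  fundamental <- !vapply(cands$consensus_unit, is_subperiodic,
                         logical(1), mmf = max_mismatch_frac)
  cands <- cands[fundamental, ]
  if (nrow(cands) == 0) return(empty_repeat_table())
  cands <- dplyr::arrange(cands, dplyr::desc(.data$score),
                          .data$unit_length, .data$start)
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cands)) > i)
    overlap <- cands$start[later] <= cands$end[i] & cands$end[later] >= cands$start[i]
    keep[later[overlap]] <- FALSE
  }
  cands[keep, setdiff(names(cands), "score")] |> dplyr::arrange(.data$start)
}

is_subperiodic <- function(consensus, mmf) {
  v <- strsplit(consensus, "")[[1]]
  u <- length(v)
  for (p in seq_len(u %/% 2)) {
    if (mean(v[seq_len(u - p)] != v[seq_len(u - p) + p]) <= mmf) return(TRUE)
  }
  FALSE
}

empty_repeat_table <- function() {
  tibble(unit_length = integer(), copies = numeric(), start = integer(),
         end = integer(), span = integer(), consensus_unit = character(),
         mismatch_fraction = numeric())
}

majority_consensus <- function(copies) {
  m <- do.call(cbind, copies)
  apply(m, 1, function(row) names(which.max(table(row))))
}

grow_array <- function(x, s, u, mmf) {
  L <- length(x)
  grow_tol <- ceiling(2 * mmf * u)   # per-copy slack against the consensus
  copies <- list(x[s:(s + u - 1L)], x[(s + u):(s + 2L * u - 1L)])
  lo <- s
  hi <- s + 2L * u - 1L
  repeat {                            # grow right
    nxt <- hi + 1L
    if (nxt + u - 1L > L) break
    cons <- majority_consensus(copies)
    w <- x[nxt:(nxt + u - 1L)]
    if (sum(w != cons) > grow_tol) break
    copies <- c(copies, list(w)); hi <- nxt + u - 1L
  }
  repeat {                            # grow left
    prv <- lo - u
    if (prv < 1L) break
    cons <- majority_consensus(copies)
    w <- x[prv:(prv + u - 1L)]
    if (sum(w != cons) > grow_tol) break
    copies <- c(list(w), copies); lo <- prv
  }
  consensus <- majority_consensus(copies)

  # partial copies: maximise matches - lambda * mismatches; ties favour the
  # shorter extension, so a single chance-matching flank base cannot drag
  # the boundary outward. The penalty is calibrated so that an extension
  # segment needs > lambda/(lambda + 1) local identity (~85% at the default
  # tolerance) to be kept -- unrelated A+T-biased flank sequence (~40%
  # identity) is rejected, while a genuine partial copy carrying one
  # isolated noise substitution is still absorbed by the running maximum.
  lambda <- 0.6 / max(mmf, 1e-9)
  best_ext <- function(obs, cons_part) {
    n <- min(length(obs), length(cons_part))
    if (n == 0) return(0L)
    mism <- cumsum(obs[seq_len(n)] != cons_part[seq_len(n)])
    score <- seq_len(n) - lambda * mism
    if (max(score) <= 0) return(0L)
    which.max(score)
  }
  tail_len <- best_ext(if (hi < L) x[(hi + 1L):L] else character(),
                       consensus[seq_len(u - 1L)])
  head_len <- best_ext(if (lo > 1L) x[(lo - 1L):1L] else character(),
                       consensus[u:2L])
  start <- lo - head_len
  end <- hi + tail_len
  tiled <- c(if (head_len > 0) consensus[(u - head_len + 1L):u],
             rep(consensus, length(copies)),
             if (tail_len > 0) consensus[seq_len(tail_len)])
  # trim mismatch-heavy margins (a seed window may start a few bases into
  # the flank while still within tolerance): drop the prefix/suffix with
  # the most negative match-minus-penalised-mismatch score
  mvec <- x[start:end] != tiled
  contrib <- ifelse(mvec, -lambda, 1)
  pre <- cumsum(contrib)
  if (min(pre) < 0) {
    p <- which.min(pre)
    start <- start + p
    tiled <- tiled[-seq_len(p)]
    mvec <- mvec[-seq_len(p)]
    contrib <- contrib[-seq_len(p)]
  }
  suf <- rev(cumsum(rev(contrib)))
  if (min(suf) < 0) {
    q <- length(suf) - which.min(rev(suf)) + 1L
    keep <- seq_len(q - 1L)
    end <- start + q - 2L
    tiled <- tiled[keep]
    mvec <- mvec[keep]
  }
  span <- end - start + 1L
  mism_total <- sum(mvec)
  tibble(unit_length = as.integer(u),
         copies = round(span / u, 1),
         start = as.integer(start), end = as.integer(end),
         span = as.integer(span),
         consensus_unit = paste(consensus, collapse = ""),
         mismatch_fraction = mism_total / span,
         score = span - lambda * mism_total)
}

#' Find a motif allowing mismatches
#'
#' All (possibly overlapping) positions where the Hamming distance between
#' the motif and the region substring is at most `max_mismatch`.
#'
#' @param region Nucleotide string.
#' @param motif Query string (DNA alphabet).
#' @param max_mismatch Maximum Hamming mismatches allowed.
#' @return A tibble of hits: `motif`, `position` (1-based), `mismatches`,
#'   `matched_text`.
#' @examples
#' find_motif("GGATACTATGG", "ATACTAA", max_mismatch = 1)
#' @export
find_motif <- function(region, motif, max_mismatch = 0) {
  if (is.null(motif) || nchar(motif) == 0) abort("motif must be nonempty")
  x <- strsplit(toupper(region), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  k <- length(m)
  n <- length(x)
  if (n < k) return(tibble(motif = character(), position = integer(),
                           mismatches = integer(), matched_text = character()))
  mism <- vapply(seq_len(n - k + 1), function(p) sum(x[p:(p + k - 1)] != m), integer(1))
  hit <- which(mism <= max_mismatch)
  tibble(motif = toupper(motif), position = hit, mismatches = mism[hit],
         matched_text = vapply(hit, function(p) paste(x[p:(p + k - 1)], collapse = ""), ""))
}

#' Find poly-T stretches
#'
#' Maximal runs of `T` of at least `min_len` bp. The default threshold
#' matches the 16-22 bp poly-T element conserved downstream of rrnS in
#' ditrysian Lepidoptera control regions.
#'
#' @param region Nucleotide string.
#' @param min_len Minimum run length, bp.
#' @return A tibble of hits: `motif` (`"poly-T"`), `position`, `length`,
#'   `matched_text`, `mismatches` (always 0).
#' @export
find_poly_t <- function(region, min_len = 16) {
  if (min_len < 1) abort("min_len must be >= 1")
  r <- rle(strsplit(toupper(region), "")[[1]] == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_len
  tibble(motif = "poly-T", position = starts[sel], length = r$lengths[sel],
         matched_text = strrep("T", r$lengths[sel]), mismatches = 0L)
}
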