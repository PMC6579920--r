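# Alignment and repeat-finding primitives shared by every pipeline stage.
#
# Nucleotide local search is seed-and-extend in the megablast regime:
# exact k-mer seeds are chained along near-constant diagonals, inter-anchor
# gaps are closed by dynamic programming (Biostrings), and block ends are
# extended ungapped under an x-drop rule. Scoring defaults: match +1,
# mismatch -2, gap open -5, gap extend -2, x-drop 20, k = 13.

ALIGN_DEFAULTS <- list(k = 13L, x_drop = 20, match = 1, mismatch = -2,
                       gap_open = 5, gap_extend = 2, band = 50L,
                       chain_gap = 1000L, gap_cap = 5000L)

aa_alphabet_ok <- function(x) !grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", x)

#' Global protein identity and coverage
#'
#' Ends-free global alignment with affine gaps (BLOSUM62). Identity is
#' matches over alignment columns excluding terminal gaps; coverage is the
#' aligned (non-terminal-gap) span of the longer sequence divided by its
#' length — the symmetric, conservative reading of an "aligned over x% of
#' the protein" rule.
#'
#' @param a,b amino-acid strings.
#' @return named numeric vector c(identity=, coverage=).
#' @export
protein_identity_coverage <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("protein sequences must be non-empty")
  if (!aa_alphabet_ok(a) || !aa_alphabet_ok(b)) {
    abort("non-amino-acid symbols in protein sequence")
  }
  r <- aa_identity_coverage_many(a, b)
  c(identity = r$identity[1], coverage = r$coverage[1])
}

# vectorized identity/coverage of one query against many references
aa_identity_coverage_many <- function(query, refs) {
  if (!length(refs)) return(tibble(identity = numeric(), coverage = numeric()))
  pat <- Biostrings::AAStringSet(refs)
  subj <- Biostrings::AAString(query)
  p <- Biostrings::pairwiseAlignment(pat, subj, type = "overlap",
                                     substitutionMatrix = "BLOSUM62",
                                     gapOpening = 10, gapExtension = 0.5)
  cols <- Biostrings::nchar(p)           # alignment columns (no terminal gaps)
  matches <- Biostrings::nmatch(p)
  qlen <- nchar(query)
  rlen <- nchar(refs)
  span_q <- Biostrings::width(Biostrings::subject(p))  # aligned span on query
  span_r <- Biostrings::width(Biostrings::pattern(p))  # aligned span on each ref
  longer_len <- pmax(qlen, rlen)
  longer_span <- ifelse(rlen >= qlen, span_r, span_q)
  tibble(identity = ifelse(cols > 0, matches / cols, 0),
         coverage = longer_span / longer_len)
}

# ---------------------------------------------------------------------------
# k-mer seed index

#' Build an exact k-mer position index of a replicon
#'
#' Indexes every forward-strand k-mer position (minus-strand positions are
#' retrieved by looking up the reverse complement); k-mers containing N are
#' skipped.
#'
#' @param x a [replicon()] or DNA string.
#' @param k word size, 8..32.
#' @export
build_kmer_index <- function(x, k = ALIGN_DEFAULTS$k) {
  if (k < 8L || k > 32L) abort("k must be in [8, 32]")
  s <- if (inherits(x, "replicon")) x$sequence else toupper(x)
  topology <- if (inherits(x, "replicon")) x$topology else "linear"
  n <- nchar(s)
  if (n < k) abort("sequence shorter than k")
  pos <- seq_len(n - k + 1L)
  kmers <- substring(s, pos, pos + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  dt <- data.table::data.table(kmer = kmers[keep], pos = pos[keep])
  data.table::setkey(dt, kmer)
  structure(list(table = dt, k = k, length = n, topology = topology,
                 sequence = s,
                 replicon_id = if (inherits(x, "replicon")) x$replicon_id else NA_character_),
            class = "kmer_index")
}

#' Positions of a k-mer in an index
#' @param index a [build_kmer_index()] object.
#' @param kmer query word of the index's k.
#' @param strand "+" for forward occurrences, "-" for occurrences whose
#'   reverse complement equals `kmer`.
#' @export
kmer_positions <- function(index, kmer, strand = "+") {
  if (nchar(kmer) != index$k) abort("kmer length does not match index k")
  key <- if (strand == "+") kmer else revcomp(kmer)
  out <- index$table[list(key), on = "kmer", nomatch = NULL]
  sort(out$pos)
}

# ungapped x-drop extension over integer-encoded sequences, processed in
# chunks so spurious seeds terminate after one small scan.
# qi/si: first positions to compare; dq: direction (+1/-1). Returns steps kept.
xdrop_extend <- function(qint, sint, qi, si, dq, par, chunk = 2048L) {
  nq <- length(qint); ns <- length(sint)
  total <- if (dq > 0) min(nq - qi + 1L, ns - si + 1L) else min(qi, si)
  if (is.na(total) || total <= 0L) return(list(len = 0L, matches = 0L, score = 0))
  done <- 0L
  base_score <- 0
  best_len <- 0L; best_matches <- 0L; best_score <- 0
  matches_so_far <- 0L
  repeat {
    take <- min(chunk, total - done)
    if (take <= 0L) break
    off <- done + seq_len(take) - 1L
    iq <- qi + dq * off
    is_ <- si + dq * off
    m <- qint[iq] == sint[is_]
    sc <- base_score + cumsum(par$mismatch + (par$match - par$mismatch) * m)
    run_max <- cummax(pmax(sc, best_score))
    cut <- which(run_max - sc > par$x_drop)
    lim <- if (length(cut)) cut[1] - 1L else take
    if (lim > 0L) {
      seg_best <- which.max(sc[seq_len(lim)])
      if (sc[seg_best] > best_score) {
        best_score <- sc[seg_best]
        best_len <- done + seg_best
        best_matches <- matches_so_far + sum(m[seq_len(seg_best)])
      }
    }
    if (length(cut)) break
    done <- done + take
    base_score <- sc[take]
    matches_so_far <- matches_so_far + sum(m)
    if (done >= total) break
  }
  list(len = best_len, matches = best_matches, score = best_score)
}

nt_submat <- function(par) {
  Biostrings::nucleotideSubstitutionMatrix(match = par$match, mismatch = par$mismatch,
                                           baseOnly = TRUE)
}

# global alignment of two short gap segments; returns cols/matches/score
align_gap_segment <- function(qs, ss, par) {
  if (!nzchar(qs) && !nzchar(ss)) return(list(cols = 0L, matches = 0L, score = 0))
  if (!nzchar(qs) || !nzchar(ss)) {
    glen <- max(nchar(qs), nchar(ss))
    return(list(cols = glen, matches = 0L,
                score = -(par$gap_open + par$gap_extend * glen)))
  }
  if (nchar(qs) == nchar(ss)) {
    mm <- hamming(qs, ss)
    return(list(cols = nchar(qs), matches = nchar(qs) - mm,
                score = (nchar(qs) - mm) * par$match + mm * par$mismatch))
  }
  p <- Biostrings::pairwiseAlignment(Biostrings::DNAString(qs), Biostrings::DNAString(ss),
                                     type = "global", substitutionMatrix = nt_submat(par),
                                     gapOpening = par$gap_open, gapExtension = par$gap_extend)
  ap <- utf8ToInt(as.character(Biostrings::alignedPattern(p)))
  as_ <- utf8ToInt(as.character(Biostrings::alignedSubject(p)))
  list(cols = length(ap), matches = sum(ap == as_ & ap != utf8ToInt("-")),
       score = Biostrings::score(p))
}

empty_blocks <- function() {
  tibble(query_id = character(), subject_id = character(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(), strand = character(),
         identity = numeric(), length = integer(), matches = integer(),
         columns = integer(), score = numeric())
}

search_one_strand <- function(q, qid, index, strand, par, min_length, min_identity) {
  k <- index$k
  n_ext <- nchar(index$sequence)
  qn <- nchar(q)
  if (qn < k) return(empty_blocks())
  qpos <- seq_len(qn - k + 1L)
  qk <- substring(q, qpos, qpos + k - 1L)
  keep <- !grepl("N", qk, fixed = TRUE)
  qdt <- data.table::data.table(kmer = qk[keep], qpos = qpos[keep])
  seeds <- index$table[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(seeds)) return(empty_blocks())
  seeds[, diag := pos - qpos]
  data.table::setorder(seeds, diag, pos)
  grp <- cumsum(c(TRUE, diff(seeds$diag) > par$band | diff(seeds$pos) > par$chain_gap))
  seeds[, cluster := grp]
  qint <- utf8ToInt(q)
  sint <- utf8ToInt(index$sequence)

  # an ungapped x-drop extension beyond the seed span cannot add more than
  # ~x_drop/2 mismatches, each buying at most k-1 further matches; clusters
  # whose seed span plus that margin cannot reach min_length are skipped
  ext_margin <- ceiling(par$x_drop / 2) * k + k
  rows <- list()
  finalize_chain <- function(sel_q, sel_s) {
    na <- length(sel_q)
    if (!na) return(NULL)
    span <- (sel_s[na] + k - 1L) - sel_s[1] + 1L
    if (span + 2L * ext_margin < min_length) return(NULL)
    # per-gap alignment statistics between consecutive anchors
    g_cols <- g_matches <- integer(max(0L, na - 1L))
    g_score <- numeric(max(0L, na - 1L))
    if (na > 1L) {
      for (i in seq_len(na - 1L)) {
        g <- align_gap_segment(substr(q, sel_q[i] + k, sel_q[i + 1L] - 1L),
                               substr(index$sequence, sel_s[i] + k, sel_s[i + 1L] - 1L),
                               par)
        g_cols[i] <- g$cols; g_matches[i] <- g$matches; g_score[i] <- g$score
      }
    }
    # best-scoring contiguous anchor window (Kadane over anchor/gap runs):
    # a stray terminal anchor joined across a low-identity gap must not
    # drag the block boundary outward
    a_score <- k * par$match
    best <- -Inf; best_i <- 1L; best_j <- 1L
    cur <- 0; cur_start <- 1L
    cur_m <- 0L; cur_c <- 0L
    best_m <- 0L; best_c <- 0L
    for (i in seq_len(na)) {
      if (i == 1L || cur + g_score[i - 1L] < 0) {
        cur <- a_score; cur_start <- i; cur_m <- k; cur_c <- k
      } else {
        cur <- cur + g_score[i - 1L] + a_score
        cur_m <- cur_m + g_matches[i - 1L] + k
        cur_c <- cur_c + g_cols[i - 1L] + k
      }
      if (cur > best) {
        best <- cur; best_i <- cur_start; best_j <- i
        best_m <- cur_m; best_c <- cur_c
      }
    }
    matches <- best_m; cols <- best_c; score <- best
    q1 <- sel_q[best_i]; s1 <- sel_s[best_i]
    q2 <- sel_q[best_j] + k - 1L; s2 <- sel_s[best_j] + k - 1L
    el <- xdrop_extend(qint, sint, q1 - 1L, s1 - 1L, -1L, par)
    er <- xdrop_extend(qint, sint, q2 + 1L, s2 + 1L, +1L, par)
    q1 <- q1 - el$len; s1 <- s1 - el$len
    q2 <- q2 + er$len; s2 <- s2 + er$len
    matches <- matches + el$matches + er$matches
    cols <- cols + el$len + er$len
    score <- score + el$score + er$score
    c(q1, q2, s1, s2, matches, cols, score)
  }
  for (cl in split(seeds, seeds$cluster)) {
    if ((max(cl$pos) - min(cl$pos) + k) + 2L * ext_margin < min_length) next
    data.table::setorder(cl, qpos, pos)
    # greedy colinear anchor chains, split wherever a gap exceeds chain_gap
    sel_q <- integer(nrow(cl)); sel_s <- integer(nrow(cl)); nsel <- 0L
    for (i in seq_len(nrow(cl))) {
      qi <- cl$qpos[i]; si <- cl$pos[i]
      if (nsel > 0L && (qi < sel_q[nsel] + k || si < sel_s[nsel] + k)) next
      if (nsel > 0L && (qi - (sel_q[nsel] + k) > par$chain_gap ||
                        si - (sel_s[nsel] + k) > par$chain_gap)) {
        r <- finalize_chain(sel_q[seq_len(nsel)], sel_s[seq_len(nsel)])
        if (!is.null(r)) rows[[length(rows) + 1L]] <- r
        nsel <- 0L
      }
      nsel <- nsel + 1L
      sel_q[nsel] <- qi; sel_s[nsel] <- si
    }
    r <- finalize_chain(sel_q[seq_len(nsel)], sel_s[seq_len(nsel)])
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) return(empty_blocks())
  m <- do.call(rbind, rows)
  out <- tibble(
    query_id = qid, subject_id = index$replicon_id %||% NA_character_,
    q_start = as.integer(m[, 1]), q_end = as.integer(m[, 2]),
    s_start = as.integer(m[, 3]), s_end = as.integer(m[, 4]), strand = strand,
    identity = m[, 5] / m[, 6], length = as.integer(m[, 2] - m[, 1] + 1),
    matches = as.integer(m[, 5]), columns = as.integer(m[, 6]), score = m[, 7])
  if (strand == "-") {
    # report query coordinates on the original (forward) query
    out <- mutate(out, q_start0 = qn - .data$q_end + 1L, q_end = qn - .data$q_start + 1L,
                  q_start = .data$q_start0) |> select(-"q_start0")
  }
  filter(out, .data$length >= min_length, .data$identity >= min_identity)
}

#' Seed-and-extend local nucleotide search
#'
#' Finds local alignments of `query` in `subject` on both strands. Circular
#' subjects are searched across the origin; origin-spanning hits keep
#' `s_end` greater than the replicon length (reduce modulo length).
#'
#' @param query DNA string.
#' @param subject a [replicon()], DNA string, or prebuilt [build_kmer_index()].
#' @param min_length minimum reported block length on the query, bp.
#' @param min_identity minimum fraction of matching columns.
#' @param par scoring parameters (see `ALIGN_DEFAULTS`).
#' @return tibble of alignment blocks (1-based inclusive coordinates,
#'   query-forward; `strand == "-"` means the subject hit is on the reverse
#'   complement).
#' @export
local_search <- function(query, subject, min_length = 100L, min_identity = 0.9,
                         par = ALIGN_DEFAULTS) {
  if (!nzchar(query)) abort("empty query")
  query <- toupper(query)
  if (inherits(subject, "kmer_index")) {
    index <- subject
    n <- index$length
  } else {
    s <- if (inherits(subject, "replicon")) subject$sequence else toupper(subject)
    topology <- if (inherits(subject, "replicon")) subject$topology else "linear"
    n <- nchar(s)
    if (!nzchar(s)) abort("empty subject")
    if (topology == "circular") {
      ext <- min(n, nchar(query) + 200L)
      s_ext <- paste0(s, substr(s, 1L, ext))
    } else s_ext <- s
    index <- build_kmer_index(s_ext, k = par$k)
    index$length <- n
    index$topology <- topology
    if (inherits(subject, "replicon")) index$replicon_id <- subject$replicon_id
  }
  if (min_length < par$k) abort("min_length must be >= seed k")
  out <- bind_rows(
    search_one_strand(query, "query", index, "+", par, min_length, min_identity),
    search_one_strand(revcomp(query), "query", index, "-", par, min_length, min_identity)
  )
  if (!nrow(out)) return(out)
  # fold extension-only hits of circular subjects back onto [1, n]
  out <- mutate(out,
                shift = ifelse(.data$s_start > n, n, 0L),
                s_start = .data$s_start - .data$shift,
                s_end = .data$s_end - .data$shift) |> select(-"shift")
  out <- distinct(out, .data$q_start, .data$q_end, .data$s_start, .data$s_end,
                  .data$strand, .keep_all = TRUE)
  drop_contained_blocks(out)
}

drop_contained_blocks <- function(blocks) {
  if (nrow(blocks) < 2L) return(blocks)
  blocks <- arrange(blocks, desc(.data$score), desc(.data$length))
  keep <- rep(TRUE, nrow(blocks))
  for (i in seq_len(nrow(blocks))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (blocks$strand[i] == blocks$strand[j] &&
          blocks$q_start[i] >= blocks$q_start[j] && blocks$q_end[i] <= blocks$q_end[j] &&
          blocks$s_start[i] >= blocks$s_start[j] && blocks$s_end[i] <= blocks$s_end[j]) {
        keep[i] <- FALSE; break
      }
    }
  }
  blocks[keep, ]
}

#' Merge alignment blocks separated by small gaps on the query
#'
#' @param blocks tibble of blocks on one (query, subject, strand) triple.
#' @param max_gap gaps of at most this many bp are bridged.
#' @return tibble of merged query intervals with subject extent and summed
#'   aligned statistics; intervals are sorted and pairwise separated by more
#'   than `max_gap`.
#' @export
merge_blocks <- function(blocks, max_gap = 1000L) {
  if (!nrow(blocks)) {
    return(tibble(q_start = integer(), q_end = integer(), s_start = integer(),
                  s_end = integer(), n_blocks = integer(),
                  aligned_length = integer(), identity = numeric(),
                  length = integer()))
  }
  b <- arrange(blocks, .data$q_start, .data$q_end)
  # gap between intervals = uncovered bp; bridge when gap <= max_gap
  grp <- cumsum(c(TRUE, b$q_start[-1] - cummax(b$q_end)[-nrow(b)] - 1L > max_gap))
  b |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(q_start = min(.data$q_start), q_end = max(.data$q_end),
              s_start = min(.data$s_start), s_end = max(.data$s_end),
              n_blocks = dplyr::n(),
              aligned_length = sum(.data$length),
              identity = sum(.data$matches) / sum(.data$columns),
              .groups = "drop") |>
    mutate(length = .data$q_end - .data$q_start + 1L) |>
    select(-".grp") |>
    arrange(.data$q_start)
}

# ---------------------------------------------------------------------------
# inverted / direct repeat detection

empty_repeats <- function() {
  tibble(left_start = integer(), left_end = integer(), right_start = integer(),
         right_end = integer(), kind = character(), mismatches = integer(),
         repeat_length = integer())
}

#' Find terminal inverted repeats of an element sequence
#'
#' Scans for arm pairs with the left arm starting within the first `window`
#' bp and the right arm ending within the last `window` bp, the right arm
#' reverse-complement-matching the left with at most `max_mismatch`
#' mismatches. Results are ranked by arm length (desc), mismatches (asc) and
#' terminal proximity; heavily overlapping alternates are collapsed.
#'
#' @param sequence element DNA string.
#' @param arm_min,arm_max arm length range, bp.
#' @param max_mismatch maximum mismatches between the arms.
#' @param window terminal search window, bp.
#' @export
find_inverted_repeats <- function(sequence, arm_min = 10L, arm_max = 50L,
                                  max_mismatch = 3L, window = 150L) {
  n <- nchar(sequence)
  if (window > n / 2) window <- floor(n / 2)
  if (n < 2L * arm_min) return(empty_repeats())
  si <- utf8ToInt(sequence)
  ci <- utf8ToInt(complement_chars(sequence))
  hits <- list()
  for (L in seq(min(arm_max, floor(n / 2)), arm_min)) {
    is_ <- seq_len(min(window, n - L + 1L))
    js <- seq(max(n - window + 1L, L), n)
    if (!length(is_) || !length(js)) next
    M <- matrix(0L, length(is_), length(js))
    for (l in 0:(L - 1L)) {
      M <- M + outer(si[is_ + l], ci[js - l], "!=")
    }
    idx <- which(M <= max_mismatch, arr.ind = TRUE)
    if (!nrow(idx)) next
    for (r in seq_len(nrow(idx))) {
      i <- is_[idx[r, 1]]; j <- js[idx[r, 2]]
      if (j - L + 1L <= i + L - 1L) next  # overlapping arms
      hits[[length(hits) + 1L]] <- tibble(
        left_start = i, left_end = i + L - 1L,
        right_start = j - L + 1L, right_end = j,
        kind = "inverted", mismatches = M[idx[r, 1], idx[r, 2]],
        repeat_length = L)
    }
  }
  if (!length(hits)) return(empty_repeats())
  out <- bind_rows(hits) |>
    # keep the longest arm for each (left_start, right_end) anchor pair
    group_by(.data$left_start, .data$right_end) |>
    slice_max(.data$repeat_length, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    arrange(desc(.data$repeat_length), .data$mismatches,
            (.data$left_start - 1L) + (n - .data$right_end))
  dedup_repeat_pairs(out)
}

dedup_repeat_pairs <- function(out) {
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (out$left_start[i] <= out$left_end[j] && out$left_end[i] >= out$left_start[j] &&
          out$right_start[i] <= out$right_end[j] && out$right_end[i] >= out$right_start[j]) {
        keep[i] <- FALSE; break
      }
    }
  }
  out[keep, ]
}

#' Find direct repeats flanking a genomic island
#'
#' Searches for forward-matching arm pairs with one arm near the island
#' start and the other near the island end; seed arms of `repeat_length` are
#' extended while following bases keep matching exactly.
#'
#' @param sequence replicon DNA string.
#' @param island c(start, end) interval of the island, 1-based inclusive.
#' @param repeat_length seed arm length, bp.
#' @param max_mismatch maximum mismatches within the seed arms.
#' @param window search window around each island boundary, bp.
#' @export
find_direct_repeats <- function(sequence, island, repeat_length = 12L,
                                max_mismatch = 0L, window = 500L) {
  n <- nchar(sequence)
  s <- island[1]; e <- island[2]
  if (s < 1L || e > n || s >= e) abort("island must lie within the sequence")
  L <- repeat_length
  si <- utf8ToInt(sequence)
  is_ <- seq(max(1L, s - window), min(s + window - 1L, n - L + 1L))
  js <- seq(max(e - window + 1L, L), min(n, e + window))
  if (!length(is_) || !length(js)) return(empty_repeats())
  M <- matrix(0L, length(is_), length(js))
  for (l in 0:(L - 1L)) {
    M <- M + outer(si[is_ + l], si[js - L + 1L + l], "!=")
  }
  idx <- which(M <= max_mismatch, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_repeats())
  hits <- purrr::map_dfr(seq_len(nrow(idx)), function(r) {
    i <- is_[idx[r, 1]]; j <- js[idx[r, 2]]
    rs <- j - L + 1L
    if (rs <= i + L - 1L) return(NULL)
    # exact extension to the right
    ext <- 0L
    while (i + L + ext <= rs - 1L && j + 1L + ext <= n &&
           si[i + L + ext] == si[j + 1L + ext]) ext <- ext + 1L
    tibble(left_start = i, left_end = i + L - 1L + ext,
           right_start = rs, right_end = j + ext,
           kind = "direct", mismatches = M[idx[r, 1], idx[r, 2]],
           repeat_length = L + ext)
  })
  if (!nrow(hits)) return(empty_repeats())
  out <- hits |>
    distinct() |>
    arrange(desc(.data$repeat_length), .data$mismatches,
            abs(.data$left_start - s) + abs(.data$right_end - e))
  dedup_repeat_pairs(out)
}

# ---------------------------------------------------------------------------
# in-silico PCR

primer_sites <- function(primer, s, max_mismatch) {
  l <- nchar(primer)
  S <- Biostrings::DNAString(s)
  base_at <- function(pos) {
    if (!length(pos)) return(character(0))
    substring(s, pos, pos)
  }
  plus <- Biostrings::matchPattern(Biostrings::DNAString(primer), S,
                                   max.mismatch = max_mismatch)
  plus_keep <- base_at(BiocGenerics::end(plus)) == substr(primer, l, l)
  minus <- Biostrings::matchPattern(Biostrings::reverseComplement(Biostrings::DNAString(primer)),
                                    S, max.mismatch = max_mismatch)
  minus_keep <- base_at(BiocGenerics::start(minus)) ==
    complement_chars(substr(primer, l, l))
  list(plus = tibble(start = BiocGenerics::start(plus)[plus_keep],
                     end = BiocGenerics::end(plus)[plus_keep]),
       minus = tibble(start = BiocGenerics::start(minus)[minus_keep],
                      end = BiocGenerics::end(minus)[minus_keep]))
}

#' Predict PCR products on a linear or circular template
#'
#' A product is reported for every pair of binding sites of the two primers
#' on opposite strands pointing toward each other, with product length at
#' most `max_product`. The 3'-terminal base of a primer must match exactly;
#' up to `max_mismatch` mismatches are tolerated elsewhere. On circular
#' templates, origin-spanning products are found and the product set is
#' rotation-invariant; on linear templates no product spans position 1.
#'
#' @param template a [replicon()] or DNA string (then assumed linear).
#' @param fwd,rev primer sequences, at least 15 nt, 5'->3'.
#' @param max_product maximum product length, bp.
#' @param max_mismatch non-3' mismatches tolerated per primer site.
#' @return tibble of products (site coordinates 1-based on the forward
#'   strand; `plus_primer` names the primer annealing to the plus strand).
#' @export
in_silico_pcr <- function(template, fwd, rev, max_product = 10000L,
                          max_mismatch = 2L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) abort("primers must be >= 15 nt")
  s <- if (inherits(template, "replicon")) template$sequence else toupper(template)
  topology <- if (inherits(template, "replicon")) template$topology else "linear"
  n <- nchar(s)
  s_search <- if (topology == "circular") paste0(s, substr(s, 1L, min(n, max_product))) else s
  sf <- primer_sites(fwd, s_search, max_mismatch)
  sr <- primer_sites(rev, s_search, max_mismatch)
  pair_up <- function(plus, minus, plus_name) {
    if (!nrow(plus) || !nrow(minus)) return(NULL)
    tidyr::crossing(rename_with(plus, ~ paste0("p_", .x)),
                    rename_with(minus, ~ paste0("m_", .x))) |>
      filter(.data$p_start <= n,
             .data$m_end - .data$p_start + 1L >= nchar(fwd) + nchar(rev),
             .data$m_start > .data$p_end,
             .data$m_end - .data$p_start + 1L <= max_product) |>
      transmute(fwd_start = if (plus_name == "fwd") .data$p_start else mod1(.data$m_start, n),
                fwd_end = if (plus_name == "fwd") .data$p_end else mod1(.data$m_end, n),
                rev_start = if (plus_name == "fwd") mod1(.data$m_start, n) else .data$p_start,
                rev_end = if (plus_name == "fwd") mod1(.data$m_end, n) else .data$p_end,
                product_start = .data$p_start,
                product_length = .data$m_end - .data$p_start + 1L,
                plus_primer = plus_name)
  }
  out <- bind_rows(pair_up(sf$plus, sr$minus, "fwd"),
                   pair_up(sr$plus, sf$minus, "rev"))
  if (is.null(out) || !nrow(out)) {
    return(tibble(fwd_start = integer(), fwd_end = integer(), rev_start = integer(),
                  rev_end = integer(), product_start = integer(),
                  product_length = integer(), plus_primer = character(),
                  template_form = character()))
  }
  out |>
    filter(.data$product_length <= n) |>
    mutate(product_start = mod1(.data$product_start, n),
           template_form = topology) |>
    distinct(.data$fwd_start, .data$rev_start, .data$plus_primer,
             .keep_all = TRUE) |>
    arrange(.data$product_start)
}
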