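# Insertion-sequence discovery, copy census, gene-disruption calls and
# composite-transposon detection.
#
# The discovery heuristic mirrors manual IS curation: transposase
# annotations of identical length are multi-copy candidates; each candidate
# CDS is extracted with 1000 bp of flanking sequence, aligned back to all
# genomes, and confirmed as an IS when at least two loci match; element
# boundaries are the interval shared by all confirmed copies, and terminal
# inverted repeats are then sought in the terminal windows.

MOBILE_KEYWORDS <- c("transposase", "mobile element")
INTEGRASE_KEYWORDS <- c("integrase")

#' Group candidate transposase CDS by identical length
#'
#' CDS whose product matches the mobile-element keyword set (transposase /
#' mobile element; integrases are tallied separately, not as IS anchors) are
#' grouped by identical translation length; groups of two or more are
#' multi-copy IS candidates.
#'
#' @param genome a [genome()].
#' @return tibble of candidate CDS with `group_id`, `group_size` and
#'   `multi_copy` columns.
#' @export
find_transposase_anchors <- function(genome) {
  g <- genes(genome) |> filter(.data$kind == "CDS")
  lp <- tolower(g$product %||% "")
  is_integrase <- grepl("integrase", lp, fixed = TRUE)
  is_mobile <- Reduce(`|`, lapply(MOBILE_KEYWORDS, function(k) grepl(k, lp, fixed = TRUE)))
  cand <- g[is_mobile & !is_integrase, ]
  if (!nrow(cand)) {
    return(mutate(cand, aa_length = integer(), group_id = character(),
                  group_size = integer(), multi_copy = logical()))
  }
  cand |>
    mutate(aa_length = nchar(.data$translation)) |>
    group_by(.data$aa_length) |>
    mutate(group_id = sprintf("len%d", .data$aa_length[1]),
           group_size = dplyr::n(), multi_copy = dplyr::n() >= 2L) |>
    ungroup() |>
    arrange(desc(.data$group_size), .data$aa_length)
}

#' Count transposase and integrase annotations in a genome
#' @param genome a [genome()].
#' @export
mobile_element_counts <- function(genome) {
  g <- genes(genome) |> filter(.data$kind == "CDS")
  lp <- tolower(g$product %||% "")
  tibble(genome = genome$strain,
         transposases = sum(Reduce(`|`, lapply(MOBILE_KEYWORDS, function(k)
           grepl(k, lp, fixed = TRUE))) & !grepl("integrase", lp, fixed = TRUE)),
         integrases = sum(grepl("integrase", lp, fixed = TRUE)))
}

#' Extract an anchor CDS with flanking sequence
#'
#' @param anchor one row of [find_transposase_anchors()] (locus_tag,
#'   replicon_id, start, end).
#' @param genome the genome it came from.
#' @param flank bp of context on each side; extraction wraps on circular
#'   replicons and is truncated (and flagged) at linear contig edges.
#' @return list (sequence, anchor_offset, truncated, genome, locus_tag).
#' @export
extract_candidate <- function(anchor, genome, flank = 1000L) {
  r <- genome$replicons[[anchor$replicon_id]]
  n <- nchar(r$sequence)
  from <- anchor$start - flank
  to <- anchor$end + flank
  truncated <- FALSE
  if (r$topology == "circular") {
    seq <- extract_circular(r$sequence, mod1(from, n), if (from < 1L) to + n else to)
  } else {
    f2 <- max(1L, from); t2 <- min(n, to)
    truncated <- f2 != from || t2 != to
    seq <- substr(r$sequence, f2, t2)
    from <- f2
  }
  list(sequence = seq, genome = genome$strain, locus_tag = anchor$locus_tag,
       replicon_id = anchor$replicon_id,
       anchor_offset = anchor$start - (if (r$topology == "circular") from else from) + 1L,
       anchor_aa_length = nchar(anchor$translation %||% ""),
       truncated = truncated)
}

empty_copies <- function() {
  tibble(element = character(), genome = character(), replicon_id = character(),
         s_start = integer(), s_end = integer(), strand = character(),
         identity = numeric(), q_start = integer(), q_end = integer(),
         span_fraction = numeric(), full = logical())
}

# search one query across all replicons of a genome list
search_genomes <- function(query, genomes, min_length, min_identity, indexes = NULL) {
  purrr::map_dfr(genomes, function(g) {
    purrr::map_dfr(g$replicons, function(r) {
      idx <- if (!is.null(indexes)) indexes[[paste(g$strain, r$replicon_id)]] else r
      hits <- local_search(query, idx, min_length = min_length,
                          min_identity = min_identity)
      if (!nrow(hits)) return(NULL)
      mutate(hits, genome = g$strain, replicon_id = r$replicon_id)
    })
  })
}

#' Prebuild k-mer indexes for a set of genomes
#' @param genomes list of [genome()].
#' @param k seed size.
#' @param ext bp of origin extension for circular replicons.
#' @export
genome_indexes <- function(genomes, k = ALIGN_DEFAULTS$k, ext = 10000L) {
  out <- list()
  for (g in genomes) for (r in g$replicons) {
    n <- nchar(r$sequence)
    s <- if (r$topology == "circular") paste0(r$sequence, substr(r$sequence, 1L, min(n, ext))) else r$sequence
    idx <- build_kmer_index(s, k)
    idx$length <- n
    idx$topology <- r$topology
    idx$replicon_id <- r$replicon_id
    out[[paste(g$strain, r$replicon_id)]] <- idx
  }
  out
}

#' Confirm that a candidate occurs at multiple loci
#'
#' Aligns the flanked candidate against all genomes. The element region is
#' estimated as the maximal run of query positions covered by at least two
#' distinct loci; loci spanning at least `min_span` of that region are full
#' copies. The candidate is confirmed as an IS when at least `min_copies`
#' full copies exist.
#'
#' @param candidate output of [extract_candidate()] (or a DNA string).
#' @param genomes list of [genome()].
#' @param min_copies loci required for IS status.
#' @param min_identity minimum alignment identity for a copy.
#' @param min_span minimum covered fraction of the element region.
#' @param indexes optional [genome_indexes()] for reuse.
#' @return tibble of loci (full and partial); empty when unconfirmed. The
#'   estimated element interval on the candidate is in attribute
#'   `element_span`.
#' @export
confirm_multicopy <- function(candidate, genomes, min_copies = 2L,
                              min_identity = 0.90, min_span = 0.80,
                              indexes = NULL) {
  qseq <- if (is.character(candidate)) candidate else candidate$sequence
  hits <- search_genomes(qseq, genomes, min_length = 200L,
                         min_identity = min_identity, indexes = indexes)
  if (nrow(hits) < min_copies) return(empty_copies())
  # coverage depth over query positions; element = longest run covered >= 2x
  cov <- integer(nchar(qseq))
  for (i in seq_len(nrow(hits))) {
    cov[hits$q_start[i]:hits$q_end[i]] <- cov[hits$q_start[i]:hits$q_end[i]] + 1L
  }
  multi <- cov >= 2L
  if (!any(multi)) return(empty_copies())
  r <- rle(multi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  el <- c(starts[best], ends[best])
  el_len <- el[2] - el[1] + 1L
  out <- hits |>
    mutate(span_fraction = (pmin(.data$q_end, el[2]) - pmax(.data$q_start, el[1]) + 1L) / el_len,
           span_fraction = pmax(.data$span_fraction, 0),
           full = .data$span_fraction >= min_span) |>
    transmute(element = NA_character_, genome = .data$genome,
              replicon_id = .data$replicon_id, s_start = .data$s_start,
              s_end = .data$s_end, strand = .data$strand,
              identity = .data$identity, q_start = .data$q_start,
              q_end = .data$q_end, span_fraction = .data$span_fraction,
              full = .data$full)
  if (sum(out$full) < min_copies) return(empty_copies())
  attr(out, "element_span") <- el
  out
}

#' Delimit an IS element from its confirmed copies
#'
#' Boundaries are the maximal candidate interval shared by all full copies
#' (the intersection of their aligned extents); terminal inverted repeats
#' are then sought within the element's terminal windows. Elements without
#' detectable IRs are retained with empty IR fields.
#'
#' @param candidate output of [extract_candidate()].
#' @param copies tibble from [confirm_multicopy()].
#' @param name element name.
#' @param ir_args arguments passed to [find_inverted_repeats()].
#' @return object of class `is_element`.
#' @export
delimit_element <- function(candidate, copies, name = "ISsyn1",
                            ir_args = list()) {
  full <- filter(copies, .data$full)
  if (nrow(full) < 2L) abort("need at least 2 full copies to delimit an element")
  span <- attr(copies, "element_span")
  qlo <- full$q_start; qhi <- full$q_end
  if (!is.null(span)) {
    # the source locus aligns across its flanks too; judge copies on the
    # multi-copy (element) region only
    qlo <- pmax(qlo, span[1]); qhi <- pmin(qhi, span[2])
  }
  lens <- qhi - qlo + 1L
  if (max(lens) > 2 * min(lens)) {
    abort("copies disagree by more than 50% in length; ambiguous element")
  }
  qs <- max(qlo); qe <- min(qhi)
  qseq <- if (is.character(candidate)) candidate else candidate$sequence
  el_seq <- substr(qseq, qs, qe)
  irs <- do.call(find_inverted_repeats, c(list(el_seq), ir_args))
  left_ir <- right_ir <- ""
  if (nrow(irs)) {
    left_ir <- substr(el_seq, irs$left_start[1], irs$left_end[1])
    right_ir <- substr(el_seq, irs$right_start[1], irs$right_end[1])
  }
  tp <- NULL
  if (!is.character(candidate)) {
    tp <- list(genome = candidate$genome, locus_tag = candidate$locus_tag)
  }
  structure(list(name = name, transposase_locus = tp,
                 boundaries = c(qs, qe), element_sequence = el_seq,
                 left_ir = left_ir, right_ir = right_ir, ir_table = irs,
                 transposase_translation = attr(copies, "transposase_translation")),
            class = "is_element")
}

#' @export
print.is_element <- function(x, ...) {
  cat(sprintf("<is_element> %s: %d bp, IRs %s/%s bp\n", x$name,
              nchar(x$element_sequence), nchar(x$left_ir), nchar(x$right_ir)))
  invisible(x)
}

#' Discover IS elements in a genome set
#'
#' Runs the full heuristic: length-grouped transposase anchors, flanked
#' extraction, multi-copy confirmation, boundary delimitation and collapse
#' of near-identical elements (default 95% identity).
#'
#' @param genomes list of [genome()].
#' @param flank bp of flanking context.
#' @param collapse_identity elements at or above this nucleotide identity are
#'   considered duplicates of one another.
#' @inheritParams confirm_multicopy
#' @return named list of `is_element`.
#' @export
discover_is_elements <- function(genomes, flank = 1000L, min_copies = 2L,
                                 min_identity = 0.90, min_span = 0.80,
                                 collapse_identity = 0.95) {
  indexes <- genome_indexes(genomes)
  anchors <- purrr::map_dfr(genomes, find_transposase_anchors) |>
    filter(.data$multi_copy)
  if (!nrow(anchors)) return(list())
  groups <- split(anchors, list(anchors$group_id, nchar(anchors$translation)), drop = TRUE)
  elements <- list()
  for (grp in groups) {
    a <- grp[1, ]
    g <- purrr::detect(genomes, ~ .x$strain == a$genome)
    cand <- extract_candidate(a, g, flank = flank)
    copies <- confirm_multicopy(cand, genomes, min_copies = min_copies,
                                min_identity = min_identity, min_span = min_span,
                                indexes = indexes)
    if (!nrow(copies)) next
    attr(copies, "transposase_translation") <- a$translation
    el <- delimit_element(cand, copies, name = sprintf("ISsyn%d", length(elements) + 1L))
    # collapse near-identical elements
    dup <- FALSE
    for (prev in elements) {
      hits <- local_search(el$element_sequence, prev$element_sequence,
                          min_length = round(0.8 * nchar(el$element_sequence)),
                          min_identity = collapse_identity)
      if (nrow(hits)) { dup <- TRUE; break }
    }
    if (!dup) elements[[el$name]] <- el
  }
  elements
}

#' Locate all copies of an IS library across genomes
#'
#' @param library named list of `is_element`.
#' @param genomes list of [genome()].
#' @param min_identity,min_span copy-confirmation thresholds; loci covering
#'   less than `min_span` of the element are flagged partial.
#' @param indexes optional [genome_indexes()].
#' @return tibble of copies with `full` flag.
#' @export
is_copies <- function(library, genomes, min_identity = 0.90, min_span = 0.80,
                      indexes = NULL) {
  if (is.null(indexes)) indexes <- genome_indexes(genomes)
  purrr::map_dfr(library, function(el) {
    elen <- nchar(el$element_sequence)
    hits <- search_genomes(el$element_sequence, genomes,
                           min_length = max(ALIGN_DEFAULTS$k, round(0.3 * elen)),
                           min_identity = min_identity, indexes = indexes)
    if (!nrow(hits)) return(NULL)
    hits |>
      mutate(element = el$name,
             span_fraction = (.data$q_end - .data$q_start + 1L) / elen,
             full = .data$span_fraction >= min_span &
               (.data$s_end - .data$s_start + 1L) <= 1.2 * elen) |>
      select("element", "genome", "replicon_id", "s_start", "s_end", "strand",
             "identity", "q_start", "q_end", "span_fraction", "full")
  })
}

#' IS copy census across genomes
#'
#' @inheritParams is_copies
#' @return tibble (element, genome, copies, partial_copies); full and
#'   partial copies are tallied separately.
#' @export
is_census <- function(library, genomes, min_identity = 0.90, min_span = 0.80,
                      indexes = NULL) {
  copies <- is_copies(library, genomes, min_identity, min_span, indexes)
  gnames <- vapply(genomes, `[[`, "", "strain")
  grid <- tidyr::crossing(element = names(library), genome = gnames)
  counts <- if (nrow(copies)) {
    copies |>
      group_by(.data$element, .data$genome) |>
      summarise(copies = sum(.data$full), partial_copies = sum(!.data$full),
                .groups = "drop")
  } else tibble(element = character(), genome = character(),
                copies = integer(), partial_copies = integer())
  left_join(grid, counts, by = c("element", "genome")) |>
    mutate(copies = tidyr::replace_na(.data$copies, 0L),
           partial_copies = tidyr::replace_na(.data$partial_copies, 0L))
}

#' Detect IS insertions that disrupt genes
#'
#' A full copy disrupts a gene when the annotation shows either a CDS
#' spanning the whole IS interval, or a CDS split into two parts with the
#' same product immediately abutting the IS on both sides (within `tol` bp).
#'
#' @param copies tibble from [is_copies()].
#' @param genomes list of [genome()].
#' @param tol adjacency tolerance, bp.
#' @return tibble of disruption records with insertion offsets.
#' @export
detect_gene_disruption <- function(copies, genomes, tol = 5L) {
  full <- filter(copies, .data$full)
  if (!nrow(full)) {
    return(tibble(genome = character(), replicon_id = character(),
                  element = character(), locus_tag = character(),
                  product = character(), copy_start = integer(),
                  copy_end = integer(), insertion_offset = integer(),
                  mode = character()))
  }
  feats <- genes(genomes) |> filter(.data$kind == "CDS")
  purrr::map_dfr(seq_len(nrow(full)), function(i) {
    cp <- full[i, ]
    f <- filter(feats, .data$genome == cp$genome, .data$replicon_id == cp$replicon_id)
    span <- filter(f, .data$start < cp$s_start, .data$end > cp$s_end)
    if (nrow(span)) {
      return(tibble(genome = cp$genome, replicon_id = cp$replicon_id,
                    element = cp$element, locus_tag = span$locus_tag[1],
                    product = span$product[1], copy_start = cp$s_start,
                    copy_end = cp$s_end,
                    insertion_offset = cp$s_start - span$start[1],
                    mode = "spanning"))
    }
    left <- filter(f, abs(.data$end - (cp$s_start - 1L)) <= tol)
    right <- filter(f, abs(.data$start - (cp$s_end + 1L)) <= tol)
    if (nrow(left) && nrow(right)) {
      hit <- inner_join(left, right, by = "product", suffix = c("_l", "_r"))
      if (nrow(hit)) {
        return(tibble(genome = cp$genome, replicon_id = cp$replicon_id,
                      element = cp$element, locus_tag = hit$locus_tag_l[1],
                      product = hit$product[1], copy_start = cp$s_start,
                      copy_end = cp$s_end,
                      insertion_offset = cp$s_start - hit$start_l[1],
                      mode = "split"))
      }
    }
    NULL
  })
}

ir_cross_identity <- function(el_a, el_b) {
  cands <- c()
  for (side in c("left_ir", "right_ir")) {
    a <- el_a[[side]]; b <- el_b[[side]]
    if (nzchar(a) && nzchar(b)) {
      p <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                         type = "global",
                                         substitutionMatrix = nt_submat(ALIGN_DEFAULTS),
                                         gapOpening = 5, gapExtension = 2)
      ap <- utf8ToInt(as.character(Biostrings::alignedPattern(p)))
      as_ <- utf8ToInt(as.character(Biostrings::alignedSubject(p)))
      cands <- c(cands, sum(ap == as_ & ap != utf8ToInt("-")) / length(ap))
    }
  }
  if (!length(cands)) NA_real_ else max(cands)
}

tpase_identity <- function(el_a, el_b) {
  a <- el_a$transposase_translation; b <- el_b$transposase_translation
  if (is.null(a) || is.null(b) || !nzchar(a %||% "") || !nzchar(b %||% "")) {
    return(if (identical(el_a$name, el_b$name)) 1.0 else NA_real_)
  }
  if (identical(a, b)) return(1.0)
  unname(protein_identity_coverage(a, b)["identity"])
}

#' Detect composite-transposon candidates
#'
#' Every ordered pair of full IS copies on one replicon whose cargo gap is
#' at most `max_cargo`, whose transposases share at least
#' `min_tpase_identity` amino-acid identity, and whose inverted repeats (when
#' both elements have them) share at least `min_ir_identity` nucleotide
#' identity, is emitted as one candidate with its cargo gene list.
#'
#' @param copies tibble from [is_copies()].
#' @param genomes list of [genome()].
#' @param library the IS library the copies refer to.
#' @param max_cargo maximum cargo length, bp.
#' @param min_tpase_identity minimum transposase amino-acid identity.
#' @param min_ir_identity minimum IR nucleotide cross-identity.
#' @export
detect_composite_transposons <- function(copies, genomes, library,
                                         max_cargo = 20000L,
                                         min_tpase_identity = 0.60,
                                         min_ir_identity = 0.60) {
  full <- filter(copies, .data$full)
  feats <- genes(genomes) |> filter(.data$kind == "CDS")
  out <- list()
  for (key in unique(paste(full$genome, full$replicon_id))) {
    sub <- full[paste(full$genome, full$replicon_id) == key, ]
    sub <- arrange(sub, .data$s_start)
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) for (j in (i + 1L):nrow(sub)) {
      gap <- sub$s_start[j] - sub$s_end[i] - 1L
      if (gap <= 0L || gap > max_cargo) next
      el_i <- library[[sub$element[i]]]; el_j <- library[[sub$element[j]]]
      tp <- tpase_identity(el_i, el_j)
      if (is.na(tp) || tp < min_tpase_identity) next
      iri <- ir_cross_identity(el_i, el_j)
      if (!is.na(iri) && iri < min_ir_identity) next
      cargo <- feats |>
        filter(.data$genome == sub$genome[i], .data$replicon_id == sub$replicon_id[i],
               .data$start > sub$s_end[i], .data$end < sub$s_start[j])
      out[[length(out) + 1L]] <- tibble(
        genome = sub$genome[i], replicon_id = sub$replicon_id[i],
        left_element = sub$element[i], right_element = sub$element[j],
        left_start = sub$s_start[i], left_end = sub$s_end[i],
        right_start = sub$s_start[j], right_end = sub$s_end[j],
        cargo_start = sub$s_end[i] + 1L, cargo_end = sub$s_start[j] - 1L,
        cargo_length = gap, n_cargo_genes = nrow(cargo),
        cargo_genes = list(select(cargo, "locus_tag", "product")),
        transposase_identity = tp, ir_cross_identity = iri)
    }
  }
  if (!length(out)) {
    return(tibble(genome = character(), replicon_id = character(),
                  left_element = character(), right_element = character(),
                  left_start = integer(), left_end = integer(),
                  right_start = integer(), right_end = integer(),
                  cargo_start = integer(), cargo_end = integer(),
                  cargo_length = integer(), n_cargo_genes = integer(),
                  cargo_genes = list(), transposase_identity = numeric(),
                  ir_cross_identity = numeric()))
  }
  bind_rows(out)
}

#' Write an IS library as FASTA plus TSV metadata
#' @param library named list of `is_element`.
#' @param dir output directory.
#' @export
write_is_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(vapply(library, `[[`, "", "element_sequence"))
  names(seqs) <- names(library)
  Biostrings::writeXStringSet(seqs, file.path(dir, "is_elements.fasta"))
  meta <- purrr::map_dfr(library, function(el) {
    tibble(name = el$name, length = nchar(el$element_sequence),
           left_ir = el$left_ir, right_ir = el$right_ir,
           transposase_genome = el$transposase_locus$genome %||% NA_character_,
           transposase_locus = el$transposase_locus$locus_tag %||% NA_character_)
  })
  readr::write_tsv(meta, file.path(dir, "is_elements.tsv"))
  invisible(dir)
}
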