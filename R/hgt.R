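# Cross-species homology blocks (putative HGT regions), their functional
# composition, and plasmid-to-chromosome integration maps.

#' Detect cross-species homology blocks in a recipient genome
#'
#' Aligns every replicon of every partner genome (of a different species)
#' against the recipient. Raw alignment blocks are filtered at
#' `min_length` / `min_identity`, then merged per partner when separated by
#' at most `merge_gap` bp on the recipient; both the raw aligned length and
#' the merged span are reported. Each region is annotated with the
#' recipient genes it contains and their functional categories.
#'
#' @param recipient a [genome()].
#' @param partners list of [genome()] with a different `species_label`
#'   (same-species partners are skipped with a warning).
#' @param min_length minimum raw block length, bp.
#' @param min_identity minimum raw block identity.
#' @param merge_gap merge blocks separated by at most this many bp.
#' @param indexes optional prebuilt indexes of the recipient
#'   ([genome_indexes()]).
#' @return tibble of regions with a `genes` list-column.
#' @export
cross_species_regions <- function(recipient, partners, min_length = 2000L,
                                  min_identity = 0.90, merge_gap = 1000L,
                                  indexes = NULL) {
  same <- vapply(partners, function(p) identical(p$species_label, recipient$species_label),
                 logical(1))
  if (any(same)) {
    warn(sprintf("%d partner(s) share the recipient species label and were excluded",
                 sum(same)))
    partners <- partners[!same]
  }
  if (is.null(indexes)) indexes <- genome_indexes(list(recipient))
  feats <- genes(recipient) |> filter(.data$kind == "CDS")
  out <- list()
  for (p in partners) for (pr in p$replicons) {
    for (rr in recipient$replicons) {
      idx <- indexes[[paste(recipient$strain, rr$replicon_id)]]
      blocks <- local_search(pr$sequence, idx, min_length = min_length,
                            min_identity = min_identity)
      if (!nrow(blocks)) next
      # re-key blocks on recipient coordinates before merging
      rblocks <- blocks |>
        mutate(r_start = .data$s_start, r_end = .data$s_end,
               p_start = .data$q_start, p_end = .data$q_end) |>
        mutate(q_start = .data$r_start, q_end = .data$r_end,
               s_start = .data$p_start, s_end = .data$p_end,
               length = .data$q_end - .data$q_start + 1L)
      for (str in unique(rblocks$strand)) {
        merged <- merge_blocks(filter(rblocks, .data$strand == str), max_gap = merge_gap)
        if (!nrow(merged)) next
        out[[length(out) + 1L]] <- merged |>
          mutate(recipient = recipient$strain, replicon_id = rr$replicon_id,
                 partner = p$strain, partner_species = p$species_label,
                 partner_replicon = pr$replicon_id, strand = str)
      }
    }
  }
  if (!length(out)) {
    return(tibble(recipient = character(), replicon_id = character(),
                  start = integer(), end = integer(), length = integer(),
                  raw_length = integer(), identity = numeric(),
                  partner = character(), partner_species = character(),
                  partner_replicon = character(), strand = character(),
                  n_blocks = integer(), n_genes = integer(), genes = list(),
                  label = character()))
  }
  regions <- bind_rows(out) |>
    rename(start = "q_start", end = "q_end",
           partner_start = "s_start", partner_end = "s_end") |>
    mutate(raw_length = .data$aligned_length)
  regions$length <- regions$end - regions$start + 1L
  regions$genes <- purrr::map(seq_len(nrow(regions)), function(i) {
    g <- feats |>
      filter(.data$replicon_id == regions$replicon_id[i],
             .data$start >= regions$start[i], .data$end <= regions$end[i]) |>
      select("locus_tag", "product")
    mutate(g, category = classify_product(.data$product))
  })
  regions |>
    mutate(n_genes = vapply(.data$genes, nrow, integer(1)),
           label = NA_character_) |>
    select("recipient", "replicon_id", "start", "end", "length", "raw_length",
           "identity", "partner", "partner_species", "partner_replicon",
           "strand", "n_blocks", "n_genes", "genes", "label") |>
    arrange(.data$replicon_id, .data$start)
}

#' Functional composition of HGT regions
#'
#' @param regions tibble from [cross_species_regions()].
#' @return tibble (category, n_genes, percent); counts sum to the total
#'   number of genes across regions.
#' @export
classify_hgt_regions <- function(regions) {
  if (!nrow(regions)) return(tibble(category = character(), n_genes = integer(),
                                    percent = numeric()))
  g <- bind_rows(regions$genes)
  if (!nrow(g)) return(tibble(category = character(), n_genes = integer(),
                              percent = numeric()))
  g |>
    count(.data$category, name = "n_genes") |>
    mutate(percent = 100 * .data$n_genes / sum(.data$n_genes)) |>
    arrange(desc(.data$n_genes))
}

#' Map integration of a plasmid into chromosomes
#'
#' Aligns the plasmid against each genome, projects hits onto plasmid
#' coordinates and merges them; reports the covered fraction of the plasmid
#' per genome together with the plasmid features left uncovered (for
#' example, replication genes absent from the integrated copies).
#'
#' @param plasmid a [replicon()].
#' @param genomes list of [genome()].
#' @param min_identity minimum block identity.
#' @param min_block minimum block length, bp.
#' @param merge_gap merge distance on plasmid coordinates, bp.
#' @param indexes optional [genome_indexes()] of `genomes`.
#' @return tibble per genome with coverage fraction, interval and uncovered
#'   feature list-columns.
#' @export
map_plasmid_integration <- function(plasmid, genomes, min_identity = 0.95,
                                    min_block = 500L, merge_gap = 200L,
                                    indexes = NULL) {
  n <- nchar(plasmid$sequence)
  if (is.null(indexes)) indexes <- genome_indexes(genomes)
  purrr::map_dfr(genomes, function(g) {
    hits <- purrr::map_dfr(g$replicons, function(r) {
      h <- local_search(plasmid$sequence, indexes[[paste(g$strain, r$replicon_id)]],
                       min_length = min_block, min_identity = min_identity)
      if (nrow(h)) mutate(h, replicon_id = r$replicon_id) else NULL
    })
    if (!nrow(hits)) {
      return(tibble(genome = g$strain, coverage_fraction = 0, n_fragments = 0L,
                    intervals = list(tibble(q_start = integer(), q_end = integer())),
                    uncovered_features = list(plasmid$features |>
                                                select("locus_tag", "product"))))
    }
    merged <- merge_blocks(hits, max_gap = merge_gap) |>
      select("q_start", "q_end", "n_blocks", "identity")
    covered <- sum(merged$q_end - merged$q_start + 1L)
    uncov <- plasmid$features |>
      filter(!purrr::map_lgl(seq_len(nrow(plasmid$features)), function(i) {
        any(merged$q_start <= plasmid$features$start[i] &
              merged$q_end >= plasmid$features$end[i])
      })) |>
      select("locus_tag", "product")
    tibble(genome = g$strain, coverage_fraction = covered / n,
           n_fragments = nrow(merged), intervals = list(merged),
           uncovered_features = list(uncov))
  })
}

#' Write HGT reports as TSV
#' @param regions tibble from [cross_species_regions()].
#' @param path output file.
#' @export
write_hgt_report <- function(regions, path) {
  flat <- regions |>
    mutate(gene_list = purrr::map_chr(.data$genes, ~ paste(.x$locus_tag, collapse = ",")),
           categories = purrr::map_chr(.data$genes, ~ paste(unique(.x$category), collapse = ","))) |>
    select(-"genes")
  readr::write_tsv(flat, path)
  invisible(path)
}
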