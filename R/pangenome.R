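# Ortholog clustering and pan/core-genome statistics.

#' Greedy centroid clustering of predicted proteins
#'
#' Proteins are sorted by length (descending, ties by locus tag then genome)
#' and processed greedily: each protein joins the first existing centroid it
#' matches at `min_identity` identity and `min_coverage` coverage of the
#' longer sequence, otherwise it founds a new cluster. The fixed processing
#' order makes the partition deterministic and independent of input file
#' order.
#'
#' @param genomes list of [genome()] objects (annotated, with translations).
#' @param min_identity minimum fraction of identical alignment columns.
#' @param min_coverage minimum aligned fraction of the longer protein.
#' @return tibble (cluster_id, genome, locus_tag, is_centroid, length).
#' @export
cluster_proteins <- function(genomes, min_identity = 0.60, min_coverage = 0.75) {
  prot <- proteins(genomes)
  if (!nrow(prot)) abort("no translated CDS found")
  prot <- arrange(prot, desc(.data$length), .data$locus_tag, .data$genome)
  greedy_cluster(prot, min_identity, min_coverage)
}

# greedy assignment against accumulated centroids, chunked for speed
greedy_cluster <- function(prot, min_identity, min_coverage, chunk = 64L) {
  n <- nrow(prot)
  cent_seq <- character(); cent_len <- integer(); cent_id <- character()
  assign_id <- character(n)
  is_centroid <- logical(n)
  for (i in seq_len(n)) {
    tr <- prot$translation[i]; len <- prot$length[i]
    hit <- NA_integer_
    if (length(cent_seq)) {
      # provably safe length prefilter: identity > min_identity over
      # >= min_coverage of the longer sequence forces
      # shorter/longer > min_identity * min_coverage
      ratio <- pmin(len, cent_len) / pmax(len, cent_len)
      elig <- which(ratio >= min_identity * min_coverage)
      for (start in seq(1L, length(elig), by = chunk)) {
        block <- elig[start:min(start + chunk - 1L, length(elig))]
        res <- aa_identity_coverage_many(tr, cent_seq[block])
        ok <- which(res$identity >= min_identity & res$coverage >= min_coverage)
        if (length(ok)) { hit <- block[ok[1]]; break }
      }
    }
    if (is.na(hit)) {
      cent_seq <- c(cent_seq, tr)
      cent_len <- c(cent_len, len)
      cid <- sprintf("OC%05d", length(cent_seq))
      cent_id <- c(cent_id, cid)
      assign_id[i] <- cid
      is_centroid[i] <- TRUE
    } else {
      assign_id[i] <- cent_id[hit]
    }
  }
  prot |>
    mutate(cluster_id = assign_id, is_centroid = is_centroid) |>
    select("cluster_id", "genome", "locus_tag", "is_centroid", "length") |>
    arrange(.data$cluster_id, desc(.data$is_centroid), .data$genome)
}

#' Presence/absence matrix of clusters across genomes
#'
#' @param clusters tibble from [cluster_proteins()].
#' @param genomes list of [genome()] objects or character vector of names.
#' @return binary matrix, clusters in rows, genomes in columns; an entry is
#'   1 when the cluster has at least one member from the genome (paralogous
#'   duplicates still give 1).
#' @export
presence_matrix <- function(clusters, genomes) {
  gnames <- if (is.character(genomes)) genomes else vapply(genomes, `[[`, "", "strain")
  cids <- sort(unique(clusters$cluster_id))
  m <- matrix(0L, length(cids), length(gnames), dimnames = list(cids, gnames))
  idx <- distinct(clusters, .data$cluster_id, .data$genome)
  m[cbind(match(idx$cluster_id, cids), match(idx$genome, gnames))] <- 1L
  m
}

#' Gene accumulation (pan) and core curves over genome orderings
#'
#' For each ordering of the genomes, the cumulative union (pan) and
#' intersection (core) of gene clusters is computed at every step. All
#' orderings are enumerated when there are at most `exhaustive_max` of
#' them; otherwise `n_orderings` random orderings are drawn (reproducibly
#' from `seed`).
#'
#' @param matrix presence/absence matrix from [presence_matrix()].
#' @param n_orderings random orderings to draw.
#' @param seed RNG seed.
#' @param exhaustive_max enumerate exhaustively when n! does not exceed this.
#' @return long tibble (ordering, k, pan, core), one row per ordering and
#'   step.
#' @export
pan_core_curves <- function(matrix, n_orderings = 100L, seed = 1L,
                            exhaustive_max = 5000L) {
  if (n_orderings < 1L) abort("n_orderings must be >= 1")
  n <- ncol(matrix)
  orderings <- if (factorial(n) <= exhaustive_max) {
    all_permutations(n)
  } else {
    with_stream(seed, "ordering", replicate(n_orderings, sample.int(n), simplify = FALSE))
  }
  purrr::imap_dfr(orderings, function(ord, oi) {
    pan <- rep(FALSE, nrow(matrix)); core <- rep(TRUE, nrow(matrix))
    purrr::map_dfr(seq_along(ord), function(k) {
      col <- matrix[, ord[k]] > 0
      pan <<- pan | col
      core <<- core & col
      tibble(ordering = oi, k = k, pan = sum(pan), core = sum(core))
    })
  })
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}

#' Summarise pan/core curves per step
#' @param curves long tibble from [pan_core_curves()].
#' @export
summarise_curves <- function(curves) {
  curves |>
    group_by(.data$k) |>
    summarise(pan_mean = mean(.data$pan), pan_min = min(.data$pan), pan_max = max(.data$pan),
              core_mean = mean(.data$core), core_min = min(.data$core),
              core_max = max(.data$core), .groups = "drop")
}

#' k-genome spectrum
#'
#' @param matrix presence/absence matrix.
#' @return tibble (k, clusters): number of clusters present in exactly k
#'   genomes, for k = 1..n; the counts sum to the number of clusters.
#' @export
k_spectrum <- function(matrix) {
  n <- ncol(matrix)
  rs <- rowSums(matrix > 0)
  tibble(k = seq_len(n),
         clusters = vapply(seq_len(n), function(k) sum(rs == k), integer(1)))
}

#' Full pan-genome profile of a genome set
#'
#' Runs [cluster_proteins()], builds the presence matrix, accumulation
#' curves, k-spectrum and the ORFan set (clusters present in exactly one
#' genome).
#'
#' @inheritParams cluster_proteins
#' @inheritParams pan_core_curves
#' @return an object of class `pangenome_profile`.
#' @export
pangenome_profile <- function(genomes, min_identity = 0.60, min_coverage = 0.75,
                              n_orderings = 100L, seed = 1L) {
  clusters <- cluster_proteins(genomes, min_identity, min_coverage)
  m <- presence_matrix(clusters, genomes)
  spectrum <- k_spectrum(m)
  curves <- pan_core_curves(m, n_orderings = n_orderings, seed = seed)
  orfan_ids <- rownames(m)[rowSums(m > 0) == 1L]
  orfans <- filter(clusters, .data$cluster_id %in% orfan_ids)
  structure(list(clusters = clusters, matrix = m, curves = curves,
                 spectrum = spectrum, orfans = orfans),
            class = "pangenome_profile")
}

#' @export
print.pangenome_profile <- function(x, ...) {
  cat(sprintf("<pangenome_profile> %d genomes, %d clusters (core %d, ORFan clusters %d)\n",
              ncol(x$matrix), nrow(x$matrix),
              x$spectrum$clusters[nrow(x$spectrum)],
              x$spectrum$clusters[1]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pangenome_profile <- function(x, ...) {
  summarise_curves(x$curves)
}

#' @export
glance.pangenome_profile <- function(x, ...) {
  tibble(n_genomes = ncol(x$matrix),
         pan_size = nrow(x$matrix),
         core_size = x$spectrum$clusters[nrow(x$spectrum)],
         orfan_clusters = x$spectrum$clusters[1],
         orfan_genes = nrow(x$orfans))
}

#' Positional density of ORFans along normalized chromosomes
#'
#' Counts ORFan gene starts in non-overlapping windows tiling each
#' chromosome; genomes must be origin-normalized first so positions are
#' comparable across strains.
#'
#' @param profile a [pangenome_profile()].
#' @param genomes the same genomes, normalized via [normalize_to_ori()].
#' @param window tile width, bp.
#' @return tibble (genome, window_start, window_end, n_orfans).
#' @export
orfan_positions <- function(profile, genomes, window = 100000L) {
  feats <- genes(genomes) |> filter(.data$kind == "CDS")
  orf <- profile$orfans
  missing <- anti_join(orf, feats, by = c("genome", "locus_tag"))
  if (nrow(missing)) {
    abort(paste0("ORFan loci not found in genomes: ",
                 paste(utils::head(paste(missing$genome, missing$locus_tag), 5), collapse = ", ")))
  }
  pos <- inner_join(orf, feats, by = c("genome", "locus_tag"))
  purrr::map_dfr(genomes, function(g) {
    n <- nchar(chromosome(g)$sequence)
    starts <- seq(1L, n, by = window)
    p <- filter(pos, .data$genome == g$strain)
    tibble(genome = g$strain, window_start = starts,
           window_end = pmin(starts + window - 1L, n)) |>
      mutate(n_orfans = vapply(seq_along(starts), function(i) {
        sum(p$start >= starts[i] & p$start <= pmin(starts[i] + window - 1L, n))
      }, integer(1)))
  })
}

#' Write pan-genome outputs as TSV
#' @param profile a [pangenome_profile()].
#' @param dir output directory.
#' @export
write_pangenome <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(profile$clusters, file.path(dir, "clusters.tsv"))
  readr::write_tsv(as_tibble(profile$matrix, rownames = "cluster_id"),
                   file.path(dir, "presence_matrix.tsv"))
  readr::write_tsv(summarise_curves(profile$curves), file.path(dir, "pan_core_curves.tsv"))
  readr::write_tsv(profile$spectrum, file.path(dir, "k_spectrum.tsv"))
  invisible(dir)
}
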