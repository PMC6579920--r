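# Genomic islands as candidate integrative and conjugative elements (ICEs):
# direct-repeat boundary refinement, signature-gene screen, and in-silico
# excision testing by PCR on the three molecular forms.

#' Refine island boundaries to flanking direct repeats
#'
#' Starting from a rough seed interval (from HGT detection or the user),
#' searches for direct-repeat (att-like) pairs around both boundaries and
#' sets the island to the chosen pair; preference is for the longest repeat
#' and, among equals, the outermost pair. Remaining pairs are kept as
#' alternates. Without any pair of at least `repeat_length`, the island is
#' returned unbounded with a warning flag.
#'
#' @param genome a [genome()].
#' @param seed_interval c(start, end) rough island interval on the
#'   chromosome.
#' @param repeat_length minimum repeat (att) length, bp.
#' @param window boundary search window, bp.
#' @param max_mismatch mismatches tolerated within the repeat arms.
#' @param island_range accepted island length range, bp.
#' @return object of class `ice_island`.
#' @export
find_island_boundaries <- function(genome, seed_interval, repeat_length = 12L,
                                   window = 500L, max_mismatch = 0L,
                                   island_range = c(20000L, 150000L)) {
  chrom <- chromosome(genome)
  reps <- find_direct_repeats(chrom$sequence, seed_interval,
                              repeat_length = repeat_length,
                              max_mismatch = max_mismatch, window = window)
  bounded <- nrow(reps) > 0L
  if (bounded) {
    best <- reps |>
      filter(.data$repeat_length == max(.data$repeat_length)) |>
      arrange(desc(.data$right_end - .data$left_start)) |>
      slice(1)
    interval <- c(best$left_start, best$right_end)
    att <- substr(chrom$sequence, best$left_start, best$left_end)
    alternates <- anti_join(reps, best, by = c("left_start", "right_end"))
  } else {
    interval <- as.integer(seed_interval)
    att <- ""
    alternates <- reps
  }
  len <- interval[2] - interval[1] + 1L
  structure(list(genome = genome$strain, replicon_id = chrom$replicon_id,
                 interval = interval, att_repeat = att, bounded = bounded,
                 in_range = len >= island_range[1] && len <= island_range[2],
                 alternates = alternates, signature_hits = NULL,
                 excision_prediction = NULL),
            class = "ice_island")
}

#' @export
print.ice_island <- function(x, ...) {
  cat(sprintf("<ice_island> %s:%s %d..%d (%d bp)%s att='%s'\n", x$genome,
              x$replicon_id, x$interval[1], x$interval[2],
              x$interval[2] - x$interval[1] + 1L,
              if (x$bounded) "" else " [unbounded]", x$att_repeat))
  invisible(x)
}

.ice_env <- new.env(parent = emptyenv())

#' ICE signature-gene keyword table
#' @param path optional alternative table (class, pattern TSV).
#' @export
ice_keyword_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ice_env$table)) return(.ice_env$table)
    path <- system.file("extdata", "ice_signature_keywords.tsv", package = "mobilomeR")
  }
  tb <- readr::read_tsv(path, col_types = "cc", comment = "#")
  if (is.null(.ice_env$table)) .ice_env$table <- tb
  tb
}

#' Screen island genes for ICE signature functions
#'
#' Assigns island genes, by case-insensitive keyword, to the three ICE core
#' function classes: integration/excision, replication as an
#' extrachromosomal element, and conjugation.
#'
#' @param island an `ice_island`.
#' @param genome the genome it belongs to.
#' @param table keyword table, see [ice_keyword_table()].
#' @return the island with `signature_hits` set (tibble class, locus_tag,
#'   product).
#' @export
screen_signature_genes <- function(island, genome, table = ice_keyword_table()) {
  chrom <- chromosome(genome)
  f <- chrom$features |>
    filter(.data$kind == "CDS", .data$start >= island$interval[1],
           .data$end <= island$interval[2])
  lp <- tolower(f$product %||% "")
  cls <- rep(NA_character_, nrow(f))
  for (i in seq_len(nrow(table))) {
    hit <- is.na(cls) & grepl(table$pattern[i], lp, fixed = TRUE)
    cls[hit] <- table$class[i]
  }
  island$signature_hits <- tibble(class = cls, locus_tag = f$locus_tag,
                                  product = f$product) |>
    filter(!is.na(.data$class)) |>
    arrange(.data$class)
  island
}

#' Construct the three molecular forms of an excisable island
#'
#' The excised circle is the att-bounded island segment taken intact and
#' circularized (its junction carries the boundary repeat); the re-sealed
#' chromosome joins the flanks across a single att copy. Consequently
#' circle length + re-sealed length = chromosome length + att length.
#'
#' @param genome a [genome()].
#' @param island a bounded `ice_island`.
#' @return list of replicons: integrated, excised_circle, resealed.
#' @export
excise_island <- function(genome, island) {
  if (!island$bounded) abort("island is not bounded by direct repeats")
  chrom <- chromosome(genome)
  n <- nchar(chrom$sequence)
  L <- island$interval[1]; R <- island$interval[2]
  a <- nchar(island$att_repeat)
  circle_seq <- substr(chrom$sequence, L, R)
  resealed_seq <- paste0(substr(chrom$sequence, 1L, L - 1L), island$att_repeat,
                         substr(chrom$sequence, R + 1L, n))
  list(
    integrated = chrom,
    excised_circle = replicon(paste0(chrom$replicon_id, "_circle"), circle_seq,
                              topology = "circular"),
    resealed = replicon(paste0(chrom$replicon_id, "_resealed"), resealed_seq,
                        topology = chrom$topology)
  )
}

#' Read a primer list (name TAB sequence)
#' @param path TSV file with columns name, sequence.
#' @export
read_primers <- function(path) {
  readr::read_tsv(path, col_types = "cc", comment = "#")
}

#' Predict excision-diagnostic PCR products
#'
#' Runs [in_silico_pcr()] with every primer pair on the three molecular
#' forms of the island — integrated chromosome, excised circular island and
#' re-sealed chromosome — and reports which pairs amplify on which form.
#' An outward-pointing pair straddling the island boundaries yields a
#' product only on the excised circle, the in-silico analogue of the
#' excision test.
#'
#' @param genome a [genome()].
#' @param island a bounded `ice_island`.
#' @param primers tibble (name, sequence).
#' @param max_product maximum product length, bp.
#' @param max_mismatch non-3' mismatches tolerated per site.
#' @return the island with `excision_prediction` set: tibble (primer_a,
#'   primer_b, form, product, product_length).
#' @export
predict_excision_pcr <- function(genome, island, primers, max_product = 5000L,
                                 max_mismatch = 2L) {
  forms <- excise_island(genome, island)
  names(forms) <- c("integrated", "excised_circle", "resealed")
  pairs <- utils::combn(seq_len(nrow(primers)), 2L, simplify = FALSE)
  pred <- purrr::map_dfr(pairs, function(pr) {
    purrr::imap_dfr(forms, function(tmpl, form) {
      prod <- in_silico_pcr(tmpl, primers$sequence[pr[1]], primers$sequence[pr[2]],
                            max_product = max_product, max_mismatch = max_mismatch)
      tibble(primer_a = primers$name[pr[1]], primer_b = primers$name[pr[2]],
             form = form, product = nrow(prod) > 0L,
             product_length = if (nrow(prod)) min(prod$product_length) else NA_integer_)
    })
  })
  island$excision_prediction <- pred
  island
}

#' @export
tidy.ice_island <- function(x, ...) {
  if (is.null(x$excision_prediction)) {
    abort("run predict_excision_pcr() first")
  }
  tidyr::pivot_wider(x$excision_prediction,
                     id_cols = c("primer_a", "primer_b"),
                     names_from = "form", values_from = "product")
}

#' @export
glance.ice_island <- function(x, ...) {
  sig <- x$signature_hits
  tibble(genome = x$genome, start = x$interval[1], end = x$interval[2],
         length = x$interval[2] - x$interval[1] + 1L,
         bounded = x$bounded, att_repeat = x$att_repeat,
         n_integration_excision = if (is.null(sig)) NA_integer_ else sum(sig$class == "integration_excision"),
         n_replication = if (is.null(sig)) NA_integer_ else sum(sig$class == "replication"),
         n_conjugation = if (is.null(sig)) NA_integer_ else sum(sig$class == "conjugation"))
}
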