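# End-to-end orchestration with a single configuration object.
#
# The package is function-first: run_pipeline() is the programmatic entry
# point, and a YAML file with the same keys can stand in for the config
# list. Every stage threshold is a named key defaulting to the study
# values (cluster_identity 0.60, cluster_coverage 0.75, hgt_min_length
# 2000, hgt_min_identity 0.90, is_flank 1000, att_repeat_length 12).

#' Default pipeline configuration
#' @export
pipeline_defaults <- function() {
  list(
    stages = c("pangenome", "is_scan", "hgt_scan", "ice_scan"),
    cluster_identity = 0.60, cluster_coverage = 0.75,
    n_orderings = 100L,
    is_flank = 1000L, is_min_copies = 2L, is_min_identity = 0.90,
    is_min_span = 0.80, composite_max_cargo = 20000L,
    hgt_min_length = 2000L, hgt_min_identity = 0.90, hgt_merge_gap = 1000L,
    plasmid_min_identity = 0.95, plasmid_min_block = 500L,
    att_repeat_length = 12L, att_window = 500L, island_range = c(20000L, 150000L),
    pcr_max_product = 5000L,
    seed = 1L, out_dir = NULL
  )
}

#' Run the analysis pipeline on a genome set
#'
#' Executes the toggled stages in order — pan-genome clustering, IS scan
#' (discovery, census, disruptions, composite transposons), HGT scan
#' (cross-species regions, plasmid integration) and ICE scan (island
#' boundaries, signature screen, excision PCR) — and returns a
#' machine-readable summary. When `config$out_dir` is set, TSV/FASTA/GFF3
#' artifacts are written there.
#'
#' @param genomes list of [genome()] (recipients).
#' @param partners list of cross-species [genome()] for the HGT stage.
#' @param plasmid optional [replicon()] for integration mapping.
#' @param island_seed optional c(start, end) seed interval for the ICE scan
#'   on the first genome carrying one; when NULL the largest HGT region is
#'   used.
#' @param primers optional tibble (name, sequence) for excision PCR.
#' @param config list of options, see [pipeline_defaults()]; a path to a
#'   YAML file is also accepted.
#' @return list of stage results plus a `summary` tibble-friendly list.
#' @export
run_pipeline <- function(genomes, partners = list(), plasmid = NULL,
                         island_seed = NULL, primers = NULL,
                         config = pipeline_defaults()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (!length(genomes)) abort("at least one genome is required")
  res <- list(config = cfg)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if ("pangenome" %in% cfg$stages) {
    res$pangenome <- pangenome_profile(genomes, min_identity = cfg$cluster_identity,
                                       min_coverage = cfg$cluster_coverage,
                                       n_orderings = cfg$n_orderings, seed = cfg$seed)
    if (!is.null(out)) write_pangenome(res$pangenome, file.path(out, "pangenome"))
  }

  indexes <- NULL
  if (any(c("is_scan", "hgt_scan") %in% cfg$stages)) {
    indexes <- genome_indexes(c(genomes, partners))
  }
  if ("is_scan" %in% cfg$stages) {
    lib <- discover_is_elements(genomes, flank = cfg$is_flank,
                                min_copies = cfg$is_min_copies,
                                min_identity = cfg$is_min_identity,
                                min_span = cfg$is_min_span)
    copies <- if (length(lib)) is_copies(lib, genomes, cfg$is_min_identity,
                                         cfg$is_min_span, indexes = indexes)
              else empty_copies()
    res$is_scan <- list(
      library = lib, copies = copies,
      census = if (length(lib)) is_census(lib, genomes, cfg$is_min_identity,
                                          cfg$is_min_span, indexes = indexes)
               else tibble(),
      disruptions = detect_gene_disruption(copies, genomes),
      composites = detect_composite_transposons(copies, genomes, lib,
                                                max_cargo = cfg$composite_max_cargo)
    )
    if (!is.null(out) && length(lib)) {
      write_is_library(lib, file.path(out, "is_library"))
      readr::write_tsv(res$is_scan$census, file.path(out, "is_census.tsv"))
      readr::write_tsv(res$is_scan$disruptions, file.path(out, "is_disruptions.tsv"))
    }
  }

  if ("hgt_scan" %in% cfg$stages && length(partners)) {
    rec_idx <- genome_indexes(genomes)
    res$hgt_scan <- purrr::map_dfr(genomes, function(g) {
      cross_species_regions(g, partners, min_length = cfg$hgt_min_length,
                            min_identity = cfg$hgt_min_identity,
                            merge_gap = cfg$hgt_merge_gap, indexes = rec_idx)
    })
    res$hgt_categories <- classify_hgt_regions(res$hgt_scan)
    if (!is.null(plasmid)) {
      res$plasmid_map <- map_plasmid_integration(plasmid, genomes,
                                                 min_identity = cfg$plasmid_min_identity,
                                                 min_block = cfg$plasmid_min_block,
                                                 indexes = rec_idx)
    }
    if (!is.null(out)) {
      write_hgt_report(res$hgt_scan, file.path(out, "hgt_regions.tsv"))
    }
  }

  if ("ice_scan" %in% cfg$stages) {
    seedint <- island_seed
    target <- genomes[[1]]
    if (is.null(seedint) && !is.null(res$hgt_scan) && nrow(res$hgt_scan)) {
      top <- res$hgt_scan |> arrange(desc(.data$length)) |> slice(1)
      target <- purrr::detect(genomes, ~ .x$strain == top$recipient)
      seedint <- c(top$start, top$end)
    }
    if (!is.null(seedint)) {
      isl <- find_island_boundaries(target, seedint,
                                    repeat_length = cfg$att_repeat_length,
                                    window = cfg$att_window,
                                    island_range = cfg$island_range)
      isl <- screen_signature_genes(isl, target)
      if (!is.null(primers) && isl$bounded) {
        isl <- predict_excision_pcr(target, isl, primers,
                                    max_product = cfg$pcr_max_product)
      }
      res$ice_scan <- isl
    }
  }

  res$summary <- pipeline_summary(res)
  if (!is.null(out)) {
    jsonlite::write_json(res$summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

pipeline_summary <- function(res) {
  s <- list()
  if (!is.null(res$pangenome)) {
    gl <- glance(res$pangenome)
    s$pan_size <- gl$pan_size
    s$core_size <- gl$core_size
    s$orfan_clusters <- gl$orfan_clusters
    s$k_spectrum <- setNames(res$pangenome$spectrum$clusters,
                             res$pangenome$spectrum$k)
  }
  if (!is.null(res$is_scan)) {
    s$n_is_elements <- length(res$is_scan$library)
    s$n_is_copies <- sum(res$is_scan$copies$full)
    s$n_disruptions <- nrow(res$is_scan$disruptions)
    s$n_composites <- nrow(res$is_scan$composites)
  }
  if (!is.null(res$hgt_scan)) {
    s$n_hgt_regions <- nrow(res$hgt_scan)
    s$largest_hgt_region <- if (nrow(res$hgt_scan)) max(res$hgt_scan$length) else 0L
    s$hgt_genes <- sum(res$hgt_scan$n_genes)
  }
  if (!is.null(res$plasmid_map)) {
    s$max_plasmid_coverage <- max(res$plasmid_map$coverage_fraction)
  }
  if (!is.null(res$ice_scan)) {
    s$ice_bounded <- res$ice_scan$bounded
    s$ice_length <- diff(res$ice_scan$interval) + 1L
    s$ice_att <- res$ice_scan$att_repeat
  }
  s
}
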