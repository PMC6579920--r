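# Shared fixtures: random sequences, toy genomes, and a cached small
# simulation suite reused across test files.

rnd_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

rnd_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
}

# substitute exactly k positions of a string, each to a different symbol
substitute_positions <- function(x, k, alphabet) {
  chars <- strsplit(x, "")[[1]]
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(old) {
    sample(setdiff(alphabet, old), 1L)
  }, "")
  paste(chars, collapse = "")
}

sub_dna <- function(x, k) substitute_positions(x, k, c("A", "C", "G", "T"))
sub_protein <- function(x, k) {
  substitute_positions(x, k, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
}

# toy genome: CDS at given starts with given translations/products
toy_genome <- function(strain, seqs_len = 10000, cds = NULL, topology = "circular",
                       species = "Toyum examplense", seq = NULL) {
  s <- seq %||% rnd_dna(seqs_len)
  feats <- if (is.null(cds)) feature_table() else do.call(feature_table, cds)
  genome(strain, species, list(replicon(paste0(strain, "_chr"), s, topology, feats)))
}

# a protein-only genome: each protein becomes a CDS with a dummy ORF of
# matching length so container invariants hold
protein_genome <- function(strain, translations, products = NULL) {
  nt <- (nchar(translations) + 1L) * 3L
  starts <- cumsum(c(200L, utils::head(nt, -1) + 150L))
  n <- max(starts + nt - 1L) + 200L
  feats <- feature_table(
    locus_tag = sprintf("%s_%03d", strain, seq_along(translations)),
    kind = "CDS", start = starts, end = starts + nt - 1L, strand = "+",
    product = products %||% rep("hypothetical protein", length(translations)),
    translation = translations
  )
  genome(strain, "Toyum examplense",
         list(replicon(paste0(strain, "_chr"), rnd_dna(n), "circular", feats)))
}

# small simulation suite shared by the integration tests (one build per run)
.test_cache <- new.env(parent = emptyenv())

test_sim_config <- function(seed = 11L) {
  simulation_config(
    n_genomes = 3L, chromosome_length = 120000L, core_genes = 40L,
    shell_genes = 10L, orfans_per_genome = 5L,
    is_library_spec = list(
      list(name = "ISsynA", length = 1350L, ir_length = 16L,
           copies_per_genome = c(2L, 3L), in_gene_fraction = 0.3,
           product = "IS3 family transposase"),
      list(name = "ISsynB", length = 1200L, ir_length = 24L,
           copies_per_genome = c(2L, 2L), in_gene_fraction = 0,
           product = "ISL3 family transposase")),
    hgt_spec = list(list(length = 5000L, identity = 0.97, genome_index = 1L),
                    list(length = 3000L, identity = 0.92, genome_index = 2L)),
    ice_spec = list(genome_index = 1L, length = 22000L, att = "AGAAGTCCCAGT",
                    roster = c("integrase", "site-specific integrase",
                               "excisionase", "replicative DNA helicase",
                               "DNA primase", "DNA polymerase III subunit alpha",
                               "conjugal transfer protein",
                               "chromosome partitioning protein ParB",
                               "conjugal transfer protein TrbL",
                               "type VI secretion protein",
                               "single-stranded DNA-binding protein"),
                    filler_genes = 4L),
    plasmid_spec = list(length = 7600L, fragment_lengths = c(3040L, 2280L, 760L),
                        identity = 0.99, genome_index = 1L),
    seed = seed)
}

get_test_sim <- function() {
  if (is.null(.test_cache$sim)) .test_cache$sim <- simulate_genome_set(test_sim_config())
  .test_cache$sim
}

get_test_indexes <- function() {
  if (is.null(.test_cache$idx)) .test_cache$idx <- genome_indexes(get_test_sim()$genomes)
  .test_cache$idx
}

get_test_is <- function() {
  if (is.null(.test_cache$is)) {
    sim <- get_test_sim()
    lib <- discover_is_elements(sim$genomes)
    copies <- is_copies(lib, sim$genomes, indexes = get_test_indexes())
    .test_cache$is <- list(lib = lib, copies = copies)
  }
  .test_cache$is
}

get_full_sim <- function() {
  if (is.null(.test_cache$full)) {
    .test_cache$full <- simulate_genome_set(simulation_config())
  }
  .test_cache$full
}

get_test_profile <- function() {
  if (is.null(.test_cache$profile)) {
    .test_cache$profile <- suppressWarnings(
      pangenome_profile(get_test_sim()$genomes, seed = 1L))
  }
  .test_cache$profile
}
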