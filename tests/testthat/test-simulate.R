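hamming_chr <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

tiny_config <- function(seed = 5L) {
  simulation_config(
    n_genomes = 2L, chromosome_length = 90000L, core_genes = 25L,
    shell_genes = 4L, orfans_per_genome = 4L,
    is_library_spec = list(
      list(name = "ISsynA", length = 1350L, ir_length = 16L,
           copies_per_genome = c(2L, 2L), in_gene_fraction = 0.5,
           product = "IS3 family transposase"),
      list(name = "ISsynB", length = 1200L, ir_length = 24L,
           copies_per_genome = c(1L, 1L), in_gene_fraction = 0,
           product = "ISL3 family transposase")),
    hgt_spec = list(list(length = 4000L, identity = 0.95, genome_index = 1L)),
    ice_spec = list(genome_index = 1L, length = 21000L, att = "AGAAGTCCCAGT",
                    roster = c("integrase", "excisionase",
                               "replicative DNA helicase",
                               "conjugal transfer protein TrbL"),
                    filler_genes = 3L),
    plasmid_spec = list(length = 7600L, fragment_lengths = c(2500L, 1500L),
                        identity = 0.99, genome_index = 1L),
    seed = seed)
}

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- tiny_config()
  s1 <- simulate_genome_set(cfg)
  s2 <- simulate_genome_set(cfg)
  for (i in seq_along(s1$genomes)) {
    expect_identical(chromosome(s1$genomes[[i]])$sequence,
                     chromosome(s2$genomes[[i]])$sequence)
    expect_identical(chromosome(s1$genomes[[i]])$features,
                     chromosome(s2$genomes[[i]])$features)
  }
  expect_identical(s1$ledger$is_copies, s2$ledger$is_copies)
  expect_identical(s1$ledger$hgt_blocks, s2$ledger$hgt_blocks)
  expect_identical(s1$primers, s2$primers)
  # written files are byte-identical too
  p1 <- withr::local_tempfile(fileext = ".gbk")
  p2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(s1$genomes[[1]], p1)
  write_genbank(s2$genomes[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed reshuffles the sequence
  s3 <- simulate_genome_set(tiny_config(seed = 6L))
  expect_false(identical(chromosome(s1$genomes[[1]])$sequence,
                         chromosome(s3$genomes[[1]])$sequence))
})

test_that("ledger bookkeeping is internally consistent", {
  sim <- get_test_sim()
  led <- sim$ledger
  expect_equal(sum(led$expected_spectrum$clusters), led$expected_pan)
  expect_equal(led$expected_spectrum$clusters[nrow(led$expected_spectrum)],
               led$expected_core)
  expect_equal(led$expected_spectrum$clusters[1], led$expected_orfans)
  # census totals match the planted copy list
  expect_equal(sum(led$expected_census$copies), nrow(led$is_copies))
  # every planted interval lies within its genome
  for (nm in c("is_copies", "hgt_blocks", "plasmid_fragments", "ice")) {
    tbl <- led[[nm]]
    for (i in seq_len(nrow(tbl))) {
      g <- purrr::detect(sim$genomes, ~ .x$strain == tbl$genome[i])
      expect_gte(tbl$start[i], 1L)
      expect_lte(tbl$end[i], nchar(chromosome(g)$sequence))
    }
  }
  # planted intervals carry their sequences: IS copies match their element
  el <- led$is_elements
  for (i in seq_len(min(5L, nrow(led$is_copies)))) {
    cp <- led$is_copies[i, ]
    g <- purrr::detect(sim$genomes, ~ .x$strain == cp$genome)
    s <- substr(chromosome(g)$sequence, cp$start, cp$end)
    if (cp$strand == "-") s <- revcomp(s)
    expect_equal(s, el$sequence[el$name == cp$element])
  }
})

test_that("planted HGT blocks hit their target identity within half a percent", {
  sim <- get_test_sim()
  led <- sim$ledger
  donor <- chromosome(sim$partners[[1]])
  for (i in seq_len(nrow(led$hgt_blocks))) {
    b <- led$hgt_blocks[i, ]
    g <- purrr::detect(sim$genomes, ~ .x$strain == b$genome)
    planted <- substr(chromosome(g)$sequence, b$start, b$end)
    original <- substr(donor$sequence, b$donor_start, b$donor_end)
    ident <- 1 - hamming_chr(planted, original) / nchar(planted)
    expect_lte(abs(ident - b$identity_target), 0.005)
    expect_equal(ident, b$identity_measured)
  }
  # identity 1.0 means a byte-identical block
  g1 <- toy_genome("R1", seq = rnd_dna(30000),
                   cds = list(locus_tag = "R1_1", kind = "CDS", start = 101L,
                              end = 400L, strand = "+", product = "membrane protein",
                              translation = NA_character_, wraps = FALSE))
  d1 <- toy_genome("D1", seq = rnd_dna(30000), species = "Donans alia")
  res <- plant_hgt_block(g1, d1, length = 2000L, identity = 1.0, seed = 3L)
  b <- res$block
  expect_identical(substr(chromosome(res$recipient)$sequence, b$start, b$end),
                   substr(chromosome(d1)$sequence, b$donor_start, b$donor_end))
})

test_that("generated GenBank files re-parse without validation errors", {
  sim <- get_test_sim()
  for (g in c(sim$genomes[1], sim$partners[1])) {
    path <- withr::local_tempfile(fileext = ".gbk")
    write_genbank(g, path)
    g2 <- read_genbank(path, strain = g$strain, species_label = g$species_label)
    expect_equal(length(g2$replicons), length(g$replicons))
    for (rid in names(g$replicons)) {
      expect_equal(g2$replicons[[rid]]$sequence, g$replicons[[rid]]$sequence)
      f1 <- g$replicons[[rid]]$features
      f2 <- g2$replicons[[rid]]$features
      expect_equal(nrow(f2), nrow(f1))
      expect_equal(f2$start, f1$start)
      expect_equal(f2$end, f1$end)
      expect_equal(f2$translation, f1$translation)
    }
  }
})

test_that("the truth ledger round-trips through JSON", {
  sim <- get_test_sim()
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_ledger(sim$ledger, path)
  led2 <- read_truth_ledger(path)
  expect_equal(led2$expected_pan, sim$ledger$expected_pan)
  expect_equal(led2$expected_orfans, sim$ledger$expected_orfans)
  cmp_df <- function(a, b) {
    a <- as.data.frame(a)[, sort(names(as.data.frame(b)))]
    b <- as.data.frame(b)[, sort(names(as.data.frame(b)))]
    expect_equal(a, b)
  }
  cmp_df(led2$is_copies, sim$ledger$is_copies)
  cmp_df(led2$hgt_blocks, sim$ledger$hgt_blocks)
  expect_equal(as.data.frame(led2$expected_spectrum),
               as.data.frame(sim$ledger$expected_spectrum))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(within_cluster_divergence = 0.5), "0.2")
  expect_error(simulation_config(hgt_spec = list(list(length = 1000, identity = 0.5,
                                                      genome_index = 1))),
               "identity")
  expect_error(simulation_config(plasmid_spec = list(length = 1000,
                                                     fragment_lengths = c(900, 900),
                                                     identity = 0.99,
                                                     genome_index = 1)),
               "exceed")
  # gene content that cannot fit in the chromosome budget
  expect_error(suppressWarnings(simulate_genome_set(
    simulation_config(n_genomes = 1L, chromosome_length = 9000L,
                      core_genes = 30L, shell_genes = 0L,
                      orfans_per_genome = 0L))),
    "packing")
})

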