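test_that("GenBank records parse with 1-based inclusive coordinates", {
  gb <- c(
    "LOCUS       TOY01            1000 bp    DNA     circular BCT",
    "DEFINITION  Toyum examplense TOY.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             101..208",
    "                     /locus_tag=\"TOY_0001\"",
    "                     /product=\"hypothetical protein\"",
    "                     /translation=\"MKLVNNNNNNNNNNNNNNNNNNNNNNNNNNNNNGW\"",
    "     CDS             complement(301..420)",
    "                     /locus_tag=\"TOY_0002\"",
    "                     /product=\"iron ABC transporter",
    "                     permease\"",
    "ORIGIN",
    paste0("        1 ", tolower(rnd_dna(60))),
    "//")
  # pad out to 1000 bp of sequence lines
  set.seed(1)
  seqs <- tolower(rnd_dna(1000))
  seq_lines <- vapply(seq(1, 1000, 60), function(p) {
    chunk <- substr(seqs, p, min(p + 59, 1000))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", p, paste(tens, collapse = " "))
  }, "")
  gb <- c(gb[1:13], seq_lines, "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)

  g <- read_genome(path)
  chrom <- chromosome(g)
  expect_equal(nchar(chrom$sequence), 1000L)
  expect_equal(chrom$topology, "circular")
  f <- chrom$features
  expect_equal(nrow(f), 2L)
  expect_equal(f$start, c(101L, 301L))
  expect_equal(f$end, c(208L, 420L))
  expect_equal(f$strand, c("+", "-"))
  # multiline qualifier reassembled with a space
  expect_equal(f$product[2], "iron ABC transporter permease")
  expect_equal(nchar(f$translation[1]), 35L)
})

test_that("FASTA input yields a genome without features", {
  path <- withr::local_tempfile(fileext = ".fasta")
  set.seed(2)
  s <- rnd_dna(500)
  writeLines(c(">contig1 test", s), path)
  g <- read_genome(path, topology_hint = "linear")
  expect_equal(nrow(chromosome(g)$features), 0L)
  expect_equal(chromosome(g)$sequence, s)
  expect_equal(chromosome(g)$topology, "linear")
})

test_that("origin-spanning features are unwrapped with a wrap flag", {
  set.seed(3)
  g <- toy_genome("WRAP", seq = rnd_dna(1000), cds = list(
    locus_tag = "WRAP_0001", kind = "CDS", start = 901L, end = 1060L,
    strand = "+", product = "membrane protein", translation = NA_character_,
    wraps = TRUE))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  txt <- readLines(path)
  expect_true(any(grepl("join(901..1000,1..60)", txt, fixed = TRUE)))
  g2 <- read_genbank(path)
  f <- chromosome(g2)$features
  expect_equal(f$start, 901L)
  expect_equal(f$end, 1060L)
  expect_true(f$wraps)
})

test_that("GenBank round-trip preserves sequence, coordinates and products", {
  set.seed(4)
  tr <- rnd_protein(60)
  g <- toy_genome("RT01", seq = rnd_dna(2000), cds = list(
    locus_tag = c("RT_0001", "RT_0002", "RT_0003"),
    kind = c("CDS", "rRNA", "CDS"),
    start = c(100L, 500L, 1200L), end = c(100L + 183L - 1L, 650L, 1199L + 183L),
    strand = c("+", "+", "-"),
    product = c("DNA gyrase subunit A", "16S ribosomal RNA",
                "transcriptional regulator, TetR family"),
    translation = c(tr, NA, tr), wraps = FALSE))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  g2 <- read_genbank(path, strain = "RT01")
  expect_equal(chromosome(g2)$sequence, chromosome(g)$sequence)
  f1 <- chromosome(g)$features; f2 <- chromosome(g2)$features
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
  expect_equal(f2$strand, f1$strand)
  expect_equal(f2$product, f1$product)
  expect_equal(f2$translation, f1$translation)
})

test_that("ori normalization rotates to the intergenic region upstream of dnaA", {
  # 10-gene toy replicon, dnaA mid-chromosome on the + strand
  set.seed(5)
  n_genes <- 10L
  starts <- seq(201L, by = 500L, length.out = n_genes)
  ends <- starts + 299L
  products <- rep("membrane protein", n_genes)
  products[4] <- "chromosomal replication initiator protein DnaA"
  seqlen <- max(ends) + 0L  # last gene flush with the end
  g <- toy_genome("ORI", seq = rnd_dna(seqlen), cds = list(
    locus_tag = sprintf("ORI_%02d", 1:n_genes), kind = "CDS",
    start = starts, end = ends, strand = "+", product = products,
    translation = NA_character_, wraps = FALSE))
  gn <- normalize_to_ori(g)
  f <- chromosome(gn)$features
  dnaa <- f[grepl("DnaA", f$product), ]
  # upstream gene (gene 3) ended at old position 1500; origin = 1501
  expect_equal(dnaa$start, starts[4] - 1500L)
  # brute-force check: all pairwise circular distances preserved
  n <- nchar(chromosome(g)$sequence)
  old <- chromosome(g)$features$start
  new <- chromosome(gn)$features$start[match(chromosome(g)$features$locus_tag,
                                             chromosome(gn)$features$locus_tag)]
  for (i in 1:(n_genes - 1)) {
    expect_equal((new[i + 1] - new[i]) %% n, (old[i + 1] - old[i]) %% n)
  }
  # rotated sequence is a rotation of the original
  expect_equal(chromosome(gn)$sequence,
               paste0(substr(chromosome(g)$sequence, 1501, n),
                      substr(chromosome(g)$sequence, 1, 1500)))
})

test_that("ambiguous or missing dnaA raises an error listing candidates", {
  set.seed(6)
  two <- toy_genome("DUP", seq = rnd_dna(2000), cds = list(
    locus_tag = c("D_01", "D_02"), kind = "CDS",
    start = c(101L, 1001L), end = c(400L, 1300L), strand = "+",
    product = rep("chromosomal replication initiator protein DnaA", 2),
    translation = NA_character_, wraps = FALSE))
  expect_error(normalize_to_ori(two), "2")
  none <- toy_genome("NON", seq = rnd_dna(2000), cds = list(
    locus_tag = "N_01", kind = "CDS", start = 101L, end = 400L, strand = "+",
    product = "membrane protein", translation = NA_character_, wraps = FALSE))
  expect_error(normalize_to_ori(none), "0")
})

test_that("gc_content handles N exclusion and is strand-symmetric", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GGCCNNNN"), 100)  # N excluded from both sides
  expect_error(gc_content("NNNN"), "undefined")
  set.seed(7)
  for (i in 1:5) {
    s <- rnd_dna(200, gc = runif(1, 0.3, 0.7))
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("product classification follows the keyword table with fallbacks", {
  expect_equal(classify_product("iron ABC transporter permease"),
               "iron acquisition & metabolism")
  expect_equal(classify_product("IS3 family transposase"),
               "phage & mobile elements")
  expect_equal(classify_product("hypothetical protein"), "hypothetical")
  expect_equal(classify_product("putative secreted thing"), "putative")
  expect_equal(classify_product("completely novel annotation"), "miscellaneous")
  # vectorized and deterministic
  p <- c("ABC transporter ATP-binding protein", "DNA gyrase subunit A")
  expect_equal(classify_product(p),
               c("membrane transport", "DNA/RNA metabolism"))
})
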