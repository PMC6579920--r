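test_that("transposase anchors group by identical length; integrases tallied apart", {
  set.seed(51)
  tp <- rnd_protein(120)
  other <- rnd_protein(150)
  g <- protein_genome("AN", c(tp, tp, tp, other, rnd_protein(90)),
                      products = c(rep("IS3 family transposase", 3),
                                   "ISL3 family transposase", "integrase"))
  anchors <- find_transposase_anchors(g)
  expect_equal(nrow(anchors), 4L)  # integrase excluded
  expect_equal(sort(unique(anchors$group_size), decreasing = TRUE), c(3L, 1L))
  expect_true(all(anchors$multi_copy[anchors$group_size == 3]))
  counts <- mobile_element_counts(g)
  expect_equal(counts$transposases, 4L)
  expect_equal(counts$integrases, 1L)
  # keyword-free genome
  g0 <- protein_genome("NO", rnd_protein(100), products = "membrane protein")
  expect_equal(nrow(find_transposase_anchors(g0)), 0L)
})

test_that("candidate extraction adds flanks, wraps circles, truncates contig edges", {
  set.seed(52)
  g <- toy_genome("EX", seq = rnd_dna(10000), cds = list(
    locus_tag = c("EX_mid", "EX_edge"), kind = "CDS",
    start = c(5001L, 201L), end = c(6200L, 500L), strand = "+",
    product = "IS3 family transposase", translation = NA_character_,
    wraps = FALSE))
  a <- genes(g)
  mid <- extract_candidate(a[a$locus_tag == "EX_mid", ], g, flank = 1000)
  expect_equal(nchar(mid$sequence), 1200L + 2000L)
  expect_false(mid$truncated)
  # anchor 200 bp from the start of a circular chromosome: wrapped, full length
  edge <- extract_candidate(a[a$locus_tag == "EX_edge", ], g, flank = 1000)
  expect_equal(nchar(edge$sequence), 300L + 2000L)
  expect_equal(substr(edge$sequence, 1, 800),
               substr(chromosome(g)$sequence, 10000 - 799, 10000))
  # linear replicon: truncated with a flag
  gl <- toy_genome("LN", seq = chromosome(g)$sequence, topology = "linear",
                   cds = list(locus_tag = "LN_edge", kind = "CDS", start = 201L,
                              end = 500L, strand = "+",
                              product = "IS3 family transposase",
                              translation = NA_character_, wraps = FALSE))
  tr <- extract_candidate(genes(gl)[1, ], gl, flank = 1000)
  expect_true(tr$truncated)
  expect_equal(nchar(tr$sequence), 200L + 300L + 1000L)
})

test_that("multi-copy confirmation enforces copy number and identity thresholds", {
  set.seed(53)
  el <- rnd_dna(1200)
  single <- toy_genome("SG", seq = paste0(rnd_dna(4000), el, rnd_dna(4000)))
  # single locus: not an IS
  expect_equal(nrow(confirm_multicopy(el, list(single))), 0L)
  # two copies at ~85% identity fail a 0.90 threshold
  far <- sub_dna(el, 180)
  g85 <- toy_genome("DV", seq = paste0(rnd_dna(3000), el, rnd_dna(3000), far,
                                       rnd_dna(2000)))
  expect_equal(nrow(confirm_multicopy(el, list(g85), min_identity = 0.90)), 0L)
  # same pair confirmed when the threshold admits the divergence
  ok <- confirm_multicopy(el, list(g85), min_identity = 0.80)
  expect_gte(sum(ok$full), 2L)
})

test_that("element delimitation recovers planted boundaries and flags truncated copies", {
  sim <- get_test_sim()
  led <- sim$ledger
  lib <- get_test_is()$lib
  expect_equal(length(lib), nrow(led$is_elements))
  planted_len <- sort(led$is_elements$length)
  got_len <- sort(vapply(lib, function(el) nchar(el$element_sequence), integer(1)))
  expect_true(all(abs(got_len - planted_len) <= 5L))
  # recovered element sequences match a planted element (either strand)
  for (el in lib) {
    hit <- vapply(led$is_elements$sequence, function(p) {
      el$element_sequence == p || el$element_sequence == revcomp(p) ||
        grepl(el$element_sequence, p, fixed = TRUE) ||
        grepl(revcomp(el$element_sequence), p, fixed = TRUE) ||
        grepl(p, el$element_sequence, fixed = TRUE)
    }, logical(1))
    expect_true(any(hit))
    expect_gte(nchar(el$left_ir), 10L)
  }
  # a 5'-truncated copy is reported partial, boundaries follow intact copies
  set.seed(54)
  el <- paste0(rnd_dna(16), rnd_dna(1170), rnd_dna(14))
  half <- substr(el, 601, 1200)
  g <- toy_genome("TR", seq = paste0(rnd_dna(3000), el, rnd_dna(3000), el,
                                     rnd_dna(3000), half, rnd_dna(2000)))
  cand <- list(sequence = paste0(rnd_dna(1000), el, rnd_dna(1000)),
               genome = "TR", locus_tag = "TR_x", replicon_id = "TR_chr")
  copies <- confirm_multicopy(cand, list(g))
  expect_equal(sum(copies$full), 2L)   # the two intact genomic copies
  expect_equal(sum(!copies$full), 1L)  # the truncated one
  elem <- delimit_element(cand, copies, name = "IStrunc")
  expect_lte(abs(nchar(elem$element_sequence) - 1200L), 5L)
})

test_that("census equals the planted copy table and counts partials apart", {
  sim <- get_test_sim()
  led <- sim$ledger
  isres <- get_test_is()
  cen <- is_census(isres$lib, sim$genomes, indexes = get_test_indexes())
  # match discovered element names to planted ones by length
  lens <- vapply(isres$lib, function(el) nchar(el$element_sequence), integer(1))
  name_map <- setNames(led$is_elements$name[
    vapply(lens, function(l) which.min(abs(led$is_elements$length - l)), 1L)],
    names(isres$lib))
  got <- cen |>
    dplyr::mutate(element = unname(name_map[.data$element])) |>
    dplyr::arrange(.data$element, .data$genome)
  want <- led$expected_census |> dplyr::arrange(.data$element, .data$genome)
  expect_equal(got$element, want$element)
  expect_equal(got$genome, want$genome)
  expect_equal(got$copies, want$copies)
  expect_true(all(got$partial_copies == 0L))
  # row sums equal total confirmed loci
  expect_equal(sum(got$copies), nrow(led$is_copies))
})

test_that("gene disruptions are recovered with offsets; intergenic copies are silent", {
  sim <- get_test_sim()
  led <- sim$ledger
  isres <- get_test_is()
  dis <- detect_gene_disruption(isres$copies, sim$genomes)
  expect_equal(nrow(dis), nrow(led$disruptions))
  want <- led$disruptions |> dplyr::arrange(.data$genome, .data$host_locus)
  got <- dis |>
    dplyr::mutate(host = sub("_5p$", "", .data$locus_tag)) |>
    dplyr::arrange(.data$genome, .data$host)
  expect_equal(got$host, want$host_locus)
  expect_equal(got$genome, want$genome)
  expect_equal(got$insertion_offset, want$insertion_offset)
  # disruption calls are a subset of confirmed copies
  cp <- isres$copies[isres$copies$full, ]
  for (i in seq_len(nrow(dis))) {
    expect_true(any(cp$genome == dis$genome[i] & cp$s_start == dis$copy_start[i]))
  }
})

test_that("composite transposon detection recovers the planted cargo region", {
  sim <- get_test_sim()
  led <- sim$ledger
  isres <- get_test_is()
  comp <- detect_composite_transposons(isres$copies, sim$genomes, isres$lib)
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$genome, led$composite$genome)
  expect_lte(abs(comp$left_start - led$composite$start), 5L)
  expect_lte(abs(comp$right_end - led$composite$end), 5L)
  expect_equal(comp$n_cargo_genes, led$composite$n_cargo_genes)
  expect_equal(comp$transposase_identity, 1.0)
  # planted cargo products carried through
  expect_true(all(grepl("iron|siderophore|ferric|TonB",
                        comp$cargo_genes[[1]]$product)))
})

test_that("divergent flanking IS pass the composite identity floors", {
  # two related elements: transposases at ~65% aa identity, IRs at ~73%
  set.seed(55)
  tp_a <- rnd_protein(300)
  tp_b <- sub_protein(tp_a, 105)
  ir_a <- rnd_dna(41)
  ir_b <- sub_dna(ir_a, 11)
  el_a <- structure(list(name = "ISdivA", element_sequence = rnd_dna(1300),
                         left_ir = ir_a, right_ir = ir_a,
                         transposase_translation = tp_a), class = "is_element")
  el_b <- structure(list(name = "ISdivB", element_sequence = rnd_dna(1300),
                         left_ir = ir_b, right_ir = ir_b,
                         transposase_translation = tp_b), class = "is_element")
  tp_id <- mobilomeR:::tpase_identity(el_a, el_b)
  ir_id <- mobilomeR:::ir_cross_identity(el_a, el_b)
  expect_gt(tp_id, 0.60); expect_lt(tp_id, 0.75)
  expect_gt(ir_id, 0.60); expect_lt(ir_id, 0.85)
  lib <- list(ISdivA = el_a, ISdivB = el_b)
  copies <- tibble::tibble(
    element = c("ISdivA", "ISdivB"), genome = "CT", replicon_id = "CT_chr",
    s_start = c(1000L, 12000L), s_end = c(2300L, 13300L), strand = "+",
    identity = 1, q_start = 1L, q_end = 1300L, span_fraction = 1, full = TRUE)
  g <- toy_genome("CT", seq = rnd_dna(20000))
  comp <- detect_composite_transposons(copies, list(g), lib)
  expect_equal(nrow(comp), 1L)
  # an isolated single copy yields no candidate
  comp1 <- detect_composite_transposons(copies[1, ], list(g), lib)
  expect_equal(nrow(comp1), 0L)
  # identity floors reject unrelated transposases
  el_c <- el_b; el_c$transposase_translation <- rnd_protein(300)
  lib2 <- list(ISdivA = el_a, ISdivB = el_c)
  expect_equal(nrow(detect_composite_transposons(copies, list(g), lib2)), 0L)
})
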