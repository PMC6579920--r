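# Synthetic genome sets with a planted-truth ledger.
#
# The generator emulates the statistical structure the pipeline detects: a
# set of related genomes sharing a core gene pool plus strain-specific
# ORFans, multi-copy IS elements with terminal inverted repeats (some
# inserted inside genes), a composite transposon, cross-species HGT blocks
# at 90-99% nucleotide identity, an att-bounded ICE-like island and partial
# plasmid integrations. Random number streams are per planting phase so
# changing one spec field does not reshuffle unrelated structure.

PRODUCT_VOCAB <- c(
  "ABC transporter ATP-binding protein", "MFS transporter",
  "amino acid permease", "sugar ABC transporter permease",
  "NAD-dependent dehydrogenase", "aminotransferase class I",
  "serine protease", "zinc metallopeptidase", "acetyl-CoA synthetase",
  "glycosyl transferase family protein", "ATP-dependent DNA ligase",
  "DNA gyrase subunit A", "DNA topoisomerase IV subunit B",
  "type I restriction-modification system methyltransferase",
  "transcriptional regulator, TetR family",
  "transcriptional regulator, MarR family", "RNA polymerase sigma factor",
  "cold shock protein", "chaperone protein DnaK", "catalase",
  "universal stress protein", "30S ribosomal protein S4",
  "elongation factor Tu", "GTP-binding protein", "membrane protein",
  "putative secreted protein", "hypothetical protein"
)

IRON_VOCAB <- c(
  "iron ABC transporter permease", "iron ABC transporter ATP-binding protein",
  "iron-siderophore ABC transporter substrate-binding protein",
  "siderophore biosynthesis protein", "ferric uptake regulation protein",
  "siderophore-interacting protein", "iron utilization protein",
  "TonB-dependent siderophore receptor"
)

ICE_ROSTER_DEFAULT <- c(
  "integrase", "site-specific integrase", "excisionase",
  "replicative DNA helicase", "DNA primase",
  "DNA polymerase III subunit alpha", "conjugal transfer protein",
  "chromosome partitioning protein ParB", "conjugal transfer protein TrbL",
  "type VI secretion protein", "single-stranded DNA-binding protein"
)

resample <- function(x, n = 1L, ...) x[sample.int(length(x), n, ...)]

#' Simulation configuration with study-scale defaults
#'
#' Defaults mirror the structures reported for dairy brevibacteria: 5-13
#' copies per genome of the dominant IS, HGT blocks at 92-99% identity, a
#' 12 bp att repeat (AGAAGTCCCAGT) flanking the island, and a partially
#' integrated ~7.6 kb plasmid covering 80% of its length; chromosome sizes
#' are scaled down to keep full runs fast.
#'
#' @param n_genomes recipient genomes.
#' @param chromosome_length base chromosome length, bp (before planting).
#' @param core_genes,shell_genes,orfans_per_genome planted gene-pool sizes
#'   (the first core gene is dnaA).
#' @param within_cluster_divergence per-genome substitution rate applied to
#'   core/shell genes.
#' @param gc background G+C fraction of intergenic DNA.
#' @param is_library_spec list of element specs (name, length, ir_length,
#'   copies_per_genome range, in_gene_fraction, product).
#' @param composite_spec composite-transposon spec (element, genome_index,
#'   cargo_genes).
#' @param hgt_spec list of blocks (length, identity, genome_index).
#' @param ice_spec island spec (genome_index, length, att, roster,
#'   filler_genes).
#' @param plasmid_spec plasmid spec (length, fragment_lengths, identity,
#'   genome_index).
#' @param is_noise per-copy substitution rate applied to planted IS copies.
#' @param orfan_hotspot list(fraction, at) placing a share of each genome's
#'   ORFans at consecutive positions around the given roster fraction.
#' @param seed master seed.
#' @export
simulation_config <- function(n_genomes = 5L,
                              chromosome_length = 400000L,
                              core_genes = 100L,
                              shell_genes = 40L,
                              orfans_per_genome = 10L,
                              within_cluster_divergence = 0.02,
                              gc = 0.627,
                              is_library_spec = NULL,
                              composite_spec = list(element = "ISsynB", genome_index = 2L,
                                                    cargo_genes = 8L),
                              hgt_spec = NULL,
                              ice_spec = list(genome_index = 1L, length = 30000L,
                                              att = "AGAAGTCCCAGT",
                                              roster = ICE_ROSTER_DEFAULT,
                                              filler_genes = 14L),
                              plasmid_spec = list(length = 7600L,
                                                  fragment_lengths = c(3040L, 2280L, 760L),
                                                  identity = 0.99, genome_index = 1L),
                              is_noise = 0,
                              orfan_hotspot = list(fraction = 0.6, at = 0.6),
                              seed = 42L) {
  if (is.null(is_library_spec)) {
    is_library_spec <- list(
      list(name = "ISsynA", length = 1350L, ir_length = 16L,
           copies_per_genome = c(5L, 13L), in_gene_fraction = 0.2,
           product = "IS3 family transposase"),
      list(name = "ISsynB", length = 1200L, ir_length = 24L,
           copies_per_genome = c(2L, 4L), in_gene_fraction = 0,
           product = "ISL3 family transposase")
    )
  }
  if (is.null(hgt_spec)) {
    hgt_spec <- list(
      list(length = 12000L, identity = 0.97, genome_index = 1L),
      list(length = 3000L, identity = 0.92, genome_index = 2L),
      list(length = 1500L, identity = 0.95, genome_index = 3L),
      list(length = 25000L, identity = 0.99, genome_index = 1L)
    )
  }
  cfg <- list(n_genomes = n_genomes, chromosome_length = chromosome_length,
              core_genes = core_genes, shell_genes = shell_genes,
              orfans_per_genome = orfans_per_genome,
              within_cluster_divergence = within_cluster_divergence, gc = gc,
              is_library_spec = is_library_spec, composite_spec = composite_spec,
              hgt_spec = hgt_spec, ice_spec = ice_spec,
              plasmid_spec = plasmid_spec, is_noise = is_noise,
              orfan_hotspot = orfan_hotspot, seed = seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_genomes >= 1, cfg$chromosome_length > 0, cfg$core_genes >= 1)
  if (cfg$within_cluster_divergence < 0 || cfg$within_cluster_divergence > 0.2) {
    abort("within_cluster_divergence must be in [0, 0.2]")
  }
  if (cfg$is_noise < 0 || cfg$is_noise > 0.2) abort("is_noise must be in [0, 0.2]")
  for (h in cfg$hgt_spec) {
    if (h$identity < 0.80 || h$identity > 1.0) abort("hgt identity must be in [0.80, 1]")
  }
  if (sum(cfg$plasmid_spec$fragment_lengths) > cfg$plasmid_spec$length) {
    abort("plasmid fragments exceed plasmid length")
  }
  invisible(cfg)
}

# --- gene and replicon construction ----------------------------------------

make_gene_pool <- function(n, products = PRODUCT_VOCAB, codon_range = c(100L, 400L)) {
  tibble(
    codons = resample(codon_range[1]:codon_range[2], n, replace = TRUE),
    product = resample(products, n, replace = TRUE)
  ) |>
    mutate(dna = purrr::map_chr(.data$codons, random_orf))
}

orf_translation <- function(dna) translate_dna(substr(dna, 1L, nchar(dna) - 3L))

RRNA_OPERON <- tibble(
  kind = c("rRNA", "rRNA", "rRNA", "tRNA", "tRNA"),
  product = c("16S ribosomal RNA", "23S ribosomal RNA", "5S ribosomal RNA",
              "tRNA-Ala", "tRNA-Gly"),
  len = c(1500L, 2900L, 120L, 76L, 76L)
)

# split `leftover` bp into n gaps of at least min_gap, summing exactly
distribute_gaps <- function(leftover, n, min_gap) {
  extra <- leftover - min_gap * n
  if (extra < 0L) abort("infeasible packing: genes exceed replicon length budget")
  w <- runif(n, 0.5, 1.5)
  min_gap + as.vector(stats::rmultinom(1L, extra, w))
}

# assemble a replicon from an ordered roster; each gene is preceded by an
# intergenic gap and the final gene is flush with the sequence end, so the
# ori intergenic region starts at base 1 and origin normalization is the
# identity on freshly built chromosomes.
build_replicon <- function(replicon_id, roster, target_length, gc,
                           topology = "circular", is_chromosome = TRUE) {
  gene_bp <- sum(nchar(roster$dna))
  n <- nrow(roster)
  gaps <- distribute_gaps(target_length - gene_bp, n, 60L)
  pieces <- character(2L * n)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- random_dna(gaps[i], gc)
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pieces[2L * i] <- roster$dna[i]
    pos <- pos + nchar(roster$dna[i])
  }
  feats <- feature_table(
    locus_tag = roster$locus_tag, kind = roster$kind,
    start = starts, end = starts + nchar(roster$dna) - 1L,
    strand = "+", product = roster$product, translation = roster$translation
  )
  replicon(replicon_id, paste(pieces, collapse = ""), topology, feats,
           is_chromosome = is_chromosome)
}

# --- insertion machinery ----------------------------------------------------

# insert seq so it occupies [pos, pos+len-1]; features at/after pos shift;
# the feature spanning pos may be split when designated as the host.
insert_dna <- function(g, replicon_id, pos, seq, new_features = NULL,
                       split_host = NULL) {
  r <- g$replicons[[replicon_id]]
  n <- nchar(r$sequence)
  len <- nchar(seq)
  stopifnot(pos >= 1L, pos <= n + 1L)
  r$sequence <- paste0(substr(r$sequence, 1L, pos - 1L), seq,
                       substr(r$sequence, pos, n))
  f <- r$features
  out <- list()
  for (i in seq_len(nrow(f))) {
    row <- f[i, ]
    if (row$start >= pos) {
      row$start <- row$start + len; row$end <- row$end + len
      out[[length(out) + 1L]] <- row
    } else if (row$end >= pos) {
      if (!is.null(split_host) && identical(row$locus_tag, split_host)) {
        left <- row; right <- row
        left$end <- pos - 1L
        left$locus_tag <- paste0(row$locus_tag, "_5p")
        left$translation <- NA_character_
        right$start <- pos + len; right$end <- row$end + len
        right$locus_tag <- paste0(row$locus_tag, "_3p")
        right$translation <- NA_character_
        out[[length(out) + 1L]] <- left
        out[[length(out) + 1L]] <- right
      } else {
        abort(sprintf("insertion at %d would split feature %s", pos, row$locus_tag))
      }
    } else {
      out[[length(out) + 1L]] <- row
    }
  }
  f2 <- bind_rows(out)
  if (!is.null(new_features) && nrow(new_features)) {
    nf <- mutate(new_features, start = .data$start + pos - 1L,
                 end = .data$end + pos - 1L, wraps = FALSE)
    f2 <- bind_rows(f2, nf)
  }
  r$features <- arrange(f2, .data$start)
  g$replicons[[replicon_id]] <- r
  g
}

shift_intervals <- function(tbl, strain, replicon_id, pos, len,
                            cols = c("start", "end")) {
  if (is.null(tbl) || !nrow(tbl)) return(tbl)
  hit <- tbl$genome == strain & tbl$replicon_id == replicon_id
  for (cl in cols) {
    if (cl %in% names(tbl)) {
      tbl[[cl]][hit & tbl[[cl]] >= pos] <- tbl[[cl]][hit & tbl[[cl]] >= pos] + len
    }
  }
  tbl
}

# state-level insertion: updates the genome, all positional ledgers and zones
sim_insert <- function(st, strain, pos, seq, new_features = NULL,
                       split_host = NULL, zone = TRUE) {
  g <- st$genomes[[strain]]
  rid <- chromosome(g)$replicon_id
  st$genomes[[strain]] <- insert_dna(g, rid, pos, seq, new_features, split_host)
  len <- nchar(seq)
  for (nm in c("zones", "is_copies", "hgt_blocks", "plasmid_fragments",
               "composite", "ice")) {
    st[[nm]] <- shift_intervals(st[[nm]], strain, rid, pos, len)
  }
  if (zone) {
    st$zones <- bind_rows(st$zones, tibble(genome = strain, replicon_id = rid,
                                           start = pos, end = pos + len - 1L))
  }
  st
}

interval_distance <- function(pos_start, pos_end, s, e) {
  pmax(s - pos_end, pos_start - e, 0L)
}

pick_insertion_site <- function(r, zones, len, margin = 20L,
                                spacing_intervals = NULL, spacing = 0L,
                                tries = 200L) {
  f <- arrange(r$features, .data$start)
  n_rep <- nchar(r$sequence)
  gs <- c(f$end[-nrow(f)] + 1L, f$end[nrow(f)] + 1L)
  ge <- c(f$start[-1] - 1L, n_rep)
  ok <- ge - gs + 1L >= 2L * margin + 1L
  gs <- gs[ok]; ge <- ge[ok]
  if (!length(gs)) abort("no intergenic gap available for insertion")
  for (t in seq_len(tries)) {
    gi <- resample(seq_along(gs), 1L)
    pos <- resample((gs[gi] + margin):(ge[gi] - margin + 1L), 1L)
    if (!is.null(zones) && nrow(zones) &&
        any(zones$start < pos & pos <= zones$end)) next
    if (!is.null(spacing_intervals) && nrow(spacing_intervals)) {
      d <- interval_distance(pos, pos + len - 1L, spacing_intervals$start,
                             spacing_intervals$end)
      if (any(d <= spacing)) next
    }
    return(pos)
  }
  abort("placement error: no admissible insertion site after bounded retries")
}

# --- IS element construction ------------------------------------------------

make_is_element <- function(spec, gc) {
  ir <- random_dna(spec$ir_length, gc)
  pad <- 30L
  n_codons <- (spec$length - 2L * spec$ir_length - 2L * pad - 6L) %/% 3L
  orf <- random_orf(n_codons)
  used <- 2L * spec$ir_length + 2L * pad + nchar(orf)
  fill <- spec$length - used
  seqs <- paste0(ir, random_dna(pad, gc), orf, random_dna(pad + fill, gc), revcomp(ir))
  list(name = spec$name, sequence = seqs, ir = ir,
       tp_start = spec$ir_length + pad + 1L,
       tp_end = spec$ir_length + pad + nchar(orf),
       product = spec$product, translation = orf_translation(orf))
}

is_element_features <- function(el, strand) {
  len <- nchar(el$sequence)
  if (strand == "+") {
    tibble(start = el$tp_start, end = el$tp_end, strand = "+")
  } else {
    tibble(start = len - el$tp_end + 1L, end = len - el$tp_start + 1L, strand = "-")
  }
}

# --- planting operations ----------------------------------------------------

# core IS-planting routine (RNG assumed seeded by the caller)
.plant_is <- function(st, strain, el, n_copies, in_gene_fraction, noise,
                      spacing = 20000L, counter_start = 1L) {
  rid <- chromosome(st$genomes[[strain]])$replicon_id
  n_in_gene <- round(in_gene_fraction * n_copies)
  for (ci in seq_len(n_copies)) {
    same <- filter(st$is_copies, .data$element == el$name, .data$genome == strain)
    strand <- resample(c("+", "-"), 1L)
    copy_seq <- mutate_dna(el$sequence, noise)
    if (strand == "-") copy_seq <- revcomp(copy_seq)
    tp <- is_element_features(el, strand)
    tag <- sprintf("%s_%s_%02d", strain, el$name, counter_start + ci - 1L)
    feats <- tibble(locus_tag = tag, kind = "CDS", start = tp$start, end = tp$end,
                    strand = tp$strand, product = el$product,
                    translation = el$translation, wraps = FALSE)
    g <- st$genomes[[strain]]
    chrom <- chromosome(g)
    if (ci <= n_in_gene) {
      hosts <- filter(st$orfan_pool, .data$genome == strain)
      if (!nrow(hosts)) abort("no undisrupted ORFan host available")
      host <- resample(hosts$locus_tag, 1L)
      hf <- filter(chrom$features, .data$locus_tag == host)
      width <- hf$end - hf$start + 1L
      pos <- hf$start + resample(30L:(width - 30L), 1L)
      same_d <- if (nrow(same)) interval_distance(pos, pos + nchar(copy_seq) - 1L,
                                                  same$start, same$end) else Inf
      if (any(same_d <= spacing)) { pos <- NULL }
      if (is.null(pos)) {
        # fall back to an intergenic site for this copy
        pos <- pick_insertion_site(chrom, filter(st$zones, .data$genome == strain),
                                   nchar(copy_seq), spacing_intervals = same,
                                   spacing = spacing)
        host <- NA_character_
      }
    } else {
      host <- NA_character_
      pos <- pick_insertion_site(chrom, filter(st$zones, .data$genome == strain),
                                 nchar(copy_seq), spacing_intervals = same,
                                 spacing = spacing)
    }
    offset <- if (!is.na(host)) pos - filter(chrom$features, .data$locus_tag == host)$start else NA_integer_
    st <- sim_insert(st, strain, pos, copy_seq, new_features = feats,
                     split_host = if (is.na(host)) NULL else host)
    st$is_copies <- bind_rows(st$is_copies, tibble(
      element = el$name, genome = strain, replicon_id = rid,
      start = pos, end = pos + nchar(copy_seq) - 1L, strand = strand,
      disrupts = host, insertion_offset = offset, in_composite = FALSE))
    if (!is.na(host)) {
      st$orfan_pool <- filter(st$orfan_pool,
                              !(.data$genome == strain & .data$locus_tag == host))
      st$disruptions <- bind_rows(st$disruptions, tibble(
        genome = strain, replicon_id = rid, element = el$name,
        host_locus = host, insertion_offset = offset))
    }
  }
  st
}

#' Plant IS copies into a genome
#'
#' Copies are inserted at random non-overlapping sites (same-element copies
#' kept farther apart than a composite-transposon cargo span); the
#' requested fraction is inserted inside ORFan genes, splitting the host
#' CDS annotation.
#'
#' @param genome a [genome()] from this generator.
#' @param element_spec spec list (name, length, ir_length, product).
#' @param n_copies copies to insert.
#' @param in_gene_fraction fraction inserted into genes.
#' @param seed RNG seed.
#' @param noise per-copy substitution rate.
#' @return list(genome, copies, disruptions).
#' @export
plant_is <- function(genome, element_spec, n_copies, in_gene_fraction = 0,
                     seed = 1L, noise = 0) {
  st <- new_sim_state(list(genome))
  el <- with_stream(seed, "sequence", make_is_element(element_spec, gc = 0.5))
  st <- with_stream(seed, "is",
                    .plant_is(st, genome$strain, el, n_copies, in_gene_fraction, noise))
  list(genome = st$genomes[[genome$strain]], copies = st$is_copies,
       disruptions = st$disruptions, element = el)
}

# minimal state wrapper for the standalone plant_* entry points
new_sim_state <- function(genomes) {
  gl <- setNames(genomes, vapply(genomes, `[[`, "", "strain"))
  zones <- purrr::map_dfr(gl, function(g) {
    chrom <- chromosome(g)
    first <- if (nrow(chrom$features)) min(chrom$features$start) else 2L
    tibble(genome = g$strain, replicon_id = chrom$replicon_id,
           start = 1L, end = max(first - 1L, 1L))
  })
  orfans <- genes(gl) |> filter(.data$kind == "CDS") |>
    select(genome = "genome", locus_tag = "locus_tag")
  list(genomes = gl, zones = zones, orfan_pool = orfans,
       is_copies = tibble(), hgt_blocks = tibble(), plasmid_fragments = tibble(),
       composite = tibble(), ice = tibble(), disruptions = tibble())
}

# extract a donor window [s, s+len-1] with its fully-contained features,
# mutate to the target identity, and return sequence + relative features
take_donor_block <- function(donor_rep, s, len, identity) {
  e <- s + len - 1L
  block <- substr(donor_rep$sequence, s, e)
  k <- round((1 - identity) * len)
  if (k > 0L) {
    chars <- strsplit(block, "", fixed = TRUE)[[1]]
    posn <- resample(seq_len(len), k)
    chars[posn] <- vapply(chars[posn], function(old)
      resample(setdiff(DNA_ALPHABET, old), 1L), "")
    block <- paste(chars, collapse = "")
  }
  f <- filter(donor_rep$features, .data$start >= s, .data$end <= e,
              .data$kind == "CDS")
  rel <- mutate(f, start = .data$start - s + 1L, end = .data$end - s + 1L)
  if (nrow(rel)) {
    rel$translation <- vapply(seq_len(nrow(rel)), function(i) {
      cds <- substr(block, rel$start[i], rel$end[i])
      if (rel$strand[i] == "-") cds <- revcomp(cds)
      orf_translation(cds)
    }, "")
  }
  list(sequence = block, features = rel, measured_identity = 1 - k / len)
}

#' Plant a cross-species homology block
#'
#' Copies a donor segment (whole genes carried over with their products)
#' into the recipient at an intergenic site, substituting bases to hit the
#' target identity within 0.5%.
#'
#' @param recipient,donor [genome()] objects.
#' @param length block length, bp.
#' @param identity target nucleotide identity in [0.80, 1].
#' @param seed RNG seed.
#' @return list(recipient, block) where block records both coordinate sets.
#' @export
plant_hgt_block <- function(recipient, donor, length, identity, seed = 1L) {
  if (identity < 0.80 || identity > 1.0) abort("identity must be in [0.80, 1]")
  donor_rep <- chromosome(donor)
  if (length > nchar(donor_rep$sequence)) abort("block longer than donor")
  st <- new_sim_state(list(recipient))
  res <- with_stream(seed, "hgt",
                     .plant_hgt(st, recipient$strain, donor, donor_rep, length, identity,
                                used_donor = tibble(start = integer(), end = integer()),
                                tag_prefix = "hgt1"))
  list(recipient = res$st$genomes[[recipient$strain]], block = res$st$hgt_blocks)
}

.plant_hgt <- function(st, strain, donor, donor_rep, len, identity, used_donor,
                       tag_prefix) {
  n_d <- nchar(donor_rep$sequence)
  for (t in seq_len(200L)) {
    s <- resample(seq_len(n_d - len + 1L), 1L)
    if (!nrow(used_donor) ||
        all(interval_distance(s, s + len - 1L, used_donor$start, used_donor$end) > 0L)) break
    if (t == 200L) abort("placement error: no free donor window")
  }
  blk <- take_donor_block(donor_rep, s, len, identity)
  feats <- blk$features
  if (nrow(feats)) {
    feats$locus_tag <- sprintf("%s_%s_%02d", strain, tag_prefix, seq_len(nrow(feats)))
  }
  chrom <- chromosome(st$genomes[[strain]])
  pos <- pick_insertion_site(chrom, filter(st$zones, .data$genome == strain),
                             len)
  st <- sim_insert(st, strain, pos, blk$sequence, new_features = feats)
  st$hgt_blocks <- bind_rows(st$hgt_blocks, tibble(
    genome = strain, replicon_id = chrom$replicon_id,
    start = pos, end = pos + len - 1L, length = len,
    identity_target = identity, identity_measured = blk$measured_identity,
    partner = donor$strain, partner_species = donor$species_label,
    donor_start = s, donor_end = s + len - 1L,
    n_genes = nrow(feats)))
  list(st = st, donor_window = tibble(start = s, end = s + len - 1L))
}

build_island <- function(spec, gc) {
  att <- toupper(spec$att)
  roster_products <- c(spec$roster, rep("hypothetical protein", spec$filler_genes))
  genes <- tibble(
    codons = resample(150L:350L, length(roster_products), replace = TRUE),
    product = roster_products
  ) |>
    mutate(dna = purrr::map_chr(.data$codons, random_orf))
  interior_target <- spec$length - 2L * nchar(att)
  gene_bp <- sum(nchar(genes$dna))
  # a terminal intergenic gap keeps the boundary repeat context random
  gaps <- distribute_gaps(interior_target - gene_bp, nrow(genes) + 1L, 40L)
  pieces <- character(2L * nrow(genes) + 1L)
  starts <- integer(nrow(genes))
  pos <- nchar(att)
  for (i in seq_len(nrow(genes))) {
    pieces[2L * i - 1L] <- random_dna(gaps[i], gc)
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pieces[2L * i] <- genes$dna[i]
    pos <- pos + nchar(genes$dna[i])
  }
  pieces[2L * nrow(genes) + 1L] <- random_dna(gaps[nrow(genes) + 1L], gc)
  seqs <- paste0(att, paste(pieces, collapse = ""), att)
  stopifnot(nchar(seqs) == spec$length)
  feats <- tibble(locus_tag = sprintf("ice_%02d", seq_len(nrow(genes))),
                  kind = "CDS", start = starts,
                  end = starts + nchar(genes$dna) - 1L, strand = "+",
                  product = genes$product,
                  translation = unname(vapply(genes$dna, orf_translation, "")),
                  wraps = FALSE)
  list(sequence = seqs, features = feats, att = att)
}

#' Plant an att-bounded ICE-like island
#'
#' The island (signature genes per roster plus fillers, bounded by the att
#' repeat on both sides) is inserted immediately after the 3' end of a host
#' gene.
#'
#' @param genome a [genome()].
#' @param ice_spec spec list (length, att, roster, filler_genes).
#' @param seed RNG seed.
#' @return list(genome, island) with the planted interval.
#' @export
plant_ice <- function(genome, ice_spec, seed = 1L) {
  st <- new_sim_state(list(genome))
  st <- with_stream(seed, "ice", .plant_ice(st, genome$strain, ice_spec, gc = 0.5))
  list(genome = st$genomes[[genome$strain]], island = st$ice)
}

.plant_ice <- function(st, strain, spec, gc) {
  isl <- build_island(spec, gc)
  chrom <- chromosome(st$genomes[[strain]])
  rid <- chrom$replicon_id
  # host gene: 3' end must face a free gap large enough to check zones
  f <- arrange(filter(chrom$features, .data$kind == "CDS"), .data$start)
  zones <- filter(st$zones, .data$genome == strain)
  for (t in seq_len(200L)) {
    hi <- resample(seq_len(nrow(f) - 1L), 1L)
    pos <- f$end[hi] + 1L
    nxt <- f$start[hi + 1L]
    if (nxt - pos < 40L) next
    if (nrow(zones) && any(zones$start < pos & pos <= zones$end)) next
    host <- f$locus_tag[hi]
    # block accidental extension of the boundary repeat into its context:
    # the interior bases adjacent to each att must differ from the
    # corresponding chromosomal context bases
    seqs <- isl$sequence
    a <- nchar(isl$att); li <- nchar(seqs)
    c_left <- substr(chrom$sequence, pos - 1L, pos - 1L)
    c_right <- substr(chrom$sequence, pos, pos)
    if (substr(seqs, li - a, li - a) == c_left) {
      substr(seqs, li - a, li - a) <- setdiff(DNA_ALPHABET, c_left)[1]
    }
    if (substr(seqs, a + 1L, a + 1L) == c_right) {
      substr(seqs, a + 1L, a + 1L) <- setdiff(DNA_ALPHABET, c_right)[1]
    }
    isl$sequence <- seqs
    feats <- mutate(isl$features,
                    locus_tag = sprintf("%s_%s", strain, .data$locus_tag))
    st <- sim_insert(st, strain, pos, isl$sequence, new_features = feats)
    st$ice <- bind_rows(st$ice, tibble(
      genome = strain, replicon_id = rid, start = pos,
      end = pos + nchar(isl$sequence) - 1L, att = isl$att, host_locus = host,
      n_genes = nrow(isl$features),
      n_signature = sum(isl$features$product != "hypothetical protein")))
    return(st)
  }
  abort("placement error: no admissible island site")
}

# excision-diagnostic primers derived from the final island coordinates:
# junction pair (integrated only), internal pair (integrated + circle),
# outward pair (circle only; the primers-2-and-5 analogue)
make_excision_primers <- function(genome, island_interval, primer_len = 22L) {
  s <- chromosome(genome)$sequence
  L <- island_interval[1]; R <- island_interval[2]
  plus_at <- function(a) substr(s, a, a + primer_len - 1L)
  minus_at <- function(a) revcomp(substr(s, a, a + primer_len - 1L))
  tibble(
    name = c("P1_flank_fwd", "P2_island_rev", "P3_island_fwd", "P4_island_rev",
             "P5_island_fwd", "P6_island_rev"),
    sequence = c(plus_at(L - 400L), minus_at(L + 300L), plus_at(L + 1000L),
                 minus_at(L + 2500L), plus_at(R - 321L), minus_at(L + 600L))
  )
}

# --- full study-conditions suite -------------------------------------------

#' Simulate the full synthetic study suite
#'
#' Builds `n_genomes` recipient genomes plus one cross-species partner
#' genome (carrying the plasmid) and plants, per configuration: core/shell
#' gene pools with per-genome ORFans, IS copies (some disrupting genes), a
#' composite transposon, HGT blocks, an att-bounded island, and partial
#' plasmid integrations. Returns the genomes together with a truth ledger
#' holding every planted interval and the expected pan-genome spectrum.
#'
#' @param config a [simulation_config()].
#' @return list (genomes, partners, plasmid, primers, ledger, config) of
#'   class `mobilome_sim`.
#' @export
simulate_genome_set <- function(config = simulation_config()) {
  validate_config(config)
  seed <- config$seed
  n <- config$n_genomes
  strains <- sprintf("SYN%02d", seq_len(n))
  recipient_species <- "Brevibacterium synthetica"
  partner_species <- "Corynebacterium synthetica"

  base <- with_stream(seed, "sequence", {
    core <- make_gene_pool(config$core_genes)
    core$product[1] <- "chromosomal replication initiator protein DnaA"
    shell <- make_gene_pool(config$shell_genes)
    shell$subset <- purrr::map(seq_len(nrow(shell)), function(i) {
      sort(resample(seq_len(n), resample(2:max(2, n - 1), 1L)))
    })
    orfans <- purrr::map(seq_len(n), function(gi) {
      make_gene_pool(config$orfans_per_genome,
                     products = c(rep("hypothetical protein", 6), PRODUCT_VOCAB))
    })
    rrna <- mutate(RRNA_OPERON, dna = purrr::map_chr(.data$len, ~ random_dna(.x, config$gc)))
    elements <- purrr::map(config$is_library_spec, make_is_element, gc = config$gc)
    names(elements) <- vapply(elements, `[[`, "", "name")
    cargo <- tibble(codons = resample(350L:450L, config$composite_spec$cargo_genes,
                                      replace = TRUE),
                    product = resample(IRON_VOCAB, config$composite_spec$cargo_genes,
                                       replace = TRUE)) |>
      mutate(dna = purrr::map_chr(.data$codons, random_orf))
    partner_core <- make_gene_pool(config$core_genes + 20L)
    partner_core$product[1] <- "chromosomal replication initiator protein DnaA"
    plasmid_genes <- tibble(
      codons = resample(80L:150L, 16L, replace = TRUE),
      product = c("replication protein RepA", "replication protein RepB",
                  "plasmid partitioning protein", rep("hypothetical protein", 13L))
    ) |>
      mutate(dna = purrr::map_chr(.data$codons, random_orf))
    list(core = core, shell = shell, orfans = orfans, rrna = rrna,
         elements = elements, cargo = cargo, partner_core = partner_core,
         plasmid_genes = plasmid_genes)
  })

  # per-genome rosters + divergence + assembly
  built <- with_stream(seed, "mutation", {
    purrr::map(seq_len(n), function(gi) {
      strain <- strains[gi]
      core_g <- base$core |>
        mutate(dna = purrr::map_chr(.data$dna, mutate_cds,
                                    rate = config$within_cluster_divergence),
               key = sprintf("core%04d", dplyr::row_number()))
      shell_keep <- vapply(base$shell$subset, function(s) gi %in% s, logical(1))
      shell_g <- base$shell[shell_keep, ] |>
        mutate(dna = purrr::map_chr(.data$dna, mutate_cds,
                                    rate = config$within_cluster_divergence),
               key = sprintf("shell%04d", which(shell_keep)))
      orf_g <- base$orfans[[gi]] |>
        mutate(key = sprintf("%s_orfan%02d", strain, dplyr::row_number()))
      list(strain = strain, core = core_g, shell = shell_g, orfans = orf_g)
    })
  })

  genomes <- with_stream(seed, "placement", {
    purrr::map(built, function(b) {
      strain <- b$strain
      backbone <- bind_rows(
        b$core |> mutate(kind = "CDS") |> select("codons", "product", "dna", "key", "kind"),
        b$shell |> select("codons", "product", "dna", "key") |> mutate(kind = "CDS")
      )
      orf <- b$orfans |> select("codons", "product", "dna", "key") |> mutate(kind = "CDS")
      n_slots <- nrow(backbone) + 1L
      n_hot <- ceiling(config$orfan_hotspot$fraction * nrow(orf))
      hot_slot <- max(2L, floor(config$orfan_hotspot$at * n_slots))
      slots <- c(rep(hot_slot, n_hot),
                 resample(seq_len(n_slots), nrow(orf) - n_hot, replace = TRUE))
      roster <- backbone
      for (oi in order(slots, decreasing = TRUE)) {
        at <- min(slots[oi], nrow(roster) + 1L)
        roster <- bind_rows(roster[seq_len(at - 1L), ], orf[oi, ],
                            roster[seq(at, length.out = nrow(roster) - at + 1L), ])
      }
      rr <- base$rrna |>
        mutate(key = sprintf("%s_rrna%d", strain, dplyr::row_number())) |>
        select("product", "dna", "key", "kind")
      roster <- bind_rows(roster, rr) |>
        mutate(locus_tag = sprintf("%s_%04d", strain, dplyr::row_number()),
               translation = NA_character_)
      cds <- roster$kind == "CDS"
      roster$translation[cds] <- purrr::map_chr(roster$dna[cds], orf_translation)
      rep <- build_replicon(paste0(strain, "_chr"), roster,
                            config$chromosome_length, config$gc)
      g <- genome(strain, recipient_species, list(rep), ori_offset = 0L)
      attr(g, "roster_keys") <- select(roster, "locus_tag", "key", "kind")
      g
    })
  })
  names(genomes) <- strains

  partner <- with_stream(seed, "partner", {
    roster <- base$partner_core |>
      mutate(key = sprintf("prt%04d", dplyr::row_number()), kind = "CDS",
             locus_tag = sprintf("PRT01_%04d", dplyr::row_number()),
             translation = purrr::map_chr(.data$dna, orf_translation))
    rep <- build_replicon("PRT01_chr", roster, config$chromosome_length, config$gc)
    genome("PRT01", partner_species, list(rep), ori_offset = 0L)
  })

  plasmid <- with_stream(seed, "plasmid", {
    roster <- base$plasmid_genes |>
      mutate(key = sprintf("pls%02d", dplyr::row_number()), kind = "CDS",
             locus_tag = sprintf("pSYN_%02d", dplyr::row_number()),
             translation = purrr::map_chr(.data$dna, orf_translation))
    build_replicon("pSYN", roster, config$plasmid_spec$length, config$gc,
                   is_chromosome = FALSE)
  })
  partner$replicons[["pSYN"]] <- plasmid

  # mutable planting state
  st <- new_sim_state(unname(genomes))
  st$orfan_pool <- purrr::map_dfr(built, function(b) {
    strain <- b$strain
    keys <- attr(genomes[[strain]], "roster_keys")
    keys |>
      filter(grepl("_orfan", .data$key)) |>
      transmute(genome = strain, locus_tag = .data$locus_tag)
  })

  # HGT blocks
  st <- with_stream(seed, "hgt", {
    used <- tibble(start = integer(), end = integer())
    donor_rep <- chromosome(partner)
    for (bi in seq_along(config$hgt_spec)) {
      h <- config$hgt_spec[[bi]]
      res <- .plant_hgt(st, strains[h$genome_index], partner, donor_rep,
                        h$length, h$identity, used, sprintf("hgt%d", bi))
      st <- res$st
      used <- bind_rows(used, res$donor_window)
    }
    st
  })

  # plasmid fragments
  st <- with_stream(seed, "plasmid_frag", {
    fl <- config$plasmid_spec$fragment_lengths
    strain <- strains[config$plasmid_spec$genome_index]
    rid <- chromosome(st$genomes[[strain]])$replicon_id
    np <- nchar(plasmid$sequence)
    # allocate the free plasmid space between fragments so any occupancy fits
    free <- np - sum(fl)
    gaps <- as.vector(stats::rmultinom(1L, free, rep(1, length(fl) + 1L)))
    frag_starts <- cumsum(gaps[seq_along(fl)]) + c(0L, cumsum(fl[-length(fl)])) + 1L
    for (fi in seq_along(fl)) {
      s <- frag_starts[fi]
      blk <- take_donor_block(plasmid, s, fl[fi], config$plasmid_spec$identity)
      feats <- blk$features
      if (nrow(feats)) {
        feats$locus_tag <- sprintf("%s_pls%d_%02d", strain, fi, seq_len(nrow(feats)))
      }
      pos <- pick_insertion_site(chromosome(st$genomes[[strain]]),
                                 filter(st$zones, .data$genome == strain), fl[fi])
      st <- sim_insert(st, strain, pos, blk$sequence, new_features = feats)
      st$plasmid_fragments <- bind_rows(st$plasmid_fragments, tibble(
        genome = strain, replicon_id = rid, start = pos, end = pos + fl[fi] - 1L,
        plasmid_start = s, plasmid_end = s + fl[fi] - 1L, length = fl[fi],
        identity_target = config$plasmid_spec$identity,
        identity_measured = blk$measured_identity, n_genes = nrow(feats)))
    }
    st
  })

  # ICE island
  st <- with_stream(seed, "ice", {
    .plant_ice(st, strains[config$ice_spec$genome_index], config$ice_spec,
               gc = config$gc)
  })

  # composite transposon, then random IS copies
  st <- with_stream(seed, "is", {
    comp <- config$composite_spec
    el <- base$elements[[comp$element]]
    comp_strain <- strains[comp$genome_index]
    cg <- base$cargo
    gaps <- resample(80L:150L, nrow(cg) + 1L, replace = TRUE)
    pieces <- el$sequence
    starts <- integer(nrow(cg))
    pos0 <- nchar(el$sequence)
    for (i in seq_len(nrow(cg))) {
      pieces <- paste0(pieces, random_dna(gaps[i], config$gc))
      pos0 <- pos0 + gaps[i]
      starts[i] <- pos0 + 1L
      pieces <- paste0(pieces, cg$dna[i])
      pos0 <- pos0 + nchar(cg$dna[i])
    }
    pieces <- paste0(pieces, random_dna(gaps[nrow(cg) + 1L], config$gc), el$sequence)
    comp_len <- nchar(pieces)
    elen <- nchar(el$sequence)
    tpL <- is_element_features(el, "+")
    feats <- bind_rows(
      tibble(locus_tag = sprintf("%s_%s_c1", comp_strain, el$name), kind = "CDS",
             start = tpL$start, end = tpL$end, strand = "+", product = el$product,
             translation = el$translation, wraps = FALSE),
      tibble(locus_tag = sprintf("%s_cargo_%02d", comp_strain, seq_len(nrow(cg))),
             kind = "CDS", start = starts, end = starts + nchar(cg$dna) - 1L,
             strand = "+", product = cg$product,
             translation = unname(vapply(cg$dna, orf_translation, "")), wraps = FALSE),
      tibble(locus_tag = sprintf("%s_%s_c2", comp_strain, el$name), kind = "CDS",
             start = comp_len - elen + tpL$start, end = comp_len - elen + tpL$end,
             strand = "+", product = el$product, translation = el$translation,
             wraps = FALSE)
    )
    pos <- pick_insertion_site(chromosome(st$genomes[[comp_strain]]),
                               filter(st$zones, .data$genome == comp_strain),
                               comp_len)
    st <- sim_insert(st, comp_strain, pos, pieces, new_features = feats)
    rid <- chromosome(st$genomes[[comp_strain]])$replicon_id
    st$composite <- tibble(
      genome = comp_strain, replicon_id = rid, start = pos,
      end = pos + comp_len - 1L, element = el$name, element_length = elen,
      cargo_start = pos + elen, cargo_end = pos + comp_len - elen - 1L,
      n_cargo_genes = nrow(cg))
    st$is_copies <- bind_rows(st$is_copies, tibble(
      element = el$name, genome = comp_strain, replicon_id = rid,
      start = c(pos, pos + comp_len - elen), end = c(pos + elen - 1L, pos + comp_len - 1L),
      strand = "+", disrupts = NA_character_, insertion_offset = NA_integer_,
      in_composite = TRUE))
    # random copies per genome per element
    for (el2 in base$elements) {
      for (gi in seq_len(n)) {
        spec <- purrr::detect(config$is_library_spec, ~ .x$name == el2$name)
        nc <- resample(spec$copies_per_genome[1]:spec$copies_per_genome[2], 1L)
        st <- .plant_is(st, strains[gi], el2, nc, spec$in_gene_fraction,
                        config$is_noise)
      }
    }
    st
  })

  primers <- make_excision_primers(st$genomes[[strains[config$ice_spec$genome_index]]],
                                   c(st$ice$start[1], st$ice$end[1]))

  ledger <- build_truth_ledger(st, built, base, config, strains)
  structure(list(genomes = unname(st$genomes[strains]), partners = list(partner),
                 plasmid = plasmid, primers = primers, ledger = ledger,
                 config = config),
            class = "mobilome_sim")
}

build_truth_ledger <- function(st, built, base, config, strains) {
  n <- config$n_genomes
  # cluster memberships of the planted base gene pools
  memberships <- purrr::map_dfr(strains, function(strain) {
    keys <- attr(st$genomes[[strain]], "roster_keys")
    # roster_keys attribute travels from construction; split genes fall out
    present <- genes(st$genomes[[strain]]) |> filter(.data$kind == "CDS")
    keys |>
      filter(.data$kind == "CDS") |>
      semi_join(present, by = "locus_tag") |>
      transmute(cluster_key = .data$key, genome = strain,
                locus_tag = .data$locus_tag)
  })
  disrupted_per_genome <- if (nrow(st$disruptions)) {
    count(st$disruptions, .data$genome, name = "n_disrupted")
  } else tibble(genome = character(), n_disrupted = integer())
  n_disrupted <- sum(disrupted_per_genome$n_disrupted)

  shell_sizes <- vapply(base$shell$subset, length, integer(1))
  hgt_genes <- sum(st$hgt_blocks$n_genes)
  plasmid_genes <- sum(st$plasmid_fragments$n_genes)
  ice_genes <- sum(st$ice$n_genes)
  cargo_genes <- sum(st$composite$n_cargo_genes)

  spectrum <- tibble(k = seq_len(n), clusters = 0L)
  spectrum$clusters[n] <- config$core_genes + length(base$elements)
  for (sz in shell_sizes) spectrum$clusters[sz] <- spectrum$clusters[sz] + 1L
  spectrum$clusters[1] <- spectrum$clusters[1] +
    (n * config$orfans_per_genome - n_disrupted) +
    hgt_genes + plasmid_genes + ice_genes + cargo_genes

  elements_tbl <- purrr::map_dfr(base$elements, function(el) {
    tibble(name = el$name, length = nchar(el$sequence), ir = el$ir,
           ir_length = nchar(el$ir), sequence = el$sequence,
           tp_start = el$tp_start, tp_end = el$tp_end,
           product = el$product, translation = el$translation)
  })
  expected_copies <- st$is_copies |>
    count(.data$element, .data$genome, name = "copies")

  list(
    seed = config$seed,
    memberships = memberships,
    expected_spectrum = spectrum,
    expected_pan = sum(spectrum$clusters),
    expected_core = spectrum$clusters[n],
    expected_orfans = spectrum$clusters[1],
    is_elements = elements_tbl,
    is_copies = st$is_copies,
    expected_census = expected_copies,
    disruptions = st$disruptions,
    composite = st$composite,
    hgt_blocks = st$hgt_blocks,
    plasmid_fragments = st$plasmid_fragments,
    plasmid_length = config$plasmid_spec$length,
    expected_plasmid_coverage = sum(config$plasmid_spec$fragment_lengths) /
      config$plasmid_spec$length,
    ice = st$ice,
    orfan_pool = st$orfan_pool
  )
}

#' @export
print.mobilome_sim <- function(x, ...) {
  cat(sprintf("<mobilome_sim> %d recipient genomes + %d partner(s); seed %d\n",
              length(x$genomes), length(x$partners), x$config$seed))
  cat(sprintf("  planted: %d IS copies, %d composite, %d HGT blocks, %d plasmid fragments, %d island(s)\n",
              nrow(x$ledger$is_copies), nrow(x$ledger$composite),
              nrow(x$ledger$hgt_blocks), nrow(x$ledger$plasmid_fragments),
              nrow(x$ledger$ice)))
  invisible(x)
}

#' Serialize a truth ledger to JSON
#' @param ledger the `ledger` element of a [simulate_genome_set()] result.
#' @param path output path.
#' @export
write_truth_ledger <- function(ledger, path) {
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a truth ledger back from JSON
#' @param path JSON file from [write_truth_ledger()].
#' @export
read_truth_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(x)) if (is.data.frame(x[[nm]])) x[[nm]] <- as_tibble(x[[nm]])
  x
}
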