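# Genome containers and GenBank/FASTA/GFF3 I/O.
#
# Internal convention: 1-based inclusive coordinates on the forward strand.
# Features spanning the origin of a circular replicon are stored unwrapped,
# with end > replicon length and wraps = TRUE; interval arithmetic reduces
# modulo the replicon length.

FEATURE_COLS <- c("locus_tag", "kind", "start", "end", "strand",
                  "product", "translation", "wraps")

#' Build a feature table
#'
#' @param locus_tag,kind,start,end,strand,product,translation,wraps vectors
#'   describing annotated features; `kind` is one of CDS/rRNA/tRNA/other,
#'   coordinates are 1-based inclusive.
#' @return a tibble with one row per feature, sorted by start.
#' @export
feature_table <- function(locus_tag = character(), kind = character(),
                          start = integer(), end = integer(),
                          strand = character(), product = character(),
                          translation = character(), wraps = FALSE) {
  tb <- tibble(
    locus_tag = unname(as.character(locus_tag)), kind = unname(as.character(kind)),
    start = unname(as.integer(start)), end = unname(as.integer(end)),
    strand = unname(as.character(strand)), product = unname(as.character(product)),
    translation = unname(as.character(translation)),
    wraps = rep_len(unname(as.logical(wraps)), length(locus_tag))
  )
  arrange(tb, .data$start)
}

#' Construct a replicon
#'
#' @param replicon_id accession or synthetic identifier.
#' @param sequence DNA string over \{A,C,G,T,N\}.
#' @param topology "circular" or "linear".
#' @param features a [feature_table()].
#' @param is_chromosome flag marking the chromosome of a genome.
#' @export
replicon <- function(replicon_id, sequence, topology = c("circular", "linear"),
                     features = feature_table(), is_chromosome = FALSE) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) abort("replicon sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) abort("replicon sequence has non-ACGTN characters")
  x <- structure(
    list(replicon_id = replicon_id, sequence = sequence, topology = topology,
         features = arrange(features, .data$start), is_chromosome = is_chromosome),
    class = "replicon"
  )
  validate_replicon(x)
  x
}

validate_replicon <- function(x) {
  n <- nchar(x$sequence)
  f <- x$features
  if (nrow(f) == 0L) return(invisible(x))
  bad <- f$start < 1L | f$start > f$end |
    (!f$wraps & f$end > n) | (f$wraps & (x$topology != "circular" | f$end <= n))
  if (any(bad)) {
    abort(paste0("invalid feature coordinates in ", x$replicon_id, ": ",
                 paste(f$locus_tag[bad], collapse = ", ")))
  }
  cds <- f$kind == "CDS" & !is.na(f$translation) & nchar(f$translation) > 0
  badlen <- cds & (nchar(f$translation) * 3L > (f$end - f$start + 1L) + 3L)
  if (any(badlen)) {
    abort(paste0("translation longer than CDS in ", x$replicon_id, ": ",
                 paste(f$locus_tag[badlen], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s, %d features%s\n", x$replicon_id,
              format(nchar(x$sequence), big.mark = ","), x$topology,
              nrow(x$features), if (x$is_chromosome) " [chromosome]" else ""))
  invisible(x)
}

#' Construct a genome
#'
#' @param strain strain name.
#' @param species_label species tag used by the HGT species guard.
#' @param replicons list of [replicon()]; exactly one flagged chromosome
#'   (defaults to the longest when none is flagged).
#' @param ori_offset origin offset in bp; 0 after [normalize_to_ori()].
#' @export
genome <- function(strain, species_label, replicons, ori_offset = NA_integer_) {
  if (!length(replicons)) abort("genome needs at least one replicon")
  chrom <- vapply(replicons, function(r) isTRUE(r$is_chromosome), logical(1))
  if (!any(chrom)) {
    i <- which.max(vapply(replicons, function(r) nchar(r$sequence), numeric(1)))
    replicons[[i]]$is_chromosome <- TRUE
  } else if (sum(chrom) > 1L) {
    abort("genome must have exactly one chromosome replicon")
  }
  names(replicons) <- vapply(replicons, `[[`, "", "replicon_id")
  structure(list(strain = strain, species_label = species_label,
                 replicons = replicons, ori_offset = ori_offset),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s (%s): %d replicon(s), %s bp total\n", x$strain,
              x$species_label, length(x$replicons),
              format(sum(vapply(x$replicons, function(r) nchar(r$sequence), numeric(1))),
                     big.mark = ",")))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' Chromosome of a genome
#' @param genome a [genome()].
#' @export
chromosome <- function(genome) {
  i <- which(vapply(genome$replicons, function(r) isTRUE(r$is_chromosome), logical(1)))
  genome$replicons[[i]]
}

#' All features of a genome as a tibble
#'
#' @param genomes a [genome()] or list of genomes.
#' @return tibble with genome, replicon_id and the feature columns.
#' @export
genes <- function(genomes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  out <- purrr::map_dfr(genomes, function(g) {
    purrr::map_dfr(g$replicons, function(r) {
      if (nrow(r$features) == 0L) return(NULL)
      mutate(r$features, genome = g$strain, replicon_id = r$replicon_id,
             .before = 1L)
    })
  })
  if (!nrow(out)) {
    out <- mutate(feature_table(), genome = character(), replicon_id = character(),
                  .before = 1L)
  }
  out
}

#' All translated proteins of one or more genomes
#' @inheritParams genes
#' @return tibble (genome, locus_tag, translation, length); CDS without a
#'   translation are dropped with a warning count.
#' @export
proteins <- function(genomes) {
  g <- genes(genomes)
  cds <- filter(g, .data$kind == "CDS")
  miss <- is.na(cds$translation) | nchar(cds$translation) == 0L
  if (any(miss)) warn(sprintf("%d CDS without translation skipped", sum(miss)))
  cds |>
    filter(!miss) |>
    transmute(genome = .data$genome, locus_tag = .data$locus_tag,
              translation = .data$translation,
              length = nchar(.data$translation))
}

# ---------------------------------------------------------------------------
# GenBank flat file I/O

parse_gb_location <- function(loc, line_no) {
  wraps <- FALSE
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(rng) == 2L && rng[[2]][1] == 1L && rng[[1]][2] >= rng[[1]][1]) {
      # origin-spanning join(a..N,1..b): unwrap
      wraps <- TRUE
      return(list(start = rng[[1]][1], end = NA_integer_, wrap_tail = rng[[2]][2],
                  wrap_head_end = rng[[1]][2], strand = strand, wraps = wraps))
    }
    # plain multi-exon join: span it
    s <- min(vapply(rng, min, 0)); e <- max(vapply(rng, max, 0))
    return(list(start = s, end = e, strand = strand, wraps = FALSE))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 3L) {
    return(list(start = as.integer(m[2]), end = as.integer(m[3]),
                strand = strand, wraps = FALSE))
  }
  if (grepl("^\\d+$", loc)) {
    p <- as.integer(loc)
    return(list(start = p, end = p, strand = strand, wraps = FALSE))
  }
  abort(sprintf("cannot parse GenBank location '%s' (line %d)", loc, line_no))
}

parse_genbank_record <- function(lines, offset = 0L) {
  locus <- lines[1]
  if (!startsWith(locus, "LOCUS")) {
    abort(sprintf("malformed GenBank record: expected LOCUS at line %d", offset + 1L))
  }
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  replicon_id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  feat_i <- which(startsWith(lines, "FEATURES"))
  orig_i <- which(startsWith(lines, "ORIGIN"))
  if (!length(orig_i)) abort(sprintf("record %s has no ORIGIN section", replicon_id))
  seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(sequence)

  feats <- feature_table()
  if (length(feat_i)) {
    fl <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    # group lines into features: a new feature starts with a key in column 6
    starts <- which(grepl("^ {5}\\S", fl))
    rows <- list()
    for (j in seq_along(starts)) {
      a <- starts[j]
      b <- if (j < length(starts)) starts[j + 1L] - 1L else length(fl)
      block <- fl[a:b]
      key <- trimws(substr(block[1], 1, 20))
      # location may continue over lines until the first qualifier
      qual_start <- which(grepl("^ {21}/", block))
      loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
      loc <- gsub("\\s", "", paste(trimws(substr(block[1:loc_end], 21, 1e4)), collapse = ""))
      quals <- character()
      if (length(qual_start)) {
        qlines <- block[qual_start[1]:length(block)]
        qidx <- which(grepl("^ {21}/", qlines))
        for (qi in seq_along(qidx)) {
          qa <- qidx[qi]
          qb <- if (qi < length(qidx)) qidx[qi + 1L] - 1L else length(qlines)
          qtxt <- paste(trimws(qlines[qa:qb]), collapse = if (grepl("^/translation", trimws(qlines[qa]))) "" else " ")
          quals <- c(quals, qtxt)
        }
      }
      get_q <- function(name) {
        hit <- quals[startsWith(quals, paste0("/", name, "="))]
        if (!length(hit)) return(NA_character_)
        v <- sub(paste0("^/", name, "="), "", hit[1])
        gsub("^\"|\"$", "", v)
      }
      if (!key %in% c("CDS", "rRNA", "tRNA", "gene", "misc_feature", "mobile_element",
                      "repeat_region", "ncRNA", "tmRNA")) next
      if (key == "gene") next  # gene wrappers duplicate CDS/rRNA/tRNA entries
      lp <- parse_gb_location(loc, offset + feat_i[1] + a)
      start <- lp$start
      end <- if (isTRUE(lp$wraps)) {
        if (lp$wrap_head_end != n) {
          abort(sprintf("origin-spanning feature in %s does not reach sequence end", replicon_id))
        }
        n + lp$wrap_tail
      } else lp$end
      if (!isTRUE(lp$wraps) && (end > n || start < 1L)) {
        abort(sprintf("feature coordinates %d..%d exceed sequence length %d in %s",
                      start, end, n, replicon_id))
      }
      kind <- if (key %in% c("CDS", "rRNA", "tRNA")) key else "other"
      rows[[length(rows) + 1L]] <- tibble(
        locus_tag = get_q("locus_tag") %||% NA_character_,
        kind = kind, start = start, end = end, strand = lp$strand,
        product = get_q("product"),
        translation = if (kind == "CDS") get_q("translation") else NA_character_,
        wraps = isTRUE(lp$wraps)
      )
    }
    if (length(rows)) feats <- arrange(bind_rows(rows), .data$start)
  }
  replicon(replicon_id, sequence, topology, feats)
}

#' Read a GenBank flat file
#'
#' Parses one or more records (chromosome plus optional plasmids) into a
#' [genome()]. CDS/rRNA/tRNA features are kept; `gene` wrappers are dropped.
#' Origin-spanning `join(a..N,1..b)` features are unwrapped (end > length,
#' wrap flag set).
#'
#' @param path file path.
#' @param strain,species_label labels for the resulting genome (default from
#'   the first record id).
#' @export
read_genbank <- function(path, strain = NULL, species_label = "unknown") {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- which(startsWith(lines, "LOCUS"))
  if (!length(rec_starts)) abort(sprintf("%s: no LOCUS line found (line 1)", path))
  rec_ends <- which(startsWith(lines, "//"))
  reps <- purrr::map2(rec_starts, rec_ends, function(a, b) {
    parse_genbank_record(lines[a:b], offset = a - 1L)
  })
  genome(strain %||% reps[[1]]$replicon_id, species_label, reps)
}

#' Read genome sequence(s) from FASTA (no annotations)
#' @inheritParams read_genbank
#' @param topology_hint topology assigned to every record.
#' @export
read_fasta_genome <- function(path, topology_hint = c("circular", "linear"),
                              strain = NULL, species_label = "unknown") {
  topology_hint <- match.arg(topology_hint)
  ss <- Biostrings::readDNAStringSet(path)
  reps <- purrr::map(seq_along(ss), function(i) {
    replicon(sub("\\s.*$", "", names(ss)[i]), as.character(ss[[i]]), topology_hint)
  })
  genome(strain %||% reps[[1]]$replicon_id, species_label, reps)
}

#' Read a genome from GenBank or FASTA, by content sniffing
#' @inheritParams read_fasta_genome
#' @export
read_genome <- function(path, topology_hint = c("circular", "linear"),
                        strain = NULL, species_label = "unknown") {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    read_fasta_genome(path, topology_hint, strain, species_label)
  } else {
    read_genbank(path, strain, species_label)
  }
}

format_gb_location <- function(start, end, strand, wraps, n) {
  loc <- if (wraps) sprintf("join(%d..%d,1..%d)", start, n, end - n)
         else sprintf("%d..%d", start, end)
  if (strand == "-") loc <- sprintf("complement(%s)", loc) else loc
}

wrap_qualifier <- function(text, width = 58L) {
  out <- character()
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1, width))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, text)
}

#' Write a genome as a GenBank flat file
#' @param genome a [genome()].
#' @param path output path.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in genome$replicons) {
    n <- nchar(r$sequence)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT", r$replicon_id, n,
                       r$topology), con)
    writeLines(sprintf("DEFINITION  %s %s.", genome$species_label, genome$strain), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    writeLines(sprintf("                     /organism=\"%s\"", genome$species_label), con)
    writeLines(sprintf("                     /strain=\"%s\"", genome$strain), con)
    if (nrow(r$features)) {
      for (i in seq_len(nrow(r$features))) {
        f <- r$features[i, ]
        key <- if (f$kind %in% c("CDS", "rRNA", "tRNA")) f$kind else "misc_feature"
        writeLines(sprintf("     %-15s %s", key,
                           format_gb_location(f$start, f$end, f$strand, f$wraps, n)), con)
        if (!is.na(f$locus_tag)) {
          writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag), con)
        }
        if (!is.na(f$product)) {
          q <- wrap_qualifier(sprintf("/product=\"%s\"", f$product))
          writeLines(paste0("                     ", q), con)
        }
        if (f$kind == "CDS" && !is.na(f$translation) && nchar(f$translation)) {
          q <- wrap_qualifier(sprintf("/translation=\"%s\"", f$translation))
          writeLines(paste0("                     ", q), con)
        }
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, n, by = 60L)
    for (p in pos) {
      chunk <- substr(r$sequence, p, min(p + 59L, n))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write genome sequences as FASTA
#' @inheritParams write_genbank
#' @export
write_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genome$replicons, `[[`, "", "sequence"))
  names(seqs) <- vapply(genome$replicons, `[[`, "", "replicon_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write genome annotations as GFF3
#' @inheritParams write_genbank
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (r in genome$replicons) {
    n <- nchar(r$sequence)
    writeLines(sprintf("##sequence-region %s 1 %d", r$replicon_id, n), con)
    if (!nrow(r$features)) next
    for (i in seq_len(nrow(r$features))) {
      f <- r$features[i, ]
      type <- switch(f$kind, CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA", "region")
      writeLines(sprintf("%s\tmobilomeR\t%s\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
                         r$replicon_id, type, f$start, min(f$end, n), f$strand,
                         f$locus_tag, gsub("[;=\t]", " ", f$product %||% "")), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# ori normalization

DNAA_KEYWORD <- "chromosomal replication initiator protein dnaa"

#' Rotate a circular chromosome so position 1 sits upstream of dnaA
#'
#' The replication origin convention places coordinate 1 at the first base of
#' the intergenic region immediately upstream of the dnaA gene (identified by
#' its annotation keyword, case-insensitively). Pairwise circular distances
#' between features are preserved.
#'
#' @param genome a [genome()] whose chromosome carries exactly one dnaA CDS.
#' @return the rotated genome with `ori_offset = 0`.
#' @export
normalize_to_ori <- function(genome) {
  chrom <- chromosome(genome)
  if (chrom$topology != "circular") abort("ori normalization requires a circular chromosome")
  f <- chrom$features
  hits <- which(f$kind == "CDS" & grepl(DNAA_KEYWORD, tolower(f$product %||% "")))
  if (length(hits) != 1L) {
    abort(paste0("expected exactly one dnaA candidate, found ", length(hits),
                 if (length(hits)) paste0(": ", paste(f$locus_tag[hits], collapse = ", ")) else ""))
  }
  n <- nchar(chrom$sequence)
  d <- f[hits, ]
  origin <- if (d$strand == "+") {
    prev_ends <- f$end[-hits][f$end[-hits] < d$start]
    u <- if (length(prev_ends)) max(prev_ends) else {
      # upstream gene wraps around the origin
      mx <- max(f$end[-hits]) ; if (mx > n) mx - n else mx
    }
    mod1(u + 1L, n)
  } else {
    mod1(d$end + 1L, n)
  }
  rotate_genome(genome, origin)
}

#' Rotate the chromosome of a genome so `origin` becomes position 1
#' @param genome a [genome()].
#' @param origin 1-based position that becomes the new coordinate 1.
#' @export
rotate_genome <- function(genome, origin) {
  chrom_i <- which(vapply(genome$replicons, function(r) isTRUE(r$is_chromosome), logical(1)))
  r <- genome$replicons[[chrom_i]]
  n <- nchar(r$sequence)
  origin <- mod1(origin, n)
  if (origin != 1L) {
    r$sequence <- paste0(substr(r$sequence, origin, n), substr(r$sequence, 1L, origin - 1L))
    f <- r$features
    if (nrow(f)) {
      width <- f$end - f$start
      f$start <- mod1(f$start - origin + 1L, n)
      f$end <- f$start + width
      f$wraps <- f$end > n
      r$features <- arrange(f, .data$start)
    }
  }
  genome$replicons[[chrom_i]] <- r
  genome$ori_offset <- 0L
  genome
}

# ---------------------------------------------------------------------------
# GC content and product classification

#' G+C content of a replicon or DNA string
#'
#' @param x a [replicon()] or DNA character string.
#' @return percentage 100 * (G+C)/(A+C+G+T); N bases are excluded from both
#'   numerator and denominator.
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "replicon")) x$sequence else toupper(x)
  counts <- table(factor(strsplit(s, "", fixed = TRUE)[[1]], levels = c(DNA_ALPHABET, "N")))
  denom <- sum(counts[DNA_ALPHABET])
  if (denom == 0L) abort("gc_content undefined: no A/C/G/T bases")
  100 * sum(counts[c("G", "C")]) / denom
}

.category_env <- new.env(parent = emptyenv())

#' Load (or retrieve) the functional-category keyword table
#'
#' A versioned tab-separated resource (category, pattern) shipped with the
#' package; patterns are matched case-insensitively as substrings, first
#' match in table order wins.
#'
#' @param path optional path to an alternative table.
#' @export
functional_keyword_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.category_env$table)) return(.category_env$table)
    path <- system.file("extdata", "functional_categories.tsv", package = "mobilomeR")
  }
  tb <- readr::read_tsv(path, col_types = "cc", comment = "#")
  if (is.null(.category_env$table)) .category_env$table <- tb
  tb
}

HYPOTHETICAL_MARKERS <- c("hypothetical", "uncharacterized", "uncharacterised",
                          "unknown function", "duf")

#' Classify gene products into coarse functional categories
#'
#' Deterministic keyword lookup: the first matching pattern of the shipped
#' table assigns the category; unmatched products fall back to
#' "hypothetical" when they carry hypothetical/uncharacterized markers, to
#' "putative" when they are merely qualified as putative, else to
#' "miscellaneous".
#'
#' @param product character vector of product annotation strings.
#' @param table keyword table as from [functional_keyword_table()].
#' @return character vector of category names.
#' @export
classify_product <- function(product, table = functional_keyword_table()) {
  lp <- tolower(product %||% "")
  lp[is.na(lp)] <- ""
  out <- rep(NA_character_, length(lp))
  for (i in seq_len(nrow(table))) {
    hit <- is.na(out) & grepl(table$pattern[i], lp, fixed = TRUE)
    out[hit] <- table$category[i]
  }
  hyp <- is.na(out) & Reduce(`|`, lapply(HYPOTHETICAL_MARKERS, function(m) grepl(m, lp, fixed = TRUE)))
  out[hyp] <- "hypothetical"
  put <- is.na(out) & grepl("putative", lp, fixed = TRUE)
  out[put] <- "putative"
  out[is.na(out)] <- "miscellaneous"
  out
}
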