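#' @importFrom rlang .data abort warn %||%
#' @importFrom stats setNames runif
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# globals used in data-masking verbs and data.table expressions
utils::globalVariables(c(".", "diag", "pos", "cluster", "kmer", "qpos"))
.datatable.aware <- TRUE

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x a single DNA character string over \{A,C,G,T,N\}.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

#' @keywords internal
seq_as_int <- function(x) utf8ToInt(x)

# substring helper returning the characters of s in [start, end] (1-based inclusive)
subseq_chr <- function(s, start, end) substr(s, start, end)

# modular 1-based coordinate on a circle of length n
mod1 <- function(x, n) ((x - 1L) %% n) + 1L

# extract [start, end] from a possibly-circular sequence, wrapping if end > n
extract_circular <- function(s, start, end) {
  n <- nchar(s)
  start <- mod1(start, n)
  if (end <= n && start <= end) return(substr(s, start, end))
  # wraps: from start to n then from 1
  w <- end - n
  if (start > n) stop("invalid extraction window")
  paste0(substr(s, start, n), substr(s, 1L, mod1(w, n)))
}

# --- deterministic per-subsystem RNG streams -------------------------------
# Sub-streams are derived arithmetically from the master seed so that changing
# one simulation stage does not reshuffle the draws of another.
stream_seed <- function(seed, stream) {
  offs <- c(sequence = 11L, placement = 211L, mutation = 3011L,
            ordering = 40009L, hgt = 500009L, ice = 611953L,
            plasmid = 700001L, is = 811001L, partner = 900047L,
            plasmid_frag = 911117L)
  o <- offs[[stream]]
  as.integer((as.numeric(seed) * 2654435761 + o) %% 2147483647)
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_ALPHABET, n, replace = TRUE, prob = p), collapse = "")
}

CODONS <- {
  b <- c("T", "C", "A", "G")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cod
}
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

.genetic_code <- local({
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
})

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  cods <- substring(dna, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- .genetic_code[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# random ORF: ATG + n_codons sense codons + stop; length in nt = 3*(n_codons+2)
random_orf <- function(n_codons) {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = ""), "TGA")
}

# substitute DNA positions at `rate`, avoiding the creation of internal stop
# codons and preserving start/stop (used for within-cluster divergence)
mutate_cds <- function(dna, rate) {
  if (rate <= 0) return(dna)
  n <- nchar(dna)
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  k <- max(0L, stats::rbinom(1L, n - 6L, rate))
  if (k == 0L) return(dna)
  pos <- sample(4:(n - 3L), k)
  for (p in pos) {
    old <- chars[p]
    chars[p] <- sample(setdiff(DNA_ALPHABET, old), 1L)
    cstart <- p - ((p - 1L) %% 3L)
    codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
    if (codon %in% STOP_CODONS) chars[p] <- old
  }
  paste(chars, collapse = "")
}

# substitute plain DNA at `rate` (no codon constraints)
mutate_dna <- function(dna, rate) {
  if (rate <= 0) return(dna)
  n <- nchar(dna)
  k <- max(0L, stats::rbinom(1L, n, rate))
  if (k == 0L) return(dna)
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  pos <- sample.int(n, k)
  chars[pos] <- vapply(chars[pos], function(old) sample(setdiff(DNA_ALPHABET, old), 1L), "")
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}
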