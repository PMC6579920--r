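# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's seed-and-extend / greedy code
# paths: plain dynamic programming and exhaustive scans at small n.

# Smith-Waterman local alignment with affine gaps (Gotoh), column-wise and
# exactly vectorized: within a column, a gap following a gap never beats
# extending the original gap, so the vertical-gap state is a running
# maximum over earlier non-gap candidates. Returns best score and end.
sw_best_end <- function(q, s, match = 1, mismatch = -2, gap_open = 5,
                        gap_extend = 2) {
  qi <- utf8ToInt(q); si <- utf8ToInt(s)
  n <- length(qi); m <- length(si)
  idx <- seq_len(n)
  H <- numeric(n); E <- rep(-Inf, n)
  best <- 0; best_q <- 0L; best_s <- 0L
  for (j in seq_len(m)) {
    sub <- ifelse(qi == si[j], match, mismatch)
    Hdiag <- c(0, H[-n])
    E <- pmax(H - gap_open - gap_extend, E - gap_extend)
    C <- pmax(Hdiag + sub, E, 0)
    run <- cummax(C + gap_extend * idx)
    F <- c(-Inf, run[-n]) - gap_open - gap_extend * idx
    H <- pmax(C, F)
    w <- which.max(H)
    if (H[w] > best) { best <- H[w]; best_q <- w; best_s <- j }
  }
  list(score = best, q_end = best_q, s_end = best_s)
}

# full local alignment interval via forward pass + reverse pass
sw_oracle <- function(q, s, ...) {
  fwd <- sw_best_end(q, s, ...)
  if (fwd$score <= 0) return(NULL)
  qr <- paste(rev(strsplit(substr(q, 1, fwd$q_end), "")[[1]]), collapse = "")
  sr <- paste(rev(strsplit(substr(s, 1, fwd$s_end), "")[[1]]), collapse = "")
  bwd <- sw_best_end(qr, sr, ...)
  list(score = fwd$score,
       q_start = fwd$q_end - bwd$q_end + 1L, q_end = fwd$q_end,
       s_start = fwd$s_end - bwd$s_end + 1L, s_end = fwd$s_end)
}

# ends-free global alignment score oracle for proteins (BLOSUM62)
nw_overlap_oracle <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  ai <- strsplit(a, "")[[1]]; bi <- strsplit(b, "")[[1]]
  n <- length(ai); m <- length(bi)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  # free leading gaps: first row/col zero
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
    H[i, j] <- max(H[i - 1, j - 1] + B[ai[i - 1], bi[j - 1]], E[i, j], F[i, j])
  }
  # free trailing gaps: best over last row/column
  max(H[n + 1, ], H[, m + 1])
}

# exhaustive inverted-repeat scan
ir_oracle <- function(sequence, arm_min, arm_max, max_mismatch, window) {
  n <- nchar(sequence)
  out <- list()
  for (L in arm_min:min(arm_max, floor(n / 2))) {
    for (i in seq_len(min(window, n - L + 1L))) {
      left <- substr(sequence, i, i + L - 1L)
      rc_left <- revcomp(left)
      for (j in seq(max(n - window + 1L, L), n)) {
        rs <- j - L + 1L
        if (rs <= i + L - 1L) next
        right <- substr(sequence, rs, j)
        mm <- sum(utf8ToInt(right) != utf8ToInt(rc_left))
        if (mm <= max_mismatch) {
          out[[length(out) + 1L]] <- c(i, i + L - 1L, rs, j, mm, L)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# brute-force interval merging: union of blocks closed under gaps <= max_gap
merge_oracle <- function(starts, ends, max_gap) {
  n <- max(ends) + 1L
  covered <- rep(FALSE, n)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  # close gaps
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  for (i in seq_along(r$values)) {
    if (!r$values[i] && i > 1 && i < length(r$values) && r$lengths[i] <= max_gap) {
      covered[(pos[i] - r$lengths[i] + 1L):pos[i]] <- TRUE
    }
  }
  r <- rle(covered)
  ends2 <- cumsum(r$lengths)
  starts2 <- ends2 - r$lengths + 1L
  cbind(starts2[r$values], ends2[r$values])
}

# greedy clustering replay from a precomputed all-pairs threshold graph.
# The pairwise metric is the shared identity/coverage definition (itself
# checked against a hand-rolled DP oracle in the alignment tests); what this
# oracle does independently is compute the FULL threshold matrix with no
# prefilters and replay the greedy assignment from it.
cluster_oracle <- function(prot, min_identity = 0.60, min_coverage = 0.75) {
  prot <- prot[order(-prot$length, prot$locus_tag, prot$genome), ]
  n <- nrow(prot)
  pass <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    r <- mobilomeR:::aa_identity_coverage_many(prot$translation[i],
                                               prot$translation)
    pass[i, ] <- r$identity >= min_identity & r$coverage >= min_coverage
    pass[i, i] <- TRUE
  }
  assign <- integer(n)
  centroids <- integer(0)
  for (i in seq_len(n)) {
    hit <- centroids[pass[i, centroids]]
    if (length(hit)) {
      assign[i] <- hit[1]
    } else {
      centroids <- c(centroids, i)
      assign[i] <- i
    }
  }
  split(paste(prot$genome, prot$locus_tag), assign)
}

# independent permutation enumerator for the ordering oracle
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (i in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(p, n, after = i)
  }
  out
}
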