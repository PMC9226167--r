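# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
NT4 <- c("A", "C", "G", "T")

rand_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")
rand_dna <- function(len) paste(sample(NT4, len, TRUE), collapse = "")

# i.i.d. substitution used to make diverged homologs for closed-loop tests
mutate_protein_for_test <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(x) sample(setdiff(AA20, x), 1), "")
  paste(ch, collapse = "")
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# exhaustive affine-gap Smith-Waterman (three-state DP), independent of the
# alignment engine used by the implementation
sw_oracle <- function(a, b, mat = blosum62, gap_open = 11,
                      gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# brute-force per-position horizontal coverage
coverage_oracle <- function(starts, ends, contig_len) {
  covered <- logical(contig_len)
  for (i in seq_along(starts)) {
    covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  mean(covered)
}

# brute-force sliding-window Hamming protospacer search over both strands
protospacer_oracle <- function(spacer, contig_seq, max_mm) {
  hits <- list()
  L <- nchar(contig_seq)
  w <- nchar(spacer)
  contig_chars <- strsplit(contig_seq, "")[[1]]
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else
      viromeprofiler::revcomp(spacer)
    pat_chars <- strsplit(pat, "")[[1]]
    if (w > L) next
    for (s in 1:(L - w + 1)) {
      mm <- sum(contig_chars[s:(s + w - 1)] != pat_chars)
      if (mm <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s - 1L, end = s + w - 1L, strand = strand,
          mismatches = mm
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

# adjusted Rand index between two label vectors
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# exact upper hypergeometric tail by explicit summation
hyper_tail_oracle <- function(shared, size_a, size_b, universe) {
  ks <- shared:min(size_a, size_b)
  sum(vapply(ks, function(k) {
    choose(size_a, k) * choose(universe - size_a, size_b - k) /
      choose(universe, size_b)
  }, numeric(1)))
}

# a small planted PC membership: n_groups groups of group_size contigs,
# each carrying `carry` of the group's `pool` PCs (sampled), no overlap
# between groups
planted_pc_membership <- function(n_groups, group_size, pool = 20,
                                  carry = 16) {
  rows <- list()
  for (g in seq_len(n_groups)) {
    pcs <- paste0("PC_g", g, "_", seq_len(pool))
    for (i in seq_len(group_size)) {
      cid <- sprintf("ctg_g%d_%02d", g, i)
      mine <- sample(pcs, carry)
      rows[[length(rows) + 1]] <- data.frame(contig_id = cid,
                                             pc_id = mine)
    }
  }
  dplyr::as_tibble(do.call(rbind, rows))
}
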