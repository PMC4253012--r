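# Independent brute-force oracles used across the test files. These stay
# deliberately naive: straight loops over every candidate, no sharing of
# code with the implementation paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Enumerates every (start, unit_size) candidate, extends it maximally by
# direct motif comparison, drops motifs that are repetitions of shorter
# motifs, and applies the documented overlap-resolution order (longer span,
# then smaller unit, then leftmost). Returns a data frame of regions.
brute_str_regions <- function(sequence, min_repeats = 4L, unit_sizes = 2:6) {
  n <- nchar(sequence)
  cand <- list()
  for (u in unit_sizes) {
    for (s in seq_len(n - u * min_repeats + 1L)) {
      motif <- substr(sequence, s, s + u - 1L)
      is_power <- FALSE
      for (d in seq_len(u - 1L)) {
        if (u %% d == 0L && strrep(substr(motif, 1L, d), u / d) == motif) {
          is_power <- TRUE
          break
        }
      }
      if (is_power) next
      k <- 1L
      while (s + (k + 1L) * u - 1L <= n &&
             substr(sequence, s + k * u, s + (k + 1L) * u - 1L) == motif) {
        k <- k + 1L
      }
      if (k >= min_repeats) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = s, unit = u, copies = k, span = u * k, motif = motif)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), unit = integer(0),
                      copies = integer(0), span = integer(0),
                      motif = character(0)))
  }
  df <- do.call(rbind, cand)
  df <- df[order(-df$span, df$unit, df$start), ]
  sel <- df[0, ]
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- s + df$span[i] - 1L
    clash <- FALSE
    for (j in seq_len(nrow(sel))) {
      if (s <= sel$start[j] + sel$span[j] - 1L && e >= sel$start[j]) {
        clash <- TRUE
        break
      }
    }
    if (!clash) sel <- rbind(sel, df[i, ])
  }
  sel <- sel[order(sel$start), ]
  rownames(sel) <- NULL
  sel
}

structure_to_df <- function(structure) {
  if (length(structure$regions) == 0L) {
    return(data.frame(start = integer(0), unit = integer(0),
                      copies = integer(0), span = integer(0),
                      motif = character(0)))
  }
  do.call(rbind, lapply(structure$regions, function(r) {
    data.frame(start = r$start + 1L, unit = r$unit_size,
               copies = r$repeat_count,
               span = r$unit_size * r$repeat_count, motif = r$motif)
  }))
}

# Brute-force primer acceptance: for every reference offset (diagonal, both
# strands) the aligner would report the score-optimal clipped window under
# match +1 / mismatch -1; a diagonal is accepted iff that window satisfies
# length >= primer_length - max_deficit and identity >= min_identity.
brute_primer_accepted <- function(primer, reference,
                                  max_deficit = 10L, min_identity = 0.9) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  p_l <- nchar(primer)
  len_min <- max(1L, p_l - max_deficit)
  for (query in c(primer, revcomp(primer))) {
    q <- strsplit(query, "")[[1]]
    r <- strsplit(reference, "")[[1]]
    n <- length(r)
    for (o in (1L - p_l):n) {                   # query start offset on ref
      best <- NULL
      for (q1 in seq_len(p_l)) {
        for (q2 in seq(q1, p_l)) {
          r1 <- o + q1 - 1L; r2 <- o + q2 - 1L
          if (r1 < 1L || r2 > n) next
          L <- q2 - q1 + 1L
          matches <- sum(q[q1:q2] == r[r1:r2])
          score <- 2L * matches - L
          if (is.null(best) || score > best$score ||
              (score == best$score && L > best$len)) {
            best <- list(score = score, len = L, id = matches / L)
          }
        }
      }
      if (!is.null(best) && best$len >= len_min && best$len <= p_l + 10L &&
          best$id >= min_identity) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Step-by-step Weir-Cockerham (1984) variance components for one locus and
# two populations given explicit diploid genotype lists (each a 2-column
# matrix of allele labels). Scalar arithmetic only.
wc_theta_oracle <- function(geno1, geno2) {
  n1 <- nrow(geno1); n2 <- nrow(geno2)
  alleles <- unique(c(geno1, geno2))
  num <- 0; den <- 0
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  for (al in alleles) {
    p1 <- sum(geno1 == al) / (2 * n1)
    p2 <- sum(geno2 == al) / (2 * n2)
    h1 <- sum(apply(geno1, 1, function(g) g[1] != g[2] && al %in% g)) / n1
    h2 <- sum(apply(geno2, 1, function(g) g[1] != g[2] && al %in% g)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Two-population genotype dataset from explicit diploid allele matrices.
two_pop_dataset <- function(geno1, geno2, marker = "L1",
                            species = c("human", "human")) {
  n1 <- nrow(geno1); n2 <- nrow(geno2)
  samples <- data.frame(
    id = c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2))),
    population = c(rep("popA", n1), rep("popB", n2)),
    species = c(rep(species[1], n1), rep(species[2], n2)))
  calls <- data.frame(id = samples$id, marker = marker,
                      a1 = c(geno1[, 1], geno2[, 1]),
                      a2 = c(geno1[, 2], geno2[, 2]))
  genotype_dataset(samples, calls, "length")
}
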