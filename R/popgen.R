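#' Population-genetic statistics on both genotype representations
#'
#' Multi-locus pairwise Weir-Cockerham theta and allele-sharing distance
#' (D_PS) over populations, sample-size-corrected expected heterozygosity,
#' and the summary that quantifies how much fragment-length genotypes
#' inflate interspecies differentiation relative to repeat-number
#' genotypes. Alleles are treated as unordered categorical states
#' throughout, so every statistic is invariant to the within-species affine
#' length-repeat calibration.
#'
#' @name popgen
NULL

#' Sample-size-corrected expected heterozygosity
#'
#' \eqn{H_e = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} over `n` allele
#' copies with frequencies `p_i`; only non-missing genotypes contribute.
#'
#' @param counts Vector of allele counts (one entry per distinct allele).
#' @return `H_e` in `[0, 1]`.
#' @export
heterozygosity <- function(counts) {
  n <- sum(counts)
  .assert(n >= 2, "need at least 2 allele copies")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Per-marker, per-species heterozygosity of a dataset
#'
#' @param dataset A [genotype_dataset()].
#' @return Data frame with `marker`, `species`, `he`, `n` (allele copies).
#' @export
marker_heterozygosity <- function(dataset) {
  species_of <- stats::setNames(dataset$samples$species, dataset$samples$id)
  calls <- dataset$calls
  calls$species <- unname(species_of[calls$id])
  out <- expand.grid(marker = dataset$loci,
                     species = unique(calls$species),
                     stringsAsFactors = FALSE)
  out$he <- NA_real_
  out$n <- 0L
  for (k in seq_len(nrow(out))) {
    sub <- calls[calls$marker == out$marker[k] & calls$species == out$species[k], ]
    alleles <- c(sub$a1, sub$a2)
    alleles <- alleles[!is.na(alleles)]
    out$n[k] <- length(alleles)
    if (length(alleles) >= 2) out$he[k] <- heterozygosity(table(alleles))
  }
  out
}

# Per-(population, marker) allele counts, per-allele heterozygote counts and
# diploid sample sizes, for the populations meeting min_pop_size.
.pop_locus_stats <- function(dataset, min_pop_size) {
  pop_of <- stats::setNames(dataset$samples$population, dataset$samples$id)
  pop_sizes <- table(dataset$samples$population)
  pops <- names(pop_sizes)[pop_sizes >= min_pop_size]
  pops <- pops[order(match(pops, dataset$samples$population))]
  calls <- dataset$calls
  calls$population <- unname(pop_of[calls$id])
  calls <- calls[calls$population %in% pops & !is.na(calls$a1), ]
  key <- paste(calls$population, calls$marker, sep = "\r")
  cells <- split(seq_len(nrow(calls)), key)
  stats <- new.env(parent = emptyenv())
  for (nm in names(cells)) {
    idx <- cells[[nm]]
    a1 <- calls$a1[idx]; a2 <- calls$a2[idx]
    counts <- table(c(a1, a2))
    het <- a1 != a2
    hcount <- vapply(names(counts), function(al) {
      al <- as.numeric(al)
      sum(het & (a1 == al | a2 == al))
    }, numeric(1))
    assign(nm, list(counts = counts, het = hcount, n = length(a1)), envir = stats)
  }
  list(pops = pops, stats = stats,
       loci = dataset$loci,
       get = function(pop, marker) {
         nm <- paste(pop, marker, sep = "\r")
         if (exists(nm, envir = stats, inherits = FALSE)) get(nm, envir = stats) else NULL
       })
}

# Weir-Cockerham (1984) variance components for one locus and two
# populations; returns c(a, b+c... ) summed over alleles as c(num, den).
.wc_locus_pair <- function(s1, s2) {
  n1 <- s1$n; n2 <- s2$n
  if (n1 < 2 || n2 < 2) return(c(0, 0))
  alleles <- union(names(s1$counts), names(s2$counts))
  if (length(alleles) < 2) return(c(0, 0))
  c1 <- rep(0, length(alleles)); names(c1) <- alleles
  c2 <- c1; h1 <- c1; h2 <- c1
  c1[names(s1$counts)] <- as.numeric(s1$counts)
  c2[names(s2$counts)] <- as.numeric(s2$counts)
  h1[names(s1$het)] <- s1$het
  h2[names(s2$het)] <- s2$het
  r <- 2
  p1 <- c1 / (2 * n1); p2 <- c2 / (2 * n2)
  hp1 <- h1 / n1; hp2 <- h2 / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * hp1 + n2 * hp2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(sum(a), sum(a + b + cc))
}

#' Pairwise multi-locus Weir-Cockerham F_ST
#'
#' For every pair of populations with at least `min_pop_size` individuals,
#' the Weir-Cockerham (1984) theta is computed with alleles as categorical
#' states and the ratio-of-sums combination of variance components across
#' loci; loci monomorphic within a pair are skipped. Negative estimates are
#' reported as computed, not clamped.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_pop_size Minimum diploid sample size per population.
#' @return A [pairwise_matrix()] with `statistic = "FST"`.
#' @export
pairwise_fst <- function(dataset, min_pop_size = 5L) {
  pls <- .pop_locus_stats(dataset, min_pop_size)
  pops <- pls$pops
  .assert(length(pops) >= 2L, "fewer than 2 populations of size >= %d", min_pop_size)
  m <- matrix(0, length(pops), length(pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq((i + 1), length(pops))) {
      num <- 0; den <- 0
      for (loc in pls$loci) {
        s1 <- pls$get(pops[i], loc); s2 <- pls$get(pops[j], loc)
        if (is.null(s1) || is.null(s2)) next
        comp <- .wc_locus_pair(s1, s2)
        num <- num + comp[1]; den <- den + comp[2]
      }
      m[i, j] <- m[j, i] <- if (den > 0) num / den else NA_real_
    }
  }
  pairwise_matrix(pops, m, "FST", dataset$representation)
}

#' Pairwise allele-sharing distance D_PS
#'
#' \eqn{D_{PS} = 1 - \frac{1}{L}\sum_l \sum_a \min(p_{la}, q_{la})}: one
#' minus the proportion of shared alleles, averaged over the loci with data
#' in both populations, with `p`/`q` the population allele frequencies.
#'
#' @inheritParams pairwise_fst
#' @return A [pairwise_matrix()] with `statistic = "DPS"`.
#' @export
pairwise_dps <- function(dataset, min_pop_size = 5L) {
  pls <- .pop_locus_stats(dataset, min_pop_size)
  pops <- pls$pops
  .assert(length(pops) >= 2L, "fewer than 2 populations of size >= %d", min_pop_size)
  m <- matrix(0, length(pops), length(pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq((i + 1), length(pops))) {
      shared <- numeric(0)
      for (loc in pls$loci) {
        s1 <- pls$get(pops[i], loc); s2 <- pls$get(pops[j], loc)
        if (is.null(s1) || is.null(s2)) next
        p <- s1$counts / sum(s1$counts)
        q <- s2$counts / sum(s2$counts)
        common <- intersect(names(p), names(q))
        shared <- c(shared, sum(pmin(p[common], q[common])))
      }
      m[i, j] <- m[j, i] <- 1 - mean(shared)
    }
  }
  pairwise_matrix(pops, m, "DPS", dataset$representation)
}

#' Length-vs-repeat inflation summary
#'
#' Compares a pairwise statistic computed from fragment-length genotypes
#' with the same statistic computed from repeat-number genotypes. For every
#' interspecies pair the percent reduction
#' \eqn{100 (S_{len} - S_{rep}) / S_{len}} is reported (pairs with
#' \eqn{S_{len} \le 0} are skipped), together with the maximum, mean and SD
#' across interspecies pairs, the \eqn{R^2} between matched entries of the
#' two matrices, a Wilcoxon signed-rank test on the interspecies entries,
#' and — when geographic distances are supplied — the Spearman correlation
#' between each human population's mean reduction and its distance from the
#' reference origin.
#'
#' @param m_length,m_repeats [pairwise_matrix()] objects over identical
#'   population sets.
#' @param species_labels Named character vector mapping population to
#'   species.
#' @param distances Optional named numeric vector of distances (km) per
#'   human population.
#' @return List of class `inflation_summary`.
#' @export
inflation_summary <- function(m_length, m_repeats, species_labels,
                              distances = NULL) {
  pops <- m_length$populations
  .assert(identical(pops, m_repeats$populations), "mismatched population sets")
  .assert(all(pops %in% names(species_labels)), "species label missing for a population")
  sp <- species_labels[pops]
  ut <- which(upper.tri(m_length$values), arr.ind = TRUE)
  len <- m_length$values[ut]
  rep_ <- m_repeats$values[ut]
  inter <- sp[ut[, 1]] != sp[ut[, 2]]
  pairs <- data.frame(pop1 = pops[ut[, 1]], pop2 = pops[ut[, 2]],
                      value_length = len, value_repeats = rep_,
                      interspecies = inter)
  pairs$reduction_pct <- ifelse(pairs$value_length > 0,
                                100 * (pairs$value_length - pairs$value_repeats) /
                                  pairs$value_length, NA_real_)
  red <- pairs$reduction_pct[pairs$interspecies & !is.na(pairs$reduction_pct)]
  wil <- if (sum(inter) >= 1 && any(len[inter] != rep_[inter])) {
    suppressWarnings(
      stats::wilcox.test(len[inter], rep_[inter], paired = TRUE)$p.value)
  } else NA_real_
  human_pops <- pops[sp == "human"]
  per_human <- vapply(human_pops, function(hp) {
    k <- pairs$interspecies & (pairs$pop1 == hp | pairs$pop2 == hp)
    mean(pairs$reduction_pct[k], na.rm = TRUE)
  }, numeric(1))
  spearman_rho <- spearman_p <- NA_real_
  if (!is.null(distances)) {
    .assert(all(human_pops %in% names(distances)), "distance missing for a human population")
    d <- distances[human_pops]
    ct <- suppressWarnings(stats::cor.test(per_human, d, method = "spearman"))
    spearman_rho <- unname(ct$estimate)
    spearman_p <- ct$p.value
  }
  structure(list(
    statistic = m_length$statistic,
    pairs = pairs,
    max_reduction_pct = if (length(red)) max(red) else NA_real_,
    mean_reduction_pct = if (length(red)) mean(red) else NA_real_,
    sd_reduction_pct = if (length(red) > 1) stats::sd(red) else NA_real_,
    r_squared = if (stats::var(len) > 0 && stats::var(rep_) > 0)
      stats::cor(len, rep_)^2 else 1,
    wilcoxon_p = wil,
    per_human_population = data.frame(population = human_pops,
                                      mean_reduction_pct = unname(per_human)),
    spearman_rho = spearman_rho, spearman_p = spearman_p
  ), class = "inflation_summary")
}

#' @export
print.inflation_summary <- function(x, ...) {
  cat(sprintf("<inflation_summary: %s> interspecies reduction max %.2f%%, mean %.2f%% (SD %.2f), R^2 %.4f\n",
              x$statistic, x$max_reduction_pct, x$mean_reduction_pct,
              x$sd_reduction_pct, x$r_squared))
  invisible(x)
}
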