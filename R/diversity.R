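#' Per-marker variability profiles and group comparisons
#'
#' The nine per-marker, per-species variability measures used throughout
#' the diversity analyses: sample-size-corrected heterozygosity, number of
#' distinct alleles, variance / range / skewness of the repeat-number
#' distribution, mean PCR fragment length, and mean / maximum / minimum
#' repeat numbers. Distinct alleles and mean fragment length come from the
#' length representation; repeat-number measures from the repeat
#' representation. When one species has many more individuals than the
#' other, its measures are means over repeated subsamples matched to the
#' smaller species' size, which removes the sample-size confound from
#' interspecies contrasts.
#'
#' @name diversity
NULL

.moment_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  if (m2 == 0) return(NA_real_)
  m3 <- sum((x - m)^3) / n
  m3 / m2^1.5
}

.profile_vars <- c("he", "n_distinct_alleles", "variance_repeats",
                   "range_repeats", "skewness_repeats", "mean_pcr_length",
                   "mean_repeats", "max_repeats", "min_repeats")

.one_profile <- function(rep1, rep2, len1, len2) {
  ok <- !is.na(rep1)
  r <- c(rep1[ok], rep2[ok])
  l <- c(len1[ok], len2[ok])
  if (length(r) < 2) {
    return(stats::setNames(rep(NA_real_, length(.profile_vars)), .profile_vars))
  }
  c(he = heterozygosity(table(r)),
    n_distinct_alleles = length(unique(l)),
    variance_repeats = stats::var(r),
    range_repeats = max(r) - min(r),
    skewness_repeats = .moment_skewness(r),
    mean_pcr_length = mean(l),
    mean_repeats = mean(r),
    max_repeats = max(r),
    min_repeats = min(r))
}

#' Variability profile of every marker in both species
#'
#' @param dataset_repeats Repeat-representation [genotype_dataset()].
#' @param dataset_lengths Matching length-representation dataset (same
#'   individuals and loci).
#' @param resample List with `sets`, `size` and `seed`: a species with more
#'   than `size` individuals is profiled as the mean over `sets` random
#'   draws of `size` individuals without replacement; the other species
#'   uses all its individuals. `NULL` disables resampling.
#' @return Data frame with one row per marker x species and the nine
#'   variability measures; attribute `resampled` names the species the
#'   resampling path was applied to.
#' @export
variability_profile <- function(dataset_repeats, dataset_lengths,
                                resample = list(sets = 1000L, size = 84L, seed = 1L)) {
  .assert(identical(dataset_repeats$loci, dataset_lengths$loci),
          "datasets disagree on loci")
  .assert(identical(dataset_repeats$samples$id, dataset_lengths$samples$id),
          "datasets disagree on individuals")
  samples <- dataset_repeats$samples
  loci <- dataset_repeats$loci
  if (!is.null(resample) && !is.null(resample$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(resample$seed)
  }
  out <- list()
  resampled_species <- character(0)
  for (sp in unique(samples$species)) {
    ids <- samples$id[samples$species == sp]
    # align calls to a fixed individual order once per species
    rcalls <- dataset_repeats$calls[dataset_repeats$calls$id %in% ids, ]
    lcalls <- dataset_lengths$calls[dataset_lengths$calls$id %in% ids, ]
    per_marker <- lapply(loci, function(mk) {
      rsub <- rcalls[rcalls$marker == mk, ]
      lsub <- lcalls[lcalls$marker == mk, ]
      o <- match(ids, rsub$id)
      ol <- match(ids, lsub$id)
      list(r1 = rsub$a1[o], r2 = rsub$a2[o],
           l1 = lsub$a1[ol], l2 = lsub$a2[ol])
    })
    names(per_marker) <- loci
    use_resample <- !is.null(resample) && length(ids) > resample$size
    if (use_resample) {
      resampled_species <- c(resampled_species, sp)
      .assert(resample$size <= length(ids),
              "resample size exceeds the %s sample", sp)
      draws <- lapply(seq_len(resample$sets),
                      function(i) sample.int(length(ids), resample$size))
      vals <- lapply(loci, function(mk) {
        pm <- per_marker[[mk]]
        acc <- matrix(NA_real_, nrow = resample$sets, ncol = length(.profile_vars))
        for (d in seq_along(draws)) {
          k <- draws[[d]]
          acc[d, ] <- .one_profile(pm$r1[k], pm$r2[k], pm$l1[k], pm$l2[k])
        }
        colMeans(acc, na.rm = TRUE)
      })
    } else {
      vals <- lapply(loci, function(mk) {
        pm <- per_marker[[mk]]
        .one_profile(pm$r1, pm$r2, pm$l1, pm$l2)
      })
    }
    df <- as.data.frame(do.call(rbind, vals))
    names(df) <- .profile_vars
    df <- cbind(data.frame(marker = loci, species = sp), df)
    out[[sp]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "resampled") <- resampled_species
  res
}

.wide_profiles <- function(profiles) {
  sps <- unique(profiles$species)
  .assert(length(sps) == 2L, "profiles must cover exactly two species")
  a <- profiles[profiles$species == "chimpanzee", ]
  b <- profiles[profiles$species == "human", ]
  b <- b[match(a$marker, b$marker), ]
  list(chimp = a, human = b)
}

#' Group-wise comparison tables of variability profiles
#'
#' Produces, per (number of STR regions, repeat-unit size) group with at
#' least `min_group` markers:
#' \itemize{
#' \item interspecies contrasts — average relative difference (ARD: mean
#'   across markers of the chimpanzee value divided by the human value),
#'   its SD, and a Wilcoxon signed-rank P per variable;
#' \item heterozygosity correlations — Spearman rho and P of each variable
#'   against H_e, per species;
#' \item optional within-species contrast between two marker sets (e.g.
#'   outliers vs non-outliers) — relative difference in means (RDM: ratio
#'   of the group means) and a Wilcoxon rank-sum P per variable per
#'   species.
#' }
#'
#' @param profiles A [variability_profile()] result covering both species.
#' @param grouping Data frame with `marker`, `n_regions`, `unit_size`.
#' @param contrast Optional named logical vector (by marker) splitting each
#'   group into TRUE/FALSE subsets for the RDM contrast.
#' @param min_group Minimum markers per group (smaller groups are skipped).
#' @return List with data frames `ard`, `he_corr` and (when `contrast` is
#'   given) `rdm`.
#' @export
group_compare <- function(profiles, grouping, contrast = NULL, min_group = 5L) {
  w <- .wide_profiles(profiles)
  grp_of <- stats::setNames(paste(grouping$n_regions, "STR,", "unit", grouping$unit_size),
                            grouping$marker)
  groups <- grp_of[w$chimp$marker]
  vars <- .profile_vars
  ard <- list(); he_corr <- list(); rdm <- list()
  for (g in unique(groups[!is.na(groups)])) {
    k <- which(groups == g)
    if (length(k) < min_group) next
    for (v in vars) {
      cv <- w$chimp[[v]][k]; hv <- w$human[[v]][k]
      ok <- is.finite(cv) & is.finite(hv)
      ratios <- (cv / hv)[ok & hv != 0]
      p <- if (sum(ok) >= 2 && any(cv[ok] != hv[ok])) {
        stats::wilcox.test(cv[ok], hv[ok], paired = TRUE, exact = FALSE)$p.value
      } else NA_real_
      ard[[length(ard) + 1L]] <- data.frame(
        group = g, variable = v, n = sum(ok),
        ard = mean(ratios), sd = stats::sd(ratios), p = p)
      if (v != "he") {
        for (sp in c("chimpanzee", "human")) {
          x <- (if (sp == "chimpanzee") w$chimp else w$human)
          ok2 <- is.finite(x$he[k]) & is.finite(x[[v]][k])
          ct <- if (sum(ok2) >= 3) {
            suppressWarnings(stats::cor.test(x$he[k][ok2], x[[v]][k][ok2],
                                             method = "spearman"))
          } else NULL
          he_corr[[length(he_corr) + 1L]] <- data.frame(
            group = g, species = sp, variable = v, n = sum(ok2),
            rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
            p = if (is.null(ct)) NA_real_ else ct$p.value)
        }
      }
      if (!is.null(contrast)) {
        fl <- contrast[w$chimp$marker[k]]
        if (sum(fl, na.rm = TRUE) >= 2 && sum(!fl, na.rm = TRUE) >= 2) {
          for (sp in c("chimpanzee", "human")) {
            x <- (if (sp == "chimpanzee") w$chimp else w$human)[[v]][k]
            hi <- x[fl %in% TRUE]; lo <- x[fl %in% FALSE]
            hi <- hi[is.finite(hi)]; lo <- lo[is.finite(lo)]
            rdm[[length(rdm) + 1L]] <- data.frame(
              group = g, species = sp, variable = v,
              rdm = mean(hi) / mean(lo),
              p = stats::wilcox.test(hi, lo, exact = FALSE)$p.value)
          }
        }
      }
    }
  }
  out <- list(ard = do.call(rbind, ard), he_corr = do.call(rbind, he_corr))
  if (!is.null(contrast)) out$rdm <- do.call(rbind, rdm)
  out
}

#' Flag markers with outlying interspecies heterozygosity differences
#'
#' Computes `d = H_e(chimpanzee) - H_e(human)` per marker and its SD `s`
#' across the whole panel; markers with `d < -2s` (markedly lower
#' chimpanzee heterozygosity) are flagged as outliers, and membership of
#' the within-1-SD band around the identity line is reported.
#'
#' @param he_pairs Data frame with `marker`, `he_chimp`, `he_human`.
#' @return The input with added columns `d`, `outlier`, `within_1sd`;
#'   attribute `sd` carries `s`.
#' @export
classify_outliers <- function(he_pairs) {
  .assert(nrow(he_pairs) >= 2L, "need at least 2 markers")
  d <- he_pairs$he_chimp - he_pairs$he_human
  s <- stats::sd(d)
  he_pairs$d <- d
  he_pairs$outlier <- d < -2 * s
  he_pairs$within_1sd <- abs(d) <= s
  attr(he_pairs, "sd") <- s
  he_pairs
}
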