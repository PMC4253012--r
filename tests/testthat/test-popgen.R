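test_that("sample-size-corrected heterozygosity matches closed forms", {
  expect_equal(heterozygosity(c(1, 1)), 1)          # single heterozygote
  expect_equal(heterozygosity(c(8)), 0)             # monomorphic
  expect_equal(heterozygosity(c(2, 2)), (4 / 3) * 0.5)
  expect_error(heterozygosity(c(1)), "at least 2")
})

test_that("pairwise theta matches a step-by-step variance-components oracle", {
  # popA: counts {8, 2} as 3 AA + 2 AB; popB mirrored
  g1 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 2), c(1, 2))
  g2 <- rbind(c(2, 2), c(2, 2), c(2, 2), c(1, 2), c(1, 2))
  ds <- two_pop_dataset(g1, g2)
  m <- pairwise_fst(ds, min_pop_size = 5)
  expect_equal(m$values["popA", "popB"], wc_theta_oracle(g1, g2))

  # a multiallelic case with uneven sample sizes
  set.seed(901)
  g3 <- cbind(sample(1:4, 12, TRUE), sample(1:4, 12, TRUE))
  g4 <- cbind(sample(2:6, 9, TRUE), sample(2:6, 9, TRUE))
  ds2 <- two_pop_dataset(g3, g4)
  m2 <- pairwise_fst(ds2, min_pop_size = 5)
  expect_equal(m2$values["popA", "popB"], wc_theta_oracle(g3, g4))
})

test_that("theta limits: no differentiation near 0, fixation at 1", {
  set.seed(902)
  pool <- 1:6
  # identical samples sit slightly below zero (the estimator's s^2 = 0 is
  # below its panmixia expectation); the bias shrinks as ~1/(2n-1)
  g1 <- cbind(sample(pool, 50, TRUE), sample(pool, 50, TRUE))
  ds_same <- two_pop_dataset(g1, g1)
  expect_lt(abs(pairwise_fst(ds_same, 5)$values[1, 2]), 0.02)
  ds_fixed <- two_pop_dataset(cbind(rep(1, 10), rep(1, 10)),
                              cbind(rep(2, 10), rep(2, 10)))
  expect_equal(pairwise_fst(ds_fixed, 5)$values[1, 2], 1)
})

test_that("allele-sharing distance evaluates the min-sum definition", {
  # p = {A: .6, B: .4}, q = {A: .1, C: .9}: shared mass 0.1
  g1 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 2), c(2, 2))
  g2 <- rbind(c(1, 3), c(3, 3), c(3, 3), c(3, 3), c(3, 3))
  ds <- two_pop_dataset(g1, g2)
  m <- pairwise_dps(ds, min_pop_size = 5)
  expect_equal(m$values["popA", "popB"], 0.9)

  ds_same <- two_pop_dataset(g1, g1)
  expect_equal(pairwise_dps(ds_same, 5)$values[1, 2], 0)
  ds_disjoint <- two_pop_dataset(rbind(c(1, 2), c(1, 2), c(2, 2), c(1, 1), c(2, 1)),
                                 rbind(c(3, 4), c(3, 4), c(4, 4), c(3, 3), c(4, 3)))
  expect_equal(pairwise_dps(ds_disjoint, 5)$values[1, 2], 1)
})

test_that("pairwise matrices are symmetric with sane ranges", {
  set.seed(903)
  pops <- data.frame(name = c("p1", "p2", "p3", "h1"),
                     species = c(rep("chimpanzee", 3), "human"), n = 12L)
  cfg <- ortholog_pair_config("M1")
  pair <- make_ortholog_pair(cfg, seed = 5)
  ds <- simulate_genotypes(list(pair$manifest), pops, F_drift = 0.1, seed = 6)
  fst <- pairwise_fst(ds, 5)
  dps <- pairwise_dps(ds, 5)
  expect_equal(fst$values, t(fst$values))
  expect_equal(dps$values, t(dps$values))
  expect_true(all(fst$values <= 1))
  expect_true(all(dps$values >= 0 & dps$values <= 1))
  expect_equal(diag(dps$values), rep(0, 4), ignore_attr = TRUE)
})

test_that("Weir-Cockerham theta recovers the Balding-Nichols drift parameter", {
  set.seed(904)
  cfgs <- lapply(1:30, function(i) ortholog_pair_config(sprintf("L%02d", i)))
  manifests <- lapply(seq_along(cfgs), function(i) {
    make_ortholog_pair(cfgs[[i]], seed = 9000 + i)$manifest
  })
  pops <- data.frame(name = sprintf("p%d", 1:6), species = "human", n = 30L)
  F_true <- 0.1
  ds <- simulate_genotypes(manifests, pops, F_drift = F_true, seed = 905)
  m <- pairwise_fst(ds, 5)
  est <- mean(m$values[upper.tri(m$values)])
  expect_lt(abs(est - F_true) / F_true, 0.25)
})

test_that("inflation summary is null for identical matrices", {
  set.seed(906)
  v <- matrix(stats::runif(16, 0.1, 0.6), 4)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  pops <- c("c1", "c2", "h1", "h2")
  sp <- stats::setNames(c("chimpanzee", "chimpanzee", "human", "human"), pops)
  m <- pairwise_matrix(pops, v, "FST", "length")
  m2 <- pairwise_matrix(pops, v, "FST", "repeats")
  s <- inflation_summary(m, m2, sp)
  expect_equal(s$max_reduction_pct, 0)
  expect_equal(s$mean_reduction_pct, 0)
  expect_equal(s$r_squared, 1)
})

test_that("a planted species-specific flank indel inflates length-based estimates", {
  set.seed(907)
  mk_manifests <- function(indel_size) {
    lapply(1:12, function(i) {
      cfg <- ortholog_pair_config(
        sprintf("L%02d", i), repeats_chimp = 10L, repeats_human = 12L,
        indels = if (i <= 6 && indel_size > 0) {
          list(list(species = "human", size = indel_size))
        } else list())
      make_ortholog_pair(cfg, seed = 950 + i)$manifest
    })
  }
  pops <- data.frame(name = c("c1", "c2", "h1", "h2"),
                     species = c("chimpanzee", "chimpanzee", "human", "human"),
                     n = 15L)
  sp <- stats::setNames(pops$species, pops$name)
  run_one <- function(indel_size) {
    manifests <- mk_manifests(indel_size)
    ds_len <- simulate_genotypes(manifests, pops, F_drift = 0.05, seed = 908)
    models <- lapply(manifests, function(mf) {
      list(chimpanzee = calibration_model(mf$marker, "chimpanzee",
                                          mf$ref_adjusted_length[["chimpanzee"]],
                                          mf$repeats[["chimpanzee"]], mf$unit_size),
           human = calibration_model(mf$marker, "human",
                                     mf$ref_adjusted_length[["human"]],
                                     mf$repeats[["human"]], mf$unit_size))
    })
    names(models) <- vapply(manifests, `[[`, character(1), "marker")
    ds_rep <- normalize_dataset(ds_len, models)$dataset
    list(fst = inflation_summary(pairwise_fst(ds_len, 5), pairwise_fst(ds_rep, 5), sp),
         dps = inflation_summary(pairwise_dps(ds_len, 5), pairwise_dps(ds_rep, 5), sp))
  }
  with_indel <- run_one(9L)     # size not a repeat-unit multiple
  expect_gt(with_indel$fst$mean_reduction_pct, 0)
  expect_gt(with_indel$dps$mean_reduction_pct, 0)
  # interspecies D_PS from lengths dominates entry-wise
  inter <- with_indel$dps$pairs[with_indel$dps$pairs$interspecies, ]
  expect_true(all(inter$value_length >= inter$value_repeats))

  without <- run_one(0L)
  expect_equal(without$fst$pairs$value_length, without$fst$pairs$value_repeats)
  expect_equal(without$dps$pairs$value_length, without$dps$pairs$value_repeats)
})

test_that("monomorphic-in-pair loci are skipped without breaking theta", {
  g1 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  g2 <- g1
  samples <- data.frame(id = c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)),
                        population = rep(c("popA", "popB"), each = 5),
                        species = "human")
  calls <- rbind(
    data.frame(id = samples$id, marker = "mono",
               a1 = c(g1[, 1], g2[, 1]), a2 = c(g1[, 2], g2[, 2])),
    data.frame(id = samples$id, marker = "poly",
               a1 = c(1, 1, 1, 2, 2, 2, 2, 2, 1, 1),
               a2 = c(1, 1, 2, 2, 2, 2, 2, 1, 1, 1)))
  ds <- genotype_dataset(samples, calls, "length")
  m <- pairwise_fst(ds, 5)
  g1p <- cbind(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 2))
  g2p <- cbind(c(2, 2, 2, 1, 1), c(2, 2, 1, 1, 1))
  expect_equal(m$values[1, 2], wc_theta_oracle(g1p, g2p))
})
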