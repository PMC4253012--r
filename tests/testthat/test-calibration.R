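ref_frag <- function(len, marker = "M1", species = "chimpanzee") {
  f <- epcr_fragment(marker, "ref", strrep("A", 1), species = species)
  f$raw_length <- len
  f$adjusted_length <- len
  f
}

test_that("model building requires a single repeat-unit size", {
  st <- str_structure(list(str_region(10, 58, "GATA", 12)))
  m <- build_model(ref_frag(210), st)
  expect_equal(m$ref_adjusted_length, 210)
  expect_equal(m$ref_total_repeats, 12L)
  expect_equal(m$unit_size, 4L)

  two_ac <- str_structure(list(str_region(0, 12, "AC", 6),
                               str_region(20, 30, "CA", 5)))
  m2 <- build_model(ref_frag(180), two_ac)
  expect_equal(m2$ref_total_repeats, 11L)
  expect_equal(m2$unit_size, 2L)

  mixed <- str_structure(list(str_region(0, 32, "GATA", 8),
                              str_region(40, 52, "AC", 6)))
  expect_error(build_model(ref_frag(200), mixed), "mixed-unit excluded")
  expect_error(build_model(ref_frag(200), str_structure()), "no STR regions")
})

test_that("length-repeat conversion is the documented affine map", {
  m <- calibration_model("M1", "chimpanzee", 210, 10L, 4L)
  expect_equal(length_to_repeats(210, m), 10)
  expect_equal(length_to_repeats(218, m), 12)
  expect_equal(length_to_repeats(211, m), 10.25)
  expect_equal(repeats_to_length(10, m), 210)
  expect_error(repeats_to_length(0, m), ">= 1")
  expect_error(length_to_repeats(-4, m), "positive")
  # round trip over a wide repeat range is exact
  for (r in 1:40) expect_equal(length_to_repeats(repeats_to_length(r, m), m), r)
})

make_length_dataset <- function(lengths_by_species, marker = "M1") {
  n_c <- nrow(lengths_by_species$chimpanzee)
  n_h <- nrow(lengths_by_species$human)
  samples <- data.frame(
    id = c(sprintf("c%d", seq_len(n_c)), sprintf("h%d", seq_len(n_h))),
    population = c(rep("chimpA", n_c), rep("humA", n_h)),
    species = c(rep("chimpanzee", n_c), rep("human", n_h)))
  calls <- data.frame(id = samples$id, marker = marker,
                      a1 = c(lengths_by_species$chimpanzee[, 1],
                             lengths_by_species$human[, 1]),
                      a2 = c(lengths_by_species$chimpanzee[, 2],
                             lengths_by_species$human[, 2]))
  genotype_dataset(samples, calls, "length")
}

test_that("normalization rounds a common decimal fraction and flags it", {
  models <- list(M1 = list(
    chimpanzee = calibration_model("M1", "chimpanzee", 200, 10L, 4L),
    human = calibration_model("M1", "human", 208, 11L, 4L)))
  # integer repeats on both sides pass through untouched
  ds <- make_length_dataset(list(chimpanzee = rbind(c(200, 204), c(196, 200)),
                                 human = rbind(c(208, 212), c(204, 208))))
  out <- normalize_dataset(ds, models)
  expect_equal(out$report$status, "integer")
  expect_equal(sort(out$dataset$calls$a1), c(9, 10, 10, 11))

  # every genotype off by 3 bp: common fraction 0.75, rounded and flagged
  ds2 <- make_length_dataset(list(chimpanzee = rbind(c(203, 207), c(199, 203)),
                                  human = rbind(c(211, 215), c(207, 211))))
  out2 <- normalize_dataset(ds2, models)
  expect_equal(out2$report$status, "common-fraction rounded")
  expect_true(all(out2$dataset$calls$a1 == round(out2$dataset$calls$a1)))
  expect_equal(sort(out2$dataset$calls$a2), c(11, 12, 12, 13))

  # mixed fractions stay unadjusted and are flagged
  ds3 <- make_length_dataset(list(chimpanzee = rbind(c(203, 207), c(198, 202)),
                                  human = rbind(c(211, 215), c(207, 211))))
  out3 <- normalize_dataset(ds3, models)
  expect_equal(out3$report$status, "mixed-fraction unadjusted")
  expect_true(any(out3$dataset$calls$a1 != round(out3$dataset$calls$a1)))

  expect_error(normalize_dataset(ds, models["MX"]), "missing calibration model")
})

test_that("normalization is idempotent", {
  models <- list(M1 = list(
    chimpanzee = calibration_model("M1", "chimpanzee", 200, 10L, 4L),
    human = calibration_model("M1", "human", 208, 11L, 4L)))
  ds <- make_length_dataset(list(chimpanzee = rbind(c(203, 207), c(199, 203)),
                                 human = rbind(c(211, 215), c(207, 211))))
  once <- normalize_dataset(ds, models)
  # map the repeat dataset back through the models and normalize again:
  # the repeat calls must be unchanged
  back <- once$dataset$calls
  sp_of <- c(stats::setNames(ds$samples$species, ds$samples$id))
  for (k in seq_len(nrow(back))) {
    m <- models$M1[[sp_of[[back$id[k]]]]]
    back$a1[k] <- repeats_to_length(back$a1[k], m)
    back$a2[k] <- repeats_to_length(back$a2[k], m)
  }
  ds_back <- genotype_dataset(ds$samples, back, "length")
  twice <- normalize_dataset(ds_back, models)
  expect_equal(twice$dataset$calls, once$dataset$calls)
  expect_equal(twice$report$status, "integer")
})

test_that("within-species heterozygosity is invariant under calibration", {
  set.seed(801)
  cfg <- ortholog_pair_config("M1", indels = list(list(species = "human", size = 11L)))
  pair <- make_ortholog_pair(cfg, seed = 31)
  pops <- data.frame(name = c("c1", "c2", "h1", "h2"),
                     species = c("chimpanzee", "chimpanzee", "human", "human"),
                     n = 15L)
  ds <- simulate_genotypes(list(pair$manifest), pops, F_drift = 0.05, seed = 32)
  models <- list(M1 = list(
    chimpanzee = calibration_model("M1", "chimpanzee",
                                   pair$manifest$ref_adjusted_length[["chimpanzee"]],
                                   pair$manifest$repeats[["chimpanzee"]], 4L),
    human = calibration_model("M1", "human",
                              pair$manifest$ref_adjusted_length[["human"]],
                              pair$manifest$repeats[["human"]], 4L)))
  out <- normalize_dataset(ds, models)
  he_len <- marker_heterozygosity(ds)
  he_rep <- marker_heterozygosity(out$dataset)
  he_len <- he_len[order(he_len$species), ]
  he_rep <- he_rep[order(he_rep$species), ]
  expect_equal(he_rep$he, he_len$he)
})

test_that("round trips through the generator's models are exact", {
  set.seed(802)
  for (unit in c(2L, 3L, 4L)) {
    motif <- c("2" = "AC", "3" = "AAT", "4" = "GATA")[[as.character(unit)]]
    cfg <- ortholog_pair_config("M1", unit_size = unit, motif = motif,
                                repeats_chimp = 9L, repeats_human = 12L)
    pair <- make_ortholog_pair(cfg, seed = 40 + unit)
    for (sp in c("chimpanzee", "human")) {
      m <- calibration_model("M1", sp, pair$manifest$ref_adjusted_length[[sp]],
                             pair$manifest$repeats[[sp]], unit)
      for (r in 2:30) {
        expect_identical(length_to_repeats(repeats_to_length(r, m), m), as.numeric(r))
      }
    }
  }
})
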