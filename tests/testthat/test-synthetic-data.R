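test_that("zero-indel equal-repeat configs give identical species records", {
  cfg <- ortholog_pair_config("T", repeats_chimp = 12L, repeats_human = 12L)
  pair <- make_ortholog_pair(cfg, seed = 3)
  expect_identical(pair$chimp_seq, pair$human_seq)
  expect_equal(unname(pair$manifest$ref_raw_length["chimpanzee"]),
               unname(pair$manifest$ref_raw_length["human"]))
})

test_that("reference length arithmetic reflects indels and repeat differences", {
  cfg <- ortholog_pair_config("T", repeats_chimp = 10L, repeats_human = 12L,
                              indels = list(list(species = "chimpanzee", size = 8L)))
  pair <- make_ortholog_pair(cfg, seed = 4)
  # chimp is 8 bp longer minus the 2-unit (8 bp) STR deficit: equal lengths
  expect_equal(nchar(pair$chimp_seq) - nchar(pair$human_seq), 8L - 2L * 4L)
  expect_error(
    make_ortholog_pair(ortholog_pair_config(
      "T", indels = list(list(species = "human", size = 33L))), seed = 1),
    "1-32")
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- ortholog_pair_config("T", indels = list(list(species = "human", size = 5L)))
  p1 <- make_ortholog_pair(cfg, seed = 77)
  p2 <- make_ortholog_pair(cfg, seed = 77)
  expect_identical(p1, p2)
  s1 <- make_study(study_config(n_core = 5, n_human_pops = 2, n_chimp_pops = 2,
                                n_per_pop = 6), seed = 21)
  s2 <- make_study(study_config(n_core = 5, n_human_pops = 2, n_chimp_pops = 2,
                                n_per_pop = 6), seed = 21)
  expect_identical(s1$refs_chimp, s2$refs_chimp)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
})

test_that("pipeline recovers every planted structure and indel total", {
  set.seed(1101)
  for (i in 1:25) {
    unit <- sample(c(2L, 3L, 4L), 1)
    motif <- c("2" = "AC", "3" = "AAT", "4" = "GATA")[[as.character(unit)]]
    cfg <- ortholog_pair_config(
      sprintf("R%02d", i), unit_size = unit, motif = motif,
      repeats_chimp = sample(5:13, 1), repeats_human = sample(5:13, 1),
      n_str_regions = if (unit == 4L) sample(1:2, 1) else 1L,
      indels = if (i %% 2 == 0) {
        list(list(species = sample(c("chimpanzee", "human"), 1),
                  size = sample(1:32, 1)))
      } else list())
    pair <- make_ortholog_pair(cfg, seed = 1100 + i)
    # detection recovers the planted structure
    for (sp in c("chimpanzee", "human")) {
      seqs <- if (sp == "chimpanzee") pair$chimp_seq else pair$human_seq
      st <- find_str_regions(seqs, 2L)
      expect_equal(total_repeats(st),
                   unname(pair$manifest$repeats[sp]),
                   info = sprintf("case %d %s", i, sp))
    }
    # epcr recovers the amplicon
    fwd <- scan_primer(pair$primers$forward, pair$chimp_seq)
    rev <- scan_primer(pair$primers$reverse, pair$chimp_seq)
    frags <- demarcate_fragments(Filter(function(h) h$strand == "+", fwd),
                                 Filter(function(h) h$strand == "-", rev),
                                 pair$chimp_seq, cfg$marker)
    expect_true(unname(pair$manifest$ref_raw_length["chimpanzee"]) %in%
                  vapply(frags, `[[`, integer(1), "raw_length"))
    # alignment recovers the planted indel totals
    aln <- align_orthologs(pair$chimp_seq, pair$human_seq)
    want_c <- sum(vapply(pair$manifest$indels, function(x)
      if (x$species == "chimpanzee") x$size else 0L, numeric(1)), 0)
    want_h <- sum(vapply(pair$manifest$indels, function(x)
      if (x$species == "human") x$size else 0L, numeric(1)), 0)
    expect_equal(aln$chimp_only_nonstr_nt, want_c, info = sprintf("case %d", i))
    expect_equal(aln$human_only_nonstr_nt, want_h, info = sprintf("case %d", i))
  }
})

test_that("simulated genotypes are deterministic and calibrate back exactly", {
  cfg <- ortholog_pair_config("T", indels = list(list(species = "human", size = 7L)))
  pair <- make_ortholog_pair(cfg, seed = 5)
  pops <- data.frame(name = c("c1", "h1"), species = c("chimpanzee", "human"),
                     n = 25L)
  d1 <- simulate_genotypes(list(pair$manifest), pops, F_drift = 0.05, seed = 9)
  d2 <- simulate_genotypes(list(pair$manifest), pops, F_drift = 0.05, seed = 9)
  expect_identical(d1$calls, d2$calls)
  expect_error(simulate_genotypes(list(pair$manifest), pops, F_drift = 0, seed = 9),
               "F_drift")

  # lengths map back to the generator's true repeat numbers exactly
  truth <- attr(d1, "truth")$repeats
  for (sp in c("chimpanzee", "human")) {
    m <- calibration_model("T", sp, pair$manifest$ref_adjusted_length[[sp]],
                           pair$manifest$repeats[[sp]], 4L)
    ids <- d1$samples$id[d1$samples$species == sp]
    got <- d1$calls[d1$calls$id %in% ids, ]
    want <- truth[truth$id %in% ids, ]
    expect_equal(length_to_repeats(got$a1, m), pmin(want$a1, want$a2))
    expect_equal(length_to_repeats(got$a2, m), pmax(want$a1, want$a2))
  }
})

test_that("drifted within-species theta tracks the drift parameter", {
  set.seed(1102)
  cfgs <- lapply(1:40, function(i) ortholog_pair_config(sprintf("L%02d", i)))
  manifests <- lapply(seq_along(cfgs), function(i)
    make_ortholog_pair(cfgs[[i]], seed = 1200 + i)$manifest)
  pops <- data.frame(name = sprintf("p%d", 1:4), species = "human", n = 40L)
  ds <- simulate_genotypes(manifests, pops, F_drift = 0.1, seed = 1103)
  m <- pairwise_fst(ds, 5)
  est <- mean(m$values[upper.tri(m$values)])
  expect_lt(abs(est - 0.1) / 0.1, 0.25)
})

test_that("study bundles are self-consistent and cover every branch", {
  study <- make_study(study_config(n_core = 6, n_human_pops = 3,
                                   n_chimp_pops = 2, n_per_pop = 8), seed = 31)
  expect_gte(length(study$refs_chimp), 6 + 12)  # core plus branch panel
  expect_setequal(names(study$refs_chimp), names(study$refs_human))
  # core references pass their own retention filter
  for (marker in sprintf("CORE%03d", 1:6)) {
    sub <- study$genotypes$calls[study$genotypes$calls$marker == marker, ]
    sp_of <- stats::setNames(study$samples$species, study$samples$id)
    v <- c(sub$a1, sub$a2)[sp_of[c(sub$id, sub$id)] == "chimpanzee"]
    rng <- length_range(min(v, na.rm = TRUE), max(v, na.rm = TRUE))
    x <- study$manifests[[marker]]$ref_adjusted_length[["chimpanzee"]]
    expect_true(retention_filter(x, rng)$keep, info = marker)
  }
  # every expected decision-tree label class appears in the panel
  labels <- unlist(study$expected)
  expect_true(all(c("retained", "rejected_length", "rejected_no_hit",
                    "rejected_multi_hit", "resolved_overlap") %in% labels))
  expect_true(all(c("identical", "three_repeat_variant", "two_repeat_variant",
                    "disrupted_variant", "discordant", "no_str") %in% labels))
  expect_true(all(c("i", "ii", "iii", "fail") %in% labels))
})

test_that("study bundles round-trip through the plain-text writers", {
  study <- make_study(study_config(n_core = 4, n_human_pops = 2,
                                   n_chimp_pops = 2, n_per_pop = 6), seed = 33)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_study(dir)
  expect_identical(back$refs_chimp, c(study$refs_chimp))
  expect_identical(back$refs_human, c(study$refs_human))
  expect_equal(back$genotypes$calls, study$genotypes$calls)
  expect_equal(back$primers, study$primers)
  expect_equal(back$distances[!is.na(back$distances)],
               study$distances[!is.na(study$distances)])
})
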