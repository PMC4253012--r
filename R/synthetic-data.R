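#' Synthetic ortholog pairs and multi-population genotype datasets
#'
#' Generates reference amplicon pairs with a shared ancestral flank,
#' species-specific small indels, embedded STR regions with species-specific
#' repeat counts, primer sites in the flanks, and drifted multi-population
#' diploid genotypes — every quantity recorded in a truth manifest so the
#' whole pipeline can be tested against known ground truth. Flanks and
#' spacers are built free of any 2+ copy tandem repeat of a 2-6 nt motif so
#' that detected STR structure is exactly the constructed structure.
#'
#' @name synthetic-data
NULL

.BASES <- c("A", "C", "G", "T")

# Random DNA containing no tandem of >= 2 contiguous copies of any 1-6 nt
# motif: appending base b at position i would complete a tandem of unit u
# iff b == s[i-u] and the preceding u-1 positions already repeat, so such
# bases are excluded from the draw (u = 1 also bans adjacent equal bases).
.nonrepetitive_dna <- function(n) {
  s <- character(n)
  for (i in seq_len(n)) {
    forbidden <- if (i > 1L) s[i - 1L] else character(0)
    for (u in 2:6) {
      if (i - 2L * u + 1L < 1L) next
      if (all(s[(i - 2L * u + 1L):(i - u - 1L)] == s[(i - u + 1L):(i - 1L)])) {
        forbidden <- c(forbidden, s[i - u])
      }
    }
    allowed <- setdiff(.BASES, unique(forbidden))
    if (length(allowed) == 0L) allowed <- setdiff(.BASES, s[i - 1L])
    s[i] <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }
  paste(s, collapse = "")
}

#' Configuration for one synthetic ortholog pair
#'
#' @param marker Marker name.
#' @param unit_size Repeat unit size (nt) of the first STR region.
#' @param motif Motif of the first region (chimpanzee and human alike);
#'   `motif_chimp`/`motif_human` override it per species to construct
#'   discordant loci.
#' @param repeats_chimp,repeats_human Repeat counts of the first region.
#' @param n_str_regions 1 or 2 embedded regions.
#' @param motif2,repeats2_chimp,repeats2_human Second region (same unit
#'   size family or different; ignored when `n_str_regions = 1`).
#' @param spacer Nucleotides separating the two regions.
#' @param flank_len Length of each flank (>= `primer_len + 10`).
#' @param primer_len Primer length (flank prefix/suffix).
#' @param indels List of `list(species =, size =)` insertions planted in a
#'   flank interior of one species (sizes <= 32; chimpanzee insertions go in
#'   the left flank, human insertions in the right).
#' @param disruption `NULL`, `"chimpanzee"` or `"human"`: insert a 1-nt
#'   interruption mid-array in the first region of that species.
#' @param mod_flag `"none"`, `"P"` or `"M"` (reverse-primer modification).
#' @param merge_offset Merge correction recorded on the primer pair.
#' @return A config list for [make_ortholog_pair()].
#' @export
ortholog_pair_config <- function(marker, unit_size = 4L, motif = "GATA",
                                 repeats_chimp = 10L, repeats_human = 12L,
                                 n_str_regions = 1L, motif2 = "CTTT",
                                 repeats2_chimp = 6L, repeats2_human = 6L,
                                 spacer = 11L, flank_len = 70L, primer_len = 20L,
                                 indels = list(), disruption = NULL,
                                 motif_chimp = NULL, motif_human = NULL,
                                 mod_flag = "none", merge_offset = 0L) {
  .assert(flank_len >= primer_len + 10L, "flank_len must be >= primer_len + 10")
  for (ind in indels) {
    .assert(ind$size >= 1L && ind$size <= 32L, "indel sizes must be 1-32 bp")
  }
  list(marker = marker, unit_size = as.integer(unit_size), motif = motif,
       repeats_chimp = as.integer(repeats_chimp),
       repeats_human = as.integer(repeats_human),
       n_str_regions = as.integer(n_str_regions), motif2 = motif2,
       repeats2_chimp = as.integer(repeats2_chimp),
       repeats2_human = as.integer(repeats2_human),
       spacer = as.integer(spacer), flank_len = as.integer(flank_len),
       primer_len = as.integer(primer_len), indels = indels,
       disruption = disruption, motif_chimp = motif_chimp,
       motif_human = motif_human, mod_flag = mod_flag,
       merge_offset = as.integer(merge_offset))
}

.str_block <- function(cfg, species) {
  motif1 <- if (species == "chimpanzee" && !is.null(cfg$motif_chimp)) cfg$motif_chimp
  else if (species == "human" && !is.null(cfg$motif_human)) cfg$motif_human
  else cfg$motif
  reps1 <- if (species == "chimpanzee") cfg$repeats_chimp else cfg$repeats_human
  block1 <- strrep(motif1, reps1)
  if (!is.null(cfg$disruption) && cfg$disruption == species && reps1 >= 4L) {
    a1 <- reps1 %/% 2L
    # a base absent from the motif cannot seed a larger-unit tandem that
    # spans the interruption
    unused <- setdiff(.BASES, strsplit(motif1, "")[[1]])
    interrupt <- if (length(unused) > 0L) unused[1] else
      setdiff(.BASES, substr(motif1, 1L, 1L))[1]
    block1 <- paste0(strrep(motif1, a1), interrupt, strrep(motif1, reps1 - a1))
  }
  if (cfg$n_str_regions == 1L) return(block1)
  reps2 <- if (species == "chimpanzee") cfg$repeats2_chimp else cfg$repeats2_human
  paste0(block1, .nonrepetitive_dna(cfg$spacer), strrep(cfg$motif2, reps2))
}

.expected_regions <- function(cfg, species) {
  motif1 <- if (species == "chimpanzee" && !is.null(cfg$motif_chimp)) cfg$motif_chimp
  else if (species == "human" && !is.null(cfg$motif_human)) cfg$motif_human
  else cfg$motif
  reps1 <- if (species == "chimpanzee") cfg$repeats_chimp else cfg$repeats_human
  regs <- if (!is.null(cfg$disruption) && cfg$disruption == species && reps1 >= 4L) {
    a1 <- reps1 %/% 2L
    list(c(motif1, a1), c(motif1, reps1 - a1))
  } else if (reps1 >= 2L) {
    list(c(motif1, reps1))
  } else {
    list()
  }
  if (cfg$n_str_regions == 2L) {
    reps2 <- if (species == "chimpanzee") cfg$repeats2_chimp else cfg$repeats2_human
    if (reps2 >= 2L) regs <- c(regs, list(c(cfg$motif2, reps2)))
  }
  regs
}

.structure_matches <- function(structure, expected) {
  regs <- structure$regions
  if (length(regs) != length(expected)) return(FALSE)
  for (k in seq_along(regs)) {
    if (regs[[k]]$repeat_count != as.integer(expected[[k]][2])) return(FALSE)
    if (!.rotation_equivalent(regs[[k]]$motif, expected[[k]][1])) return(FALSE)
  }
  TRUE
}

#' Generate one synthetic ortholog amplicon pair
#'
#' Both species share the ancestral flanks; species-specific insertions are
#' planted in flank interiors (never overlapping a primer site; the two
#' species use different flanks so opposing insertions occupy different
#' alignment segments), and the STR block carries the species' configured
#' repeat counts. The
#' constructed structure is verified by detection at `min_repeats = 2`;
#' flanks are re-drawn (deterministically from the seed) when a junction
#' artefact would alter it.
#'
#' @param config An [ortholog_pair_config()].
#' @param seed Integer seed; generation is fully deterministic given
#'   (config, seed).
#' @return List with `chimp_seq`, `human_seq`, `primers` ([primer_pair()])
#'   and `manifest` (truth record: motifs, counts, indels with positions,
#'   primer positions, per-species reference lengths).
#' @export
make_ortholog_pair <- function(config, seed = 1L) {
  cfg <- config
  for (attempt in 1:50) {
    set.seed(seed + 7919L * (attempt - 1L))
    left <- .nonrepetitive_dna(cfg$flank_len)
    right <- .nonrepetitive_dna(cfg$flank_len)
    blocks <- list(chimpanzee = .str_block(cfg, "chimpanzee"),
                   human = .str_block(cfg, "human"))
    seqs <- list(); indel_log <- list(); ok <- TRUE
    for (species in c("chimpanzee", "human")) {
      l <- left; r <- right
      for (ind in cfg$indels) {
        if (ind$species != species) next
        # flank interior, clear of the primer sites; the two species use
        # different flanks so opposing insertions land in different
        # alignment segments and can never pair
        at <- cfg$flank_len %/% 2L
        .assert(at > cfg$primer_len && at < cfg$flank_len - cfg$primer_len,
                "indel overlaps a primer site")
        ins <- .nonrepetitive_dna(ind$size)
        if (species == "chimpanzee") {
          l <- paste0(substr(l, 1L, at), ins, substr(l, at + 1L, nchar(l)))
          indel_log[[length(indel_log) + 1L]] <-
            list(species = species, size = ind$size, position = at)
        } else {
          r <- paste0(substr(r, 1L, at), ins, substr(r, at + 1L, nchar(r)))
          indel_log[[length(indel_log) + 1L]] <-
            list(species = species, size = ind$size,
                 position = nchar(l) + nchar(blocks[[species]]) + at)
        }
      }
      s <- paste0(l, blocks[[species]], r)
      st <- find_str_regions(s, min_repeats = 2L)
      if (!.structure_matches(st, .expected_regions(cfg, species))) {
        ok <- FALSE
        break
      }
      seqs[[species]] <- s
    }
    if (ok) break
  }
  .assert(ok, "could not construct %s without junction artefacts", cfg$marker)
  extra <- c(none = 0L, P = 7L, M = 1L)[[cfg$mod_flag]]
  primers <- primer_pair(
    cfg$marker,
    forward = substr(left, 1L, cfg$primer_len),
    reverse = as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(seqs$human, nchar(seqs$human) - cfg$primer_len + 1L, nchar(seqs$human))))),
    forward_extra_bp = 0L, reverse_extra_bp = extra,
    merge_offset = cfg$merge_offset)
  ref_len <- vapply(seqs, nchar, integer(1))
  manifest <- list(
    marker = cfg$marker, unit_size = cfg$unit_size,
    config = cfg,
    repeats = c(chimpanzee = sum(vapply(.expected_regions(cfg, "chimpanzee"),
                                        function(x) as.integer(x[2]), integer(1))),
                human = sum(vapply(.expected_regions(cfg, "human"),
                                   function(x) as.integer(x[2]), integer(1)))),
    indels = indel_log,
    primer_positions = c(forward = 1L,
                         reverse = unname(ref_len["human"]) - cfg$primer_len + 1L),
    ref_raw_length = ref_len,
    ref_adjusted_length = ref_len + extra - cfg$merge_offset,
    seed = seed)
  list(chimp_seq = seqs$chimpanzee, human_seq = seqs$human,
       primers = primers, manifest = manifest)
}

.double_geometric <- function(center, half_width = 5L, q = 0.65, lo = 2L) {
  support <- seq(max(lo, center - half_width), center + half_width)
  w <- q^abs(support - center)
  list(support = support, prob = w / sum(w))
}

#' Simulate drifted multi-population diploid genotypes
#'
#' Species base repeat-number frequencies are a discretized double-geometric
#' around the species' reference repeat count (the long-tailed, mostly
#' single-step allele spacing expected at stepwise-mutating loci); each
#' population's frequencies are a Dirichlet draw around the species base
#' with Balding-Nichols drift parameter F (`Dirichlet(p (1-F)/F)`), and
#' diploid alleles are sampled i.i.d. Repeat numbers are converted to
#' fragment lengths against the species' own reference, so species-specific
#' flank indels propagate into the length representation.
#'
#' @param manifests List of [make_ortholog_pair()] manifests (one per
#'   marker).
#' @param pops Data frame with `name`, `species`, `n` (diploids) and
#'   optionally `drift_f` (per-population F overriding `F_drift`).
#' @param F_drift Drift parameter in (0, 1).
#' @param seed Integer seed (required; all randomness flows from it).
#' @param missing_rate Fraction of genotypes set missing.
#' @return A length-representation [genotype_dataset()]; attribute `truth`
#'   holds the repeat-number calls and the per-population frequency draws.
#' @export
simulate_genotypes <- function(manifests, pops, F_drift = 0.02, seed,
                               missing_rate = 0) {
  .assert(F_drift > 0 && F_drift < 1, "F_drift must lie in (0, 1)")
  .assert(!missing(seed), "a seed is required")
  set.seed(seed)
  if (is.null(pops$drift_f)) pops$drift_f <- F_drift
  samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(id = sprintf("%s_%02d", pops$name[i], seq_len(pops$n[i])),
               population = pops$name[i], species = pops$species[i])
  }))
  calls <- list(); truth <- list(); freqs <- list()
  for (mf in manifests) {
    base <- list(
      chimpanzee = .double_geometric(mf$repeats[["chimpanzee"]]),
      human = .double_geometric(mf$repeats[["human"]]))
    for (i in seq_len(nrow(pops))) {
      sp <- pops$species[i]
      b <- base[[sp]]
      f <- pops$drift_f[i]
      shape <- b$prob * (1 - f) / f
      g <- stats::rgamma(length(shape), shape = shape)
      if (sum(g) == 0) g[which.max(shape)] <- 1
      p <- g / sum(g)
      n <- pops$n[i]
      reps <- matrix(sample(b$support, 2L * n, replace = TRUE, prob = p),
                     ncol = 2L)
      len <- mf$ref_adjusted_length[[sp]] +
        (reps - mf$repeats[[sp]]) * mf$unit_size
      if (missing_rate > 0) {
        drop <- stats::runif(n) < missing_rate
        len[drop, ] <- NA_real_
        reps[drop, ] <- NA_integer_
      }
      ids <- samples$id[samples$population == pops$name[i]]
      calls[[length(calls) + 1L]] <- data.frame(
        id = ids, marker = mf$marker, a1 = len[, 1], a2 = len[, 2])
      truth[[length(truth) + 1L]] <- data.frame(
        id = ids, marker = mf$marker, a1 = reps[, 1], a2 = reps[, 2])
      freqs[[length(freqs) + 1L]] <- data.frame(
        marker = mf$marker, population = pops$name[i],
        repeat_n = b$support, freq = p)
    }
  }
  ds <- genotype_dataset(samples, do.call(rbind, calls), "length")
  attr(ds, "truth") <- list(repeats = do.call(rbind, truth),
                            freqs = do.call(rbind, freqs))
  ds
}

#' Study-level configuration for [make_study()]
#'
#' Defaults are the package's standing study conditions: 138 concordant
#' single-unit-size core loci grouped as in the field's human-derived
#' panels (31 tri- and 86 tetra-nucleotide single-region loci, 21
#' two-region tetranucleotide loci), a species repeat-count offset of 2
#' (chimpanzee lower), species-specific flank insertions of 1-32 bp at
#' about half the loci, 10 human populations on an increasing-drift
#' gradient plus 5 chimpanzee populations, 20 diploids each.
#'
#' @param n_core Number of concordant core loci.
#' @param indel_prob Probability a core locus carries a species-specific
#'   flank insertion.
#' @param max_indel Maximum insertion size (bp).
#' @param species_offset Human-minus-chimpanzee repeat-count offset.
#' @param n_human_pops,n_chimp_pops,n_per_pop Population layout.
#' @param f_human_base,f_human_step Balding-Nichols F of the first human
#'   population and its per-population increment along the distance
#'   gradient.
#' @param f_chimp F for chimpanzee populations.
#' @param with_branch_panel Include the engineered decision-tree branch
#'   markers.
#' @return Config list for [make_study()].
#' @export
study_config <- function(n_core = 138L, indel_prob = 0.5, max_indel = 32L,
                         species_offset = 2L,
                         n_human_pops = 10L, n_chimp_pops = 5L, n_per_pop = 20L,
                         f_human_base = 0.02, f_human_step = 0.015,
                         f_chimp = 0.05, with_branch_panel = TRUE) {
  list(n_core = as.integer(n_core), indel_prob = indel_prob,
       max_indel = as.integer(max_indel),
       species_offset = as.integer(species_offset),
       n_human_pops = as.integer(n_human_pops),
       n_chimp_pops = as.integer(n_chimp_pops),
       n_per_pop = as.integer(n_per_pop),
       f_human_base = f_human_base, f_human_step = f_human_step,
       f_chimp = f_chimp, with_branch_panel = with_branch_panel)
}

# Engineered markers, one per decision-tree branch, with the deterministic
# genotype ranges (relative to the reference lengths) that exercise it.
.branch_specs <- function() {
  tetra <- function(marker, ...) ortholog_pair_config(marker, unit_size = 4L,
                                                      motif = "GATA", ...)
  di <- function(marker, ...) ortholog_pair_config(marker, unit_size = 2L,
                                                   motif = "AC", ...)
  list(
    list(cfg = tetra("M_EP_RET", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(epcr = "retained"),
         chimp_range = c(-12, 12), human_range = c(-12, 12)),
    list(cfg = tetra("M_EP_LEN", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(epcr = "rejected_length"),
         chimp_range = c(40, 60), human_range = c(-12, 12)),
    list(cfg = tetra("M_EP_NOHIT", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(epcr = "rejected_no_hit"), corrupt_forward = TRUE,
         chimp_range = c(-12, 12), human_range = c(-12, 12)),
    list(cfg = tetra("M_EP_MULTI", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(epcr = "rejected_multi_hit"), duplicate_target = TRUE,
         chimp_range = c(-12, 12), human_range = c(-12, 12)),
    list(cfg = tetra("M_EP_OVER", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(epcr = "resolved_overlap"), extra_forward_site = TRUE,
         chimp_range = c(-12, 40), human_range = c(-12, 12)),
    list(cfg = tetra("M_RC_IDENT", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(epcr = "retained", range_class = "identical",
                       criterion = "i", concordance = "identical"),
         chimp_range = c(-12, 12), human_range = c(-12, 12)),
    list(cfg = tetra("M_RC_CSUB", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(range_class = "chimp_subsumed", criterion = "i"),
         chimp_range = c(-8, 8), human_range = c(-16, 16)),
    list(cfg = tetra("M_RC_HSUB", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(range_class = "human_subsumed", criterion = "i"),
         chimp_range = c(-16, 16), human_range = c(-8, 8)),
    list(cfg = tetra("M_RC_PLOW", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(range_class = "partial_chimp_lower", criterion = "i"),
         chimp_range = c(-20, 4), human_range = c(-4, 20)),
    list(cfg = tetra("M_RC_PHIGH", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(range_class = "partial_chimp_higher", criterion = "i"),
         chimp_range = c(-4, 20), human_range = c(-20, 4)),
    list(cfg = tetra("M_RC_DISJ", repeats_chimp = 12L, repeats_human = 12L),
         expect = list(range_class = "disjoint"),
         chimp_range = c(-16, 0), human_range = c(8, 24)),
    list(cfg = di("M_CR_II", repeats_chimp = 14L, repeats_human = 14L),
         expect = list(criterion = "ii"),
         chimp_range = c(4, 20), human_range = c(-12, 20)),
    list(cfg = di("M_CR_III", repeats_chimp = 14L, repeats_human = 19L),
         expect = list(criterion = "iii"),
         chimp_range = c(2, 18), human_range = c(-6, 10)),
    list(cfg = di("M_CR_FAIL", repeats_chimp = 14L, repeats_human = 29L),
         expect = list(criterion = "fail"),
         chimp_range = c(2, 30), human_range = c(-4, 70)),
    list(cfg = tetra("M_CC_3REP", repeats_chimp = 3L, repeats_human = 12L),
         expect = list(concordance = "three_repeat_variant"),
         chimp_range = c(-4, 40), human_range = c(-12, 12)),
    list(cfg = tetra("M_CC_2REP", repeats_chimp = 2L, repeats_human = 12L),
         expect = list(concordance = "two_repeat_variant"),
         chimp_range = c(-4, 44), human_range = c(-12, 12)),
    list(cfg = tetra("M_CC_DISR", repeats_chimp = 12L, repeats_human = 12L,
                     disruption = "chimpanzee"),
         expect = list(concordance = "disrupted_variant"),
         chimp_range = c(-12, 12), human_range = c(-12, 12)),
    list(cfg = tetra("M_CC_DISC", repeats_chimp = 8L, repeats_human = 8L,
                     motif_chimp = "TACC", motif_human = "TGTC"),
         expect = list(concordance = "discordant"),
         chimp_range = c(-8, 8), human_range = c(-8, 8)),
    list(cfg = tetra("M_CC_NOSTR", repeats_chimp = 1L, repeats_human = 12L),
         expect = list(concordance = "no_str"),
         chimp_range = c(-4, 48), human_range = c(-12, 12))
  )
}

# Deterministic genotypes realizing an exact range [ref+lo, ref+hi] in unit
# steps: alleles cycle over the support and the first individual carries
# both endpoints.
.engineered_calls <- function(marker, ids, ref_len, rel_range, unit) {
  support <- seq(ref_len + rel_range[1], ref_len + rel_range[2], by = unit)
  n <- length(ids)
  a1 <- support[(seq_len(n) - 1L) %% length(support) + 1L]
  a2 <- support[seq_len(n) %% length(support) + 1L]
  a1[1L] <- support[1L]; a2[1L] <- support[length(support)]
  data.frame(id = ids, marker = marker, a1 = a1, a2 = a2)
}

#' Generate a complete self-contained synthetic study
#'
#' Builds reference FASTA pairs, a primer table, population samples with a
#' distance gradient, and diploid length genotypes: `n_core` concordant
#' loci with drifted genotypes plus (optionally) one engineered marker per
#' branch of the retention and ortholog-assessment decision trees, with the
#' expected branch labels recorded.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return List of class `orthosat_study`: `refs_chimp`, `refs_human`
#'   (named sequence vectors), `primers`, `genotypes`
#'   ([genotype_dataset()], length representation), `samples`, `distances`,
#'   `manifests` (per-marker truth), `expected` (per-marker expected branch
#'   labels), `config`, `seed`.
#' @export
make_study <- function(config = study_config(), seed = 1L) {
  set.seed(seed)
  units <- c(rep(3L, 31L), rep(4L, 86L), rep(4L, 21L))
  nregs <- c(rep(1L, 31L), rep(1L, 86L), rep(2L, 21L))
  idx <- seq_len(config$n_core)
  units <- units[(idx - 1L) %% length(units) + 1L]
  nregs <- nregs[(idx - 1L) %% length(nregs) + 1L]
  core_cfgs <- lapply(idx, function(i) {
    rh <- sample(10:18, 1L)
    rc <- max(4L, rh - config$species_offset)
    r2 <- sample(5:8, 1L)
    indels <- list()
    if (stats::runif(1) < config$indel_prob) {
      indels <- list(list(species = sample(c("chimpanzee", "human"), 1L),
                          size = sample.int(config$max_indel, 1L)))
    }
    ortholog_pair_config(sprintf("CORE%03d", i),
                         unit_size = units[i],
                         motif = if (units[i] == 3L) "AAT" else "GATA",
                         repeats_chimp = rc, repeats_human = rh,
                         n_str_regions = nregs[i],
                         repeats2_chimp = r2, repeats2_human = r2,
                         indels = indels)
  })
  branch <- if (config$with_branch_panel) .branch_specs() else list()

  refs_chimp <- character(0); refs_human <- character(0)
  primers <- list(); manifests <- list(); expected <- list()
  pair_seeds <- sample.int(2^30, config$n_core + length(branch))
  k <- 0L
  for (cfg in core_cfgs) {
    k <- k + 1L
    pair <- make_ortholog_pair(cfg, seed = pair_seeds[k])
    refs_chimp[cfg$marker] <- pair$chimp_seq
    refs_human[cfg$marker] <- pair$human_seq
    primers[[cfg$marker]] <- pair$primers
    manifests[[cfg$marker]] <- pair$manifest
  }
  for (br in branch) {
    k <- k + 1L
    pair <- make_ortholog_pair(br$cfg, seed = pair_seeds[k])
    marker <- br$cfg$marker
    chimp_ref <- pair$chimp_seq
    prim <- pair$primers
    if (isTRUE(br$corrupt_forward)) {
      set.seed(pair_seeds[k] + 1L)
      for (try in 1:25) {
        cand <- .nonrepetitive_dna(br$cfg$primer_len)
        if (length(scan_primer(cand, chimp_ref)) == 0L) break
      }
      prim$forward <- cand
    }
    if (isTRUE(br$duplicate_target)) {
      set.seed(pair_seeds[k] + 2L)
      chimp_ref <- paste0(chimp_ref, .nonrepetitive_dna(100L), chimp_ref)
    }
    if (isTRUE(br$extra_forward_site)) {
      set.seed(pair_seeds[k] + 3L)
      chimp_ref <- paste0(prim$forward, .nonrepetitive_dna(16L), chimp_ref)
    }
    refs_chimp[marker] <- chimp_ref
    refs_human[marker] <- pair$human_seq
    primers[[marker]] <- prim
    manifests[[marker]] <- pair$manifest
    expected[[marker]] <- br$expect
  }

  pops <- data.frame(
    name = c(sprintf("HUM%02d", seq_len(config$n_human_pops)),
             sprintf("CHI%02d", seq_len(config$n_chimp_pops))),
    species = c(rep("human", config$n_human_pops),
                rep("chimpanzee", config$n_chimp_pops)),
    n = config$n_per_pop,
    drift_f = c(config$f_human_base +
                  config$f_human_step * (seq_len(config$n_human_pops) - 1L),
                rep(config$f_chimp, config$n_chimp_pops)))
  core_manifests <- manifests[vapply(core_cfgs, `[[`, character(1), "marker")]
  genotypes <- simulate_genotypes(core_manifests, pops,
                                  seed = sample.int(2^30, 1L))
  if (length(branch) > 0L) {
    # engineered ranges for the branch markers, appended per species
    extra_calls <- list()
    for (br in branch) {
      marker <- br$cfg$marker
      mf <- manifests[[marker]]
      unit <- br$cfg$unit_size
      cid <- genotypes$samples$id[genotypes$samples$species == "chimpanzee"]
      hid <- genotypes$samples$id[genotypes$samples$species == "human"]
      extra_calls[[length(extra_calls) + 1L]] <- .engineered_calls(
        marker, cid, mf$ref_adjusted_length[["chimpanzee"]], br$chimp_range, unit)
      extra_calls[[length(extra_calls) + 1L]] <- .engineered_calls(
        marker, hid, mf$ref_adjusted_length[["human"]], br$human_range, unit)
    }
    calls <- rbind(genotypes$calls, do.call(rbind, extra_calls))
    truth <- attr(genotypes, "truth")
    genotypes <- genotype_dataset(genotypes$samples, calls, "length")
    attr(genotypes, "truth") <- truth
  }
  distances <- stats::setNames(
    c(500 * (seq_len(config$n_human_pops) - 1L)^1.2,
      rep(NA_real_, config$n_chimp_pops)),
    pops$name)
  structure(list(refs_chimp = refs_chimp, refs_human = refs_human,
                 primers = primers, genotypes = genotypes,
                 samples = genotypes$samples, distances = distances,
                 manifests = manifests, expected = expected,
                 config = config, seed = seed),
            class = "orthosat_study")
}

#' Write a study bundle to plain-text files
#'
#' @param study A [make_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$refs_chimp, file.path(dir, "refs_chimpanzee.fa"),
              species = rep("chimpanzee", length(study$refs_chimp)))
  write_fasta(study$refs_human, file.path(dir, "refs_human.fa"),
              species = rep("human", length(study$refs_human)))
  write_primer_table(study$primers, file.path(dir, "primers.tsv"))
  samples <- study$samples
  samples$distance_km <- unname(study$distances[match(
    samples$population, names(study$distances))])
  .write_tsv(samples, file.path(dir, "samples.tsv"), "samples")
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"), "long")
  jsonlite::write_json(
    list(seed = study$seed, config = study$config,
         expected = study$expected),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
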