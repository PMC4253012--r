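#' End-to-end study pipeline
#'
#' Runs the full chain on a study bundle: in-silico PCR with the retention
#' decision tree on the chimpanzee side, fragment selection on the human
#' side, interspecies range classification and ortholog assessment, STR
#' detection and structure concordance, STR-anchored alignment, calibration
#' of fragment lengths into repeat numbers at the concordant
#' single-unit-size loci, and the pairwise F_ST / D_PS inflation analysis
#' on both genotype representations. Every marker's fate is recorded in a
#' disposition ledger (each input marker appears exactly once).
#'
#' @name pipeline
NULL

.species_range <- function(dataset, marker, species) {
  sp_of <- stats::setNames(dataset$samples$species, dataset$samples$id)
  sub <- dataset$calls[dataset$calls$marker == marker &
                         sp_of[dataset$calls$id] == species, ]
  v <- c(sub$a1, sub$a2)
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NULL)
  length_range(min(v), max(v), species)
}

#' Run the whole analysis on a study bundle
#'
#' @param study An `orthosat_study` bundle from [make_study()], or a
#'   directory written by [write_study()].
#' @param min_repeats Minimum repeats for STR detection (default 4).
#' @param concordance_min_repeats Minimum repeats when re-deriving
#'   structures for concordance scoring (default 2, so two- and
#'   three-repeat variants are visible).
#' @param slack Retention slack in bp around observed ranges (default 6).
#' @param ros_threshold ROS acceptance threshold (default 0.289).
#' @param min_pop_size Minimum population size for the pairwise statistics.
#' @param resample Optional resampling spec for [variability_profile()]
#'   (`list(sets, size, seed)`); `NULL` profiles all individuals directly.
#' @return List of class `orthosat_result` with per-stage tables (see
#'   details in the package vignette), the repeat-number dataset, pairwise
#'   matrices on both representations, the inflation summaries, and the
#'   marker-disposition ledger.
#' @export
run_study <- function(study,
                      min_repeats = 4L, concordance_min_repeats = 2L,
                      slack = 6L, ros_threshold = 0.289,
                      min_pop_size = 5L, resample = NULL) {
  if (is.character(study)) study <- read_study(study)
  genotypes <- study$genotypes
  markers <- names(study$refs_chimp)
  stage_guard <- function(stage, marker, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed at marker %s: %s",
                   stage, marker, conditionMessage(e)), call. = FALSE)
    })
  }

  epcr_rows <- list(); assess_rows <- list(); conc_rows <- list()
  align_rows <- list(); ledger <- list(); models <- list()
  structures <- list()
  conversion <- character(0)
  add_ledger <- function(marker, stage, fate, reason) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      marker = marker, stage = stage, fate = fate, reason = reason)
  }

  for (marker in markers) {
    primers <- study$primers[[marker]]
    ## -- chimpanzee side: the retention decision tree
    dec <- stage_guard("epcr", marker, {
      crange <- .species_range(genotypes, marker, "chimpanzee")
      .assert(!is.null(crange), "no chimpanzee genotype data")
      fwd <- scan_primer(primers$forward, study$refs_chimp[[marker]], marker)
      rev <- scan_primer(primers$reverse, study$refs_chimp[[marker]], marker)
      frags <- demarcate_fragments(fwd, rev, study$refs_chimp[[marker]],
                                   marker, "chimpanzee")
      for (k in seq_along(frags)) {
        frags[[k]]$adjusted_length <- adjust_length(frags[[k]], primers)
      }
      d <- resolve_candidates(frags, crange, slack)
      d$marker <- marker
      d$range <- crange
      d
    })
    epcr_rows[[marker]] <- data.frame(
      marker = marker, outcome = dec$outcome,
      candidates = dec$candidates_considered,
      x_c = if (!is.null(dec$chosen_fragment)) dec$chosen_fragment$adjusted_length else NA_integer_,
      g = dec$range$lo, G = dec$range$hi, margin_bp = dec$margin_bp)
    if (!dec$outcome %in% c("retained", "resolved_overlap")) {
      add_ledger(marker, "epcr", paste0("rejected_", sub("^rejected_", "", dec$outcome)),
                 sprintf("chimpanzee ePCR %s", dec$outcome))
      next
    }
    chimp_frag <- dec$chosen_fragment

    ## -- human side: fragment selection (no length rejection; the human
    ## fragment is taken as given, nearest to the observed range)
    human_frag <- stage_guard("epcr", marker, {
      hrange <- .species_range(genotypes, marker, "human")
      .assert(!is.null(hrange), "no human genotype data")
      fwd <- scan_primer(primers$forward, study$refs_human[[marker]], marker)
      rev <- scan_primer(primers$reverse, study$refs_human[[marker]], marker)
      frags <- demarcate_fragments(fwd, rev, study$refs_human[[marker]],
                                   marker, "human")
      if (length(frags) == 0L) NULL else {
        for (k in seq_along(frags)) {
          frags[[k]]$adjusted_length <- adjust_length(frags[[k]], primers)
        }
        margins <- vapply(frags, function(f)
          retention_filter(f$adjusted_length, hrange, slack)$margin, integer(1))
        frags[[which.min(margins)]]
      }
    })
    if (is.null(human_frag)) {
      add_ledger(marker, "assessment", "no_human_fragment",
                 "no human ePCR fragment available")
      next
    }

    ## -- interspecies range classification and ortholog assessment
    crange <- dec$range
    hrange <- .species_range(genotypes, marker, "human")
    x_c <- chimp_frag$adjusted_length
    x_h <- human_frag$adjusted_length
    rc <- classify_ranges(crange, hrange)
    if (rc == "disjoint") {
      assess_rows[[marker]] <- data.frame(
        marker = marker, c = crange$lo, C = crange$hi,
        h = hrange$lo, H = hrange$hi, x_c = x_c, x_h = x_h,
        range_class = rc, ros = 0, criterion = "fail",
        retained = FALSE, reason = "possible regression/non-ortholog")
      add_ledger(marker, "assessment", "excluded_disjoint",
                 "chimpanzee and human ranges do not overlap")
      next
    }
    asm <- stage_guard("assessment", marker,
                       assess_lengths(x_c, x_h, crange, hrange,
                                      ros_threshold, slack, marker))
    assess_rows[[marker]] <- data.frame(
      marker = marker, c = crange$lo, C = crange$hi,
      h = hrange$lo, H = hrange$hi, x_c = x_c, x_h = x_h,
      range_class = rc, ros = asm$ros, criterion = asm$criterion,
      retained = asm$retained, reason = asm$reason)
    if (!asm$retained) {
      add_ledger(marker, "assessment", "excluded_assessment", asm$reason)
      next
    }

    ## -- STR structure, alignment, concordance
    conc <- stage_guard("concordance", marker, {
      cs2 <- find_str_regions(chimp_frag$sequence, concordance_min_repeats)
      hs2 <- find_str_regions(human_frag$sequence, concordance_min_repeats)
      aln <- align_orthologs(chimp_frag$sequence, human_frag$sequence,
                             cs2, hs2, marker)
      cmp <- compare_structures(cs2, hs2, chimp_frag$sequence,
                                human_frag$sequence, aln)
      list(cs2 = cs2, hs2 = hs2, aln = aln, cmp = cmp)
    })
    structures[[marker]] <- list(chimp = conc$cs2, human = conc$hs2)
    conc_rows[[marker]] <- data.frame(
      marker = marker, class = conc$cmp$class,
      affected_species = conc$cmp$affected_species, detail = conc$cmp$detail)
    align_rows[[marker]] <- data.frame(
      marker = marker, anchored = conc$aln$anchored,
      chimp_only_nonstr_nt = conc$aln$chimp_only_nonstr_nt,
      human_only_nonstr_nt = conc$aln$human_only_nonstr_nt)

    cls <- conc$cmp$class
    if (cls %in% c("discordant", "two_repeat_variant", "no_str")) {
      add_ledger(marker, "concordance", paste0("excluded_", cls), conc$cmp$detail)
      next
    }
    if (cls %in% c("three_repeat_variant", "disrupted_variant")) {
      add_ledger(marker, "concordance", paste0("retained_", cls),
                 "kept for diversity analyses; excluded from repeat conversion")
      next
    }

    ## -- calibration models for the concordant loci (single unit size)
    cunits <- vapply(conc$cs2$regions, `[[`, integer(1), "unit_size")
    hunits <- vapply(conc$hs2$regions, `[[`, integer(1), "unit_size")
    if (length(unique(c(cunits, hunits))) > 1L) {
      add_ledger(marker, "calibration", "retained_mixed_unit",
                 "mixed-unit excluded from repeat conversion")
      next
    }
    models[[marker]] <- stage_guard("calibration", marker, list(
      chimpanzee = build_model(chimp_frag, conc$cs2),
      human = build_model(human_frag, conc$hs2)))
    conversion <- c(conversion, marker)
    add_ledger(marker, "calibration", "converted",
               "same STR structure, single repeat-unit size")
  }

  ledger <- do.call(rbind, ledger)
  .assert(identical(sort(ledger$marker), sort(markers)),
          "disposition ledger does not conserve markers")

  ## -- conversion and population-genetic comparison
  he <- marker_heterozygosity(genotypes)
  result <- list(
    epcr = do.call(rbind, epcr_rows),
    assessment = do.call(rbind, assess_rows),
    concordance = do.call(rbind, conc_rows),
    alignment = do.call(rbind, align_rows),
    he = he, ledger = ledger,
    conversion_markers = conversion,
    models = models, structures = structures,
    params = list(min_repeats = min_repeats,
                  concordance_min_repeats = concordance_min_repeats,
                  slack = slack, ros_threshold = ros_threshold,
                  min_pop_size = min_pop_size),
    seed = study$seed)

  if (length(conversion) >= 1L) {
    sub_len <- .subset_loci(genotypes, conversion)
    norm <- normalize_dataset(sub_len, models)
    result$normalization <- norm$report
    result$repeats <- norm$dataset
    result$lengths <- sub_len
    pops_ok <- names(which(table(genotypes$samples$population) >= min_pop_size))
    if (length(pops_ok) >= 2L) {
      result$fst_length <- pairwise_fst(sub_len, min_pop_size)
      result$fst_repeats <- pairwise_fst(norm$dataset, min_pop_size)
      result$dps_length <- pairwise_dps(sub_len, min_pop_size)
      result$dps_repeats <- pairwise_dps(norm$dataset, min_pop_size)
      sp_labels <- stats::setNames(study$samples$species, study$samples$population)
      sp_labels <- sp_labels[!duplicated(names(sp_labels))]
      dist <- study$distances[!is.na(study$distances)]
      result$inflation_fst <- inflation_summary(result$fst_length,
                                                result$fst_repeats,
                                                sp_labels, dist)
      result$inflation_dps <- inflation_summary(result$dps_length,
                                                result$dps_repeats,
                                                sp_labels, dist)
    }
    if (!is.null(resample)) {
      result$profiles <- variability_profile(norm$dataset, sub_len, resample)
    }
  }
  structure(result, class = "orthosat_result")
}

.subset_loci <- function(dataset, loci) {
  genotype_dataset(dataset$samples,
                   dataset$calls[dataset$calls$marker %in% loci, ],
                   dataset$representation)
}

#' @export
print.orthosat_result <- function(x, ...) {
  cat(sprintf("<orthosat_result: %d markers in, %d converted to repeats>\n",
              nrow(x$ledger), length(x$conversion_markers)))
  print(table(x$ledger$fate))
  if (!is.null(x$inflation_fst)) print(x$inflation_fst)
  invisible(x)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir Directory containing the bundle files.
#' @return An `orthosat_study` list.
#' @export
read_study <- function(dir) {
  refs_c <- read_fasta(file.path(dir, "refs_chimpanzee.fa"))
  refs_h <- read_fasta(file.path(dir, "refs_human.fa"))
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  genotypes <- read_genotypes(file.path(dir, "genotypes.tsv"), samples, "long")
  distances <- if ("distance_km" %in% names(samples)) {
    d <- samples[!duplicated(samples$population), c("population", "distance_km")]
    stats::setNames(d$distance_km, d$population)
  } else NULL
  manifest <- if (file.exists(file.path(dir, "manifest.json"))) {
    jsonlite::read_json(file.path(dir, "manifest.json"))
  } else list()
  structure(list(refs_chimp = c(refs_c), refs_human = c(refs_h),
                 primers = read_primer_table(file.path(dir, "primers.tsv")),
                 genotypes = genotypes, samples = samples,
                 distances = distances,
                 manifests = list(), expected = manifest$expected,
                 config = manifest$config, seed = manifest$seed),
            class = "orthosat_study")
}

#' Write per-stage report tables
#'
#' Emits the stage TSVs (epcr, assessment, concordance, alignment,
#' heterozygosity, disposition ledger, normalization), the pairwise
#' matrices as square TSVs, the inflation summaries, and a machine-readable
#' run manifest (parameters + seed + package version).
#'
#' @param result An [run_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("epcr", "assessment", "concordance", "alignment", "he",
            "ledger", "normalization")
  for (nm in tabs) {
    if (!is.null(result[[nm]])) {
      .write_tsv(result[[nm]], file.path(dir, paste0(nm, ".tsv")), nm)
    }
  }
  for (nm in c("fst_length", "fst_repeats", "dps_length", "dps_repeats")) {
    m <- result[[nm]]
    if (is.null(m)) next
    df <- cbind(data.frame(population = m$populations), as.data.frame(m$values))
    .write_tsv(df, file.path(dir, paste0(nm, ".tsv")), nm)
  }
  for (nm in c("inflation_fst", "inflation_dps")) {
    s <- result[[nm]]
    if (is.null(s)) next
    .write_tsv(s$pairs, file.path(dir, paste0(nm, "_pairs.tsv")), nm)
  }
  jsonlite::write_json(
    list(params = result$params, seed = result$seed,
         package_version = as.character(utils::packageVersion("orthosat")),
         n_markers = nrow(result$ledger),
         n_converted = length(result$conversion_markers),
         inflation = list(
           fst = if (!is.null(result$inflation_fst))
             result$inflation_fst[c("max_reduction_pct", "mean_reduction_pct",
                                    "sd_reduction_pct", "r_squared")] else NULL,
           dps = if (!is.null(result$inflation_dps))
             result$inflation_dps[c("max_reduction_pct", "mean_reduction_pct",
                                    "sd_reduction_pct", "r_squared")] else NULL)),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
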