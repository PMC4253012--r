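#' Fragment-length to repeat-number calibration
#'
#' Under the assumption that within-species differences in PCR fragment
#' length are wholly due to repeat-number changes in the embedded STR
#' regions, a genotype's length maps affinely onto a total repeat number by
#' calibration against the species' own reference amplicon. Calibration is
#' species-specific by design: applying one species' model to the other's
#' genotypes is exactly the incommensurability the pipeline quantifies, so
#' it is refused.
#'
#' @name calibration
NULL

#' Build a calibration model from a reference fragment
#'
#' Only markers whose STR regions all share a single repeat-unit size can
#' be calibrated; with mixed unit sizes a length difference has no unique
#' repeat-number interpretation, and such markers are rejected.
#'
#' @param fragment The species' reference [epcr_fragment()] (its
#'   `adjusted_length` is the calibration anchor).
#' @param structure The fragment's [str_structure()]; must be non-empty.
#' @return A [calibration_model()].
#' @export
build_model <- function(fragment, structure) {
  .assert(length(structure$regions) > 0L,
          "%s: no STR regions; cannot calibrate", fragment$marker_name)
  units <- unique(vapply(structure$regions, `[[`, integer(1), "unit_size"))
  .assert(length(units) == 1L,
          "%s: mixed-unit excluded (repeat units of different sizes)",
          fragment$marker_name)
  calibration_model(marker = fragment$marker_name, species = fragment$species,
                    ref_adjusted_length = fragment$adjusted_length,
                    ref_total_repeats = total_repeats(structure),
                    unit_size = units)
}

#' Convert a fragment length to a repeat number
#'
#' @param L Fragment length in bp (> 0); may be a vector.
#' @param model A [calibration_model()].
#' @return Repeat number(s), possibly non-integer; fractional results are
#'   handled dataset-wide by [normalize_dataset()].
#' @export
length_to_repeats <- function(L, model) {
  .assert(all(L > 0, na.rm = TRUE), "lengths must be positive")
  model$ref_total_repeats + (L - model$ref_adjusted_length) / model$unit_size
}

#' Convert a repeat number back to a fragment length
#'
#' Exact inverse of [length_to_repeats()]; used to reconstruct length
#' datasets from repeat-number genotypes.
#'
#' @param R Repeat number(s) (>= 1).
#' @param model A [calibration_model()].
#' @return Fragment length(s) in bp.
#' @export
repeats_to_length <- function(R, model) {
  .assert(all(R >= 1, na.rm = TRUE), "repeat numbers must be >= 1")
  model$ref_adjusted_length + (R - model$ref_total_repeats) * model$unit_size
}

.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a length dataset to repeat numbers
#'
#' Each marker's alleles are converted with its own species' model. When
#' every converted value at a marker (pooled across species) shares one
#' common nonzero decimal fraction — the signature of a small constant
#' inaccuracy in a reference sequence or in genotype calls — all values are
#' rounded to the nearest integer (half away from zero). Markers showing
#' multiple distinct decimal fractions are left unadjusted. Integer-valued
#' markers pass through untouched.
#'
#' @param dataset A length-representation [genotype_dataset()].
#' @param models Named list: `models[[marker]][[species]]` is a
#'   [calibration_model()]. Markers without a model for every species
#'   present raise an error.
#' @param tol Tolerance when comparing decimal fractions.
#' @return List with `dataset` (repeats representation) and `report`
#'   (data frame: marker, status in `integer` / `common-fraction rounded` /
#'   `mixed-fraction unadjusted`).
#' @export
normalize_dataset <- function(dataset, models, tol = 1e-9) {
  .assert(dataset$representation == "length",
          "dataset is already in repeat representation")
  calls <- dataset$calls
  species_of <- stats::setNames(dataset$samples$species, dataset$samples$id)
  calls$species <- unname(species_of[calls$id])
  status <- character(0)
  for (marker in dataset$loci) {
    idx <- which(calls$marker == marker)
    for (sp in unique(calls$species[idx])) {
      m <- models[[marker]][[sp]]
      .assert(!is.null(m), "missing calibration model for %s in %s", marker, sp)
      k <- idx[calls$species[idx] == sp]
      calls$a1[k] <- length_to_repeats(calls$a1[k], m)
      calls$a2[k] <- length_to_repeats(calls$a2[k], m)
    }
    vals <- c(calls$a1[idx], calls$a2[idx])
    vals <- vals[!is.na(vals)]
    frac <- vals - floor(vals)
    frac_classes <- unique(.round_half_up(frac / tol) * tol)
    if (all(abs(frac) < tol | abs(frac - 1) < tol)) {
      status <- c(status, "integer")
    } else if (length(frac_classes) == 1L) {
      calls$a1[idx] <- .round_half_up(calls$a1[idx])
      calls$a2[idx] <- .round_half_up(calls$a2[idx])
      status <- c(status, "common-fraction rounded")
    } else {
      status <- c(status, "mixed-fraction unadjusted")
    }
  }
  calls$species <- NULL
  list(dataset = genotype_dataset(dataset$samples, calls, "repeats"),
       report = data.frame(marker = dataset$loci, status = status))
}
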