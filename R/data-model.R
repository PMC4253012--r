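#' Domain types for the ortholog-microsatellite pipeline
#'
#' Lightweight S3 records shared across the pipeline stages. Constructors
#' validate their invariants and return plain lists with a class attribute;
#' all coordinates are 0-based half-open internally and 1-based inclusive in
#' emitted reports (the convention is stated in every report header).
#'
#' @name orthosat-types
NULL

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

.is_dna <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) > 0L &&
    !grepl("[^ACGT]", x)
}

#' Primer pair record
#'
#' @param marker_name Marker identifier.
#' @param forward,reverse Primer sequences (5'->3', genomic portion only,
#'   over A/C/G/T).
#' @param forward_extra_bp,reverse_extra_bp Non-genomic tail length in bp:
#'   0 (unmodified), 1 (extra adenine, "M"), or 7 (pig-tail, "P"). At most
#'   one primer of a pair may carry a nonzero tail.
#' @param merge_offset Signed bp correction that was applied to genotypes
#'   when datasets were merged; it is reversed before range comparisons.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(marker_name, forward, reverse,
                        forward_extra_bp = 0L, reverse_extra_bp = 0L,
                        merge_offset = 0L) {
  .assert(is.character(marker_name) && nzchar(marker_name), "empty marker name")
  .assert(.is_dna(forward), "forward primer of %s is not a non-empty ACGT string", marker_name)
  .assert(.is_dna(reverse), "reverse primer of %s is not a non-empty ACGT string", marker_name)
  .assert(forward_extra_bp %in% c(0L, 1L, 7L) && reverse_extra_bp %in% c(0L, 1L, 7L),
          "extra-bp fields of %s must be 0, 1 or 7", marker_name)
  .assert(forward_extra_bp == 0L || reverse_extra_bp == 0L,
          "%s: at most one primer may carry a non-genomic tail", marker_name)
  structure(list(marker_name = marker_name,
                 forward = forward, reverse = reverse,
                 forward_extra_bp = as.integer(forward_extra_bp),
                 reverse_extra_bp = as.integer(reverse_extra_bp),
                 merge_offset = as.integer(merge_offset)),
            class = "primer_pair")
}

#' Primer alignment hit
#'
#' One accepted local alignment of a primer against a reference strand,
#' reported with the genomic position of the primer's 5'-terminal base.
#'
#' @param chromosome Reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param five_prime_pos 1-based position of the primer's 5' terminus.
#' @param alignment_length Alignment length in columns (the q_l quantity).
#' @param identity Fraction of matching columns in `[0, 1]` (the q_i quantity).
#' @param primer_length Genomic primer length in nt (the p_l quantity).
#' @return An object of class `primer_hit`.
#' @export
primer_hit <- function(chromosome, strand, five_prime_pos,
                       alignment_length, identity, primer_length) {
  .assert(strand %in% c("+", "-"), "strand must be + or -")
  .assert(alignment_length <= primer_length + 10L,
          "alignment length %d implausible for primer of %d nt",
          alignment_length, primer_length)
  .assert(identity >= 0 && identity <= 1, "identity must lie in [0,1]")
  structure(list(chromosome = chromosome, strand = strand,
                 five_prime_pos = as.integer(five_prime_pos),
                 alignment_length = as.integer(alignment_length),
                 identity = identity,
                 primer_length = as.integer(primer_length)),
            class = "primer_hit")
}

.minimal_period <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(motif, 1L, d), u %/% d) == motif) return(d)
  }
  u
}

#' STR region within an amplicon
#'
#' @param start,end 0-based half-open offsets within the fragment.
#' @param motif Repeat unit (2-6 nt; must not itself be a whole-number
#'   repetition of a shorter motif).
#' @param repeat_count Number of contiguous copies.
#' @return An object of class `str_region`.
#' @export
str_region <- function(start, end, motif, repeat_count) {
  unit_size <- nchar(motif)
  .assert(.is_dna(motif), "motif must be a non-empty ACGT string")
  .assert(unit_size >= 2L && unit_size <= 6L, "unit size must be 2-6 nt")
  .assert(.minimal_period(motif) == unit_size,
          "motif %s is a repetition of a shorter motif", motif)
  .assert(end - start == unit_size * repeat_count,
          "span %d-%d inconsistent with %d copies of %s", start, end, repeat_count, motif)
  structure(list(start = as.integer(start), end = as.integer(end),
                 motif = motif, unit_size = as.integer(unit_size),
                 repeat_count = as.integer(repeat_count)),
            class = "str_region")
}

#' STR structure of an amplicon
#'
#' Ordered, non-overlapping STR regions plus the nucleotide gaps (spacers)
#' separating consecutive regions. Abutting regions with different motifs
#' (compound repeats) are permitted, so spacers may be 0.
#'
#' @param regions List of [str_region()] objects sorted by start.
#' @return An object of class `str_structure`.
#' @export
str_structure <- function(regions = list()) {
  if (length(regions) > 1L) {
    starts <- vapply(regions, `[[`, integer(1), "start")
    ends <- vapply(regions, `[[`, integer(1), "end")
    .assert(!is.unsorted(starts, strictly = TRUE), "regions must be sorted by start")
    .assert(all(starts[-1L] >= ends[-length(ends)]), "regions overlap")
    spacers <- as.integer(starts[-1L] - ends[-length(ends)])
  } else {
    spacers <- integer(0)
  }
  structure(list(regions = regions, spacers = spacers), class = "str_structure")
}

#' @export
print.str_structure <- function(x, ...) {
  if (length(x$regions) == 0L) {
    cat("<str_structure: no STR regions>\n")
    return(invisible(x))
  }
  cat(sprintf("<str_structure: %d region(s)>\n", length(x$regions)))
  for (r in x$regions) {
    cat(sprintf("  [%d,%d) (%s)x%d\n", r$start, r$end, r$motif, r$repeat_count))
  }
  invisible(x)
}

#' In-silico PCR fragment
#'
#' @param marker_name Marker identifier.
#' @param chromosome Reference sequence name.
#' @param sequence Amplicon sequence (A/C/G/T).
#' @param adjusted_length Fragment length after primer-tail addition and
#'   merge-offset reversal (the x quantity; x_c or x_h when species-tagged).
#' @param species `"human"` or `"chimpanzee"`.
#' @param start 1-based position of the fragment's first base in the
#'   reference (optional bookkeeping).
#' @return An object of class `epcr_fragment` with `raw_length` equal to
#'   `nchar(sequence)`.
#' @export
epcr_fragment <- function(marker_name, chromosome, sequence,
                          adjusted_length = nchar(sequence),
                          species = c("chimpanzee", "human"),
                          start = NA_integer_) {
  species <- match.arg(species)
  .assert(.is_dna(sequence), "fragment sequence of %s is not ACGT", marker_name)
  structure(list(marker_name = marker_name, chromosome = chromosome,
                 sequence = sequence,
                 raw_length = nchar(sequence),
                 adjusted_length = as.integer(adjusted_length),
                 species = species, start = as.integer(start)),
            class = "epcr_fragment")
}

#' Observed fragment-length (or repeat-number) range
#'
#' Closed integer interval `[lo, hi]`; houses the g/G, c/C and h/H range
#' endpoints of the retention decision trees.
#'
#' @param lo,hi Interval endpoints, `lo <= hi`.
#' @param species Optional species tag.
#' @return An object of class `length_range`.
#' @export
length_range <- function(lo, hi, species = NA_character_) {
  .assert(lo <= hi, "range lo %s > hi %s", lo, hi)
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi), species = species),
            class = "length_range")
}

#' Per-locus, per-species calibration between fragment length and repeats
#'
#' @param marker Marker name.
#' @param species Species tag.
#' @param ref_adjusted_length Adjusted ePCR fragment length of the species'
#'   reference sequence, in bp.
#' @param ref_total_repeats Total repeats across all STR regions of the
#'   reference sequence.
#' @param unit_size Repeat unit size in nt (all regions must share it).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(marker, species, ref_adjusted_length,
                              ref_total_repeats, unit_size) {
  .assert(unit_size >= 2L && unit_size <= 6L, "unit size must be 2-6 nt")
  .assert(ref_total_repeats >= 1L, "reference must contain at least one repeat")
  structure(list(marker = marker, species = species,
                 ref_adjusted_length = as.numeric(ref_adjusted_length),
                 ref_total_repeats = as.integer(ref_total_repeats),
                 unit_size = as.integer(unit_size)),
            class = "calibration_model")
}

#' Diploid genotype dataset
#'
#' @param samples Data frame with columns `id`, `population`, `species` and
#'   optionally `distance_km` (one row per individual; every population must
#'   map to exactly one species).
#' @param calls Data frame with columns `id`, `marker`, `a1`, `a2`; allele
#'   values are bp lengths or repeat numbers, stored sorted ascending
#'   (unordered pairs), `NA` for missing.
#' @param representation `"length"` or `"repeats"`.
#' @return An object of class `genotype_dataset` with a `loci` element
#'   listing marker names in first-appearance order.
#' @export
genotype_dataset <- function(samples, calls, representation = c("length", "repeats")) {
  representation <- match.arg(representation)
  .assert(all(c("id", "population", "species") %in% names(samples)),
          "samples sheet needs id, population, species columns")
  .assert(all(c("id", "marker", "a1", "a2") %in% names(calls)),
          "calls need id, marker, a1, a2 columns")
  ps <- unique(samples[, c("population", "species")])
  .assert(!anyDuplicated(ps$population),
          "a population maps to more than one species")
  .assert(all(calls$id %in% samples$id), "calls reference unknown individuals")
  ok <- is.na(calls$a1) == is.na(calls$a2)
  .assert(all(ok), "half-missing genotypes are not allowed")
  present <- !is.na(calls$a1)
  .assert(all(calls$a1[present] > 0 & calls$a2[present] > 0),
          "allele values must be strictly positive when present")
  # store unordered pairs sorted ascending for deterministic output
  swap <- present & calls$a1 > calls$a2
  if (any(swap)) {
    tmp <- calls$a1[swap]
    calls$a1[swap] <- calls$a2[swap]
    calls$a2[swap] <- tmp
  }
  structure(list(samples = samples, calls = calls,
                 loci = unique(calls$marker),
                 representation = representation),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset: %d individuals, %d populations, %d loci, %s representation>\n",
              nrow(x$samples), length(unique(x$samples$population)),
              length(x$loci), x$representation))
  invisible(x)
}

#' Symmetric pairwise-statistic matrix
#'
#' @param populations Ordered population names.
#' @param values Symmetric numeric matrix.
#' @param statistic `"FST"` or `"DPS"`.
#' @param representation Genotype representation the matrix was computed from.
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(populations, values, statistic = c("FST", "DPS"),
                            representation = c("length", "repeats")) {
  statistic <- match.arg(statistic)
  representation <- match.arg(representation)
  .assert(is.matrix(values) && nrow(values) == length(populations) &&
            ncol(values) == length(populations), "matrix dimensions mismatch")
  .assert(isTRUE(all.equal(values, t(values), tolerance = 1e-12)),
          "matrix must be symmetric")
  if (statistic == "DPS") {
    .assert(all(diag(values) == 0), "DPS diagonal must be 0")
    .assert(all(values >= 0 & values <= 1), "DPS entries must lie in [0,1]")
  }
  dimnames(values) <- list(populations, populations)
  structure(list(populations = populations, values = values,
                 statistic = statistic, representation = representation),
            class = "pairwise_matrix")
}
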