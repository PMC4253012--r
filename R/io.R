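#' Readers and writers for the pipeline's external formats
#'
#' All tabular formats are tab-separated with a header; writers emit a
#' leading comment line `#orthosat <format> v1 coords=1-based-inclusive`.
#' Missing genotypes are coded -9 on write; -9 and blank are accepted on
#' read.
#'
#' @name orthosat-io
NULL

MISSING_CODE <- -9

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.format_header <- function(format) {
  sprintf("#orthosat %s v1 coords=1-based-inclusive", format)
}

.write_tsv <- function(df, path, format) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.format_header(format), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer-pair table
#'
#' Expects tab-separated columns `marker`, `forward`, `reverse`, `mod_flag`,
#' `merge_offset`. `mod_flag` is `none`, `P` (7-bp pig-tail) or `M` (single
#' extra adenine) and applies to the reverse primer, the primer such
#' modifications are conventionally placed on.
#'
#' @param path Path to the TSV file.
#' @return A named list of [primer_pair()] objects, one per marker.
#' @export
read_primer_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("marker", "forward", "reverse", "mod_flag")
  .assert(all(need %in% names(df)), "primer table needs columns %s",
          paste(need, collapse = ", "))
  if (is.null(df$merge_offset)) df$merge_offset <- 0L
  .assert(!anyDuplicated(df$marker), "duplicate marker names in primer table")
  out <- lapply(seq_len(nrow(df)), function(i) {
    flag <- df$mod_flag[i]
    .assert(flag %in% c("none", "P", "M"), "unknown modification flag '%s'", flag)
    extra <- c(none = 0L, P = 7L, M = 1L)[[flag]]
    primer_pair(df$marker[i],
                toupper(df$forward[i]), toupper(df$reverse[i]),
                forward_extra_bp = 0L, reverse_extra_bp = extra,
                merge_offset = as.integer(df$merge_offset[i]))
  })
  names(out) <- df$marker
  out
}

#' Write a primer-pair table
#'
#' Inverse of [read_primer_table()]; re-reading the written file reproduces
#' the same records.
#'
#' @param primers Named list of [primer_pair()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  df <- do.call(rbind, lapply(primers, function(p) {
    flag <- if (p$reverse_extra_bp == 7L) "P" else if (p$reverse_extra_bp == 1L) "M" else "none"
    data.frame(marker = p$marker_name, forward = p$forward, reverse = p$reverse,
               mod_flag = flag, merge_offset = p$merge_offset)
  }))
  .write_tsv(df, path, "primers")
}

#' Read reference amplicon sequences from FASTA
#'
#' Record ids are marker names with an optional `|species` suffix.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences; when species
#'   suffixes are present the `species` attribute carries them (same order).
#' @export
read_fasta <- function(path) {
  # read as raw strings so invalid letters (e.g. RNA's U) are rejected here
  # rather than silently dropped by alphabet coercion
  set <- Biostrings::readBStringSet(path)
  .assert(length(set) > 0L, "empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  species <- ifelse(grepl("\\|", ids), sub("^.*\\|", "", ids), NA_character_)
  markers <- sub("\\|.*$", "", ids)
  .assert(!anyDuplicated(ids), "duplicate record ids in %s", path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  .assert(!any(bad), "non-ACGT characters in FASTA records: %s",
          paste(markers[bad], collapse = ", "))
  names(seqs) <- markers
  attr(seqs, "species") <- species
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences. When `species` is given,
#'   ids are written as `marker|species`.
#' @param path Output path.
#' @param species Optional character vector of species tags.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, species = NULL) {
  ids <- names(seqs)
  if (!is.null(species)) ids <- paste(ids, species, sep = "|")
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `id`, `population`, `species` and optionally
#'   `distance_km`.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- .read_tsv(path)
  .assert(all(c("id", "population", "species") %in% names(df)),
          "sample sheet needs id, population, species columns")
  df
}

.decode_allele <- function(x) {
  x <- as.character(x)
  x[x == "" | is.na(x)] <- as.character(MISSING_CODE)
  v <- suppressWarnings(as.numeric(x))
  .assert(!anyNA(v), "non-numeric allele value in genotype file")
  v[v == MISSING_CODE] <- NA_real_
  .assert(all(is.na(v) | v > 0), "allele value <= 0 that is not the missing code")
  v
}

#' Read a diploid genotype file
#'
#' Two dialects are supported. `"long"`: one row per individual x locus with
#' columns `id`, `population`, `marker`, `a1`, `a2`. `"structure"`: two rows
#' per individual (one per haploid complement), first columns `id` and
#' `population`, then one column per locus. Missing alleles are coded -9 or
#' left blank.
#'
#' @param path Genotype TSV path.
#' @param samples Sample sheet data frame (see [read_sample_sheet()]);
#'   supplies population/species labels.
#' @param dialect `"long"` or `"structure"`.
#' @param representation `"length"` or `"repeats"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, samples, dialect = c("long", "structure"),
                           representation = c("length", "repeats")) {
  dialect <- match.arg(dialect)
  representation <- match.arg(representation)
  df <- .read_tsv(path)
  if (dialect == "long") {
    .assert(all(c("id", "marker", "a1", "a2") %in% names(df)),
            "long dialect needs id, marker, a1, a2 columns")
    calls <- data.frame(id = as.character(df$id), marker = df$marker,
                        a1 = .decode_allele(df$a1), a2 = .decode_allele(df$a2),
                        stringsAsFactors = FALSE)
  } else {
    .assert(nrow(df) %% 2L == 0L, "structure-like file must have an even row count")
    meta_cols <- intersect(c("id", "population"), names(df))
    loci <- setdiff(names(df), meta_cols)
    odd <- seq(1L, nrow(df), by = 2L)
    .assert(all(df$id[odd] == df$id[odd + 1L]),
            "structure-like rows must pair by individual")
    calls <- do.call(rbind, lapply(odd, function(i) {
      data.frame(id = as.character(df$id[i]), marker = loci,
                 a1 = .decode_allele(unlist(df[i, loci])),
                 a2 = .decode_allele(unlist(df[i + 1L, loci])),
                 stringsAsFactors = FALSE)
    }))
  }
  # half-missing pairs are collapsed to missing on read
  half <- xor(is.na(calls$a1), is.na(calls$a2))
  calls$a1[half] <- NA_real_
  calls$a2[half] <- NA_real_
  genotype_dataset(samples, calls, representation)
}

#' Write a diploid genotype file
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path.
#' @param dialect `"long"` or `"structure"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, dialect = c("long", "structure")) {
  dialect <- match.arg(dialect)
  calls <- dataset$calls
  pop <- stats::setNames(dataset$samples$population, dataset$samples$id)
  if (dialect == "long") {
    df <- data.frame(id = calls$id, population = unname(pop[calls$id]),
                     marker = calls$marker,
                     a1 = ifelse(is.na(calls$a1), MISSING_CODE, calls$a1),
                     a2 = ifelse(is.na(calls$a2), MISSING_CODE, calls$a2))
    return(.write_tsv(df, path, "genotypes-long"))
  }
  loci <- dataset$loci
  ids <- unique(calls$id)
  enc <- function(v) ifelse(is.na(v), MISSING_CODE, v)
  rows <- lapply(ids, function(ind) {
    sub <- calls[calls$id == ind, ]
    a1 <- stats::setNames(rep(MISSING_CODE, length(loci)), loci)
    a2 <- a1
    a1[sub$marker] <- enc(sub$a1)
    a2[sub$marker] <- enc(sub$a2)
    rbind(c(id = ind, population = unname(pop[ind]), a1),
          c(id = ind, population = unname(pop[ind]), a2))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  .write_tsv(df, path, "genotypes-structure")
}

#' Read per-population geographic distances
#'
#' @param path TSV with columns `population`, `distance_km`.
#' @return A named numeric vector of distances (km).
#' @export
read_distances <- function(path) {
  df <- .read_tsv(path)
  .assert(all(c("population", "distance_km") %in% names(df)),
          "distance table needs population, distance_km columns")
  .assert(all(df$distance_km >= 0), "distances must be non-negative")
  stats::setNames(df$distance_km, df$population)
}
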