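#' STR region detection and interspecies structure comparison
#'
#' An STR region is a run of at least `min_repeats` contiguous copies of a
#' 2-6 nt motif. Any interruption of one base pair or greater terminates a
#' region; runs on either side of an interruption are separate regions and
#' are kept only if each reaches `min_repeats` copies. Motifs that are a
#' whole-number repetition of a shorter motif (including homopolymers) are
#' reported at the shortest unit size only.
#'
#' @name str-detection
NULL

#' Detect STR regions in a sequence
#'
#' Enumerates every maximally extended run of every 2-6 nt motif at every
#' start, then resolves overlapping candidate calls deterministically:
#' longer span first, then smaller unit size, then leftmost start.
#'
#' @param sequence DNA string (A/C/G/T).
#' @param min_repeats Minimum number of contiguous copies (4 for detection,
#'   2 when scoring interspecies concordance).
#' @param unit_sizes Integer vector of motif lengths to consider.
#' @return An [str_structure()] with regions sorted by start (0-based
#'   half-open coordinates).
#' @export
find_str_regions <- function(sequence, min_repeats = 4L, unit_sizes = 2:6) {
  .assert(is.character(sequence) && length(sequence) == 1L, "sequence must be a string")
  sequence <- toupper(sequence)
  .assert(!grepl("[^ACGT]", sequence), "non-ACGT characters in sequence")
  .assert(all(unit_sizes >= 2L & unit_sizes <= 6L), "unit sizes must lie in 2..6")
  n <- nchar(sequence)
  .assert(n >= min_repeats * min(unit_sizes),
          "sequence shorter than %d copies of a %d-mer", min_repeats, min(unit_sizes))
  chars <- strsplit(sequence, "")[[1]]

  cand_start <- integer(0); cand_unit <- integer(0); cand_copies <- integer(0)
  for (u in sort(unique(as.integer(unit_sizes)))) {
    m <- n - u
    if (m < 1L) next
    eq <- chars[seq_len(m)] == chars[seq_len(m) + u]
    # run[i]: length of the TRUE run in eq starting at i
    run <- integer(m)
    acc <- 0L
    for (i in m:1L) {
      acc <- if (eq[i]) acc + 1L else 0L
      run[i] <- acc
    }
    copies <- run %/% u + 1L
    keep <- which(copies >= min_repeats)
    if (length(keep) == 0L) next
    motifs <- substring(sequence, keep, keep + u - 1L)
    prim <- vapply(motifs, function(mo) .minimal_period(mo) == u, logical(1))
    keep <- keep[prim]
    if (length(keep) == 0L) next
    cand_start <- c(cand_start, keep)
    cand_unit <- c(cand_unit, rep(u, length(keep)))
    cand_copies <- c(cand_copies, copies[keep])
  }
  if (length(cand_start) == 0L) return(str_structure())

  span <- cand_unit * cand_copies
  ord <- order(-span, cand_unit, cand_start)
  sel_start <- integer(0); sel_end <- integer(0); sel_idx <- integer(0)
  for (k in ord) {
    s <- cand_start[k]; e <- s + span[k] - 1L
    if (any(s <= sel_end & e >= sel_start)) next
    sel_start <- c(sel_start, s); sel_end <- c(sel_end, e); sel_idx <- c(sel_idx, k)
  }
  o <- order(sel_start)
  regions <- lapply(sel_idx[o], function(k) {
    s <- cand_start[k]
    str_region(start = s - 1L, end = s - 1L + span[k],
               motif = substr(sequence, s, s + cand_unit[k] - 1L),
               repeat_count = cand_copies[k])
  })
  str_structure(regions)
}

.rotations <- function(motif) {
  u <- nchar(motif)
  vapply(seq_len(u), function(r) {
    paste0(substr(motif, r, u), substr(motif, 1L, r - 1L))
  }, character(1))
}

.rotation_equivalent <- function(a, b) {
  nchar(a) == nchar(b) && b %in% .rotations(a)
}

#' Shift STR-region boundaries onto a common motif
#'
#' Where two regions of a structure have rotationally equivalent motifs
#' (e.g. ATCT and TCTA) and a phase shift supported by the sequence keeps
#' each region's repeat count unchanged, later regions are re-phased to the
#' first region's motif. Regions remain non-overlapping; when no valid shift
#' exists the structure is returned unchanged (no-op).
#'
#' @param structure An [str_structure()] produced by [find_str_regions()]
#'   on `sequence`.
#' @param sequence The same DNA string.
#' @return An [str_structure()] with identical repeat counts.
#' @export
harmonize_boundaries <- function(structure, sequence) {
  regions <- structure$regions
  if (length(regions) < 2L) return(structure)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  for (i in seq_along(regions)[-1L]) {
    r <- regions[[i]]
    canon <- NULL
    for (j in seq_len(i - 1L)) {
      prev <- regions[[j]]
      if (prev$unit_size == r$unit_size &&
          .rotation_equivalent(prev$motif, r$motif) &&
          prev$motif != r$motif) {
        canon <- prev$motif
        break
      }
    }
    if (is.null(canon)) next
    span <- r$unit_size * r$repeat_count
    target <- strrep(canon, r$repeat_count)
    # try small phase shifts first; 0 is a no-op for a differing motif
    u <- r$unit_size
    deltas <- as.integer(unlist(lapply(seq_len(u - 1L), function(d) c(d, -d))))
    for (delta in deltas) {
      s0 <- r$start + delta          # 0-based
      e0 <- s0 + span
      if (s0 < 0L || e0 > n) next
      prev_end <- if (i > 1L) regions[[i - 1L]]$end else 0L
      next_start <- if (i < length(regions)) regions[[i + 1L]]$start else n
      if (s0 < prev_end || e0 > next_start) next
      if (substr(sequence, s0 + 1L, e0) == target) {
        regions[[i]] <- str_region(s0, e0, canon, r$repeat_count)
        break
      }
    }
  }
  str_structure(regions)
}

#' Total repeats across all STR regions
#'
#' @param structure An [str_structure()].
#' @return Integer sum of `repeat_count` over regions; 0 when empty.
#' @export
total_repeats <- function(structure) {
  if (length(structure$regions) == 0L) return(0L)
  sum(vapply(structure$regions, `[[`, integer(1), "repeat_count"))
}

#' Interspecies STR-structure concordance
#'
#' Classifies a pair of STR structures derived (with `min_repeats = 2` so
#' that two- and three-repeat variants are visible) from a chimpanzee and a
#' human amplicon of the same putative ortholog:
#' \describe{
#'   \item{identical}{same region count, order-paired regions share unit
#'     size and (rotation-equivalent) motif, all counts >= 4.}
#'   \item{three_repeat_variant}{an order-paired region has exactly 3 copies
#'     in one or both species (none has 2).}
#'   \item{two_repeat_variant}{an order-paired region has exactly 2 copies
#'     in one or both species.}
#'   \item{disrupted_variant}{one species' single region corresponds to two
#'     regions in the other separated by a short (<= `max_interruption` nt)
#'     interruption, as left by a point or small indel mutation.}
#'   \item{discordant}{different motifs at corresponding positions, or
#'     region sets that cannot be paired.}
#'   \item{no_str}{one species has no STR regions at all.}
#' }
#'
#' @param chimp,human [str_structure()] objects (use `min_repeats = 2`).
#' @param chimp_seq,human_seq The amplicon sequences the structures came from.
#' @param alignment Optional [align_orthologs()] result; when supplied it
#'   must cover both sequences.
#' @param max_interruption Maximum interruption, nt, for the disrupted call.
#' @return A list of class `structure_concordance` with elements `class`,
#'   `affected_species` and `detail`.
#' @export
compare_structures <- function(chimp, human, chimp_seq, human_seq,
                               alignment = NULL, max_interruption = 6L) {
  if (!is.null(alignment)) {
    cov_c <- sum(strsplit(alignment$aligned_chimp, "")[[1]] != "-")
    cov_h <- sum(strsplit(alignment$aligned_human, "")[[1]] != "-")
    .assert(cov_c == nchar(chimp_seq) && cov_h == nchar(human_seq),
            "alignment does not cover both sequences")
  }
  chimp <- harmonize_boundaries(chimp, chimp_seq)
  human <- harmonize_boundaries(human, human_seq)
  nc <- length(chimp$regions); nh <- length(human$regions)
  res <- function(class, affected, detail = "") {
    structure(list(class = class, affected_species = affected, detail = detail),
              class = "structure_concordance")
  }
  if (nc == 0L || nh == 0L) {
    return(res("no_str", "none",
               sprintf("chimpanzee has %d regions, human %d", nc, nh)))
  }

  if (nc == nh) {
    pairs_ok <- vapply(seq_len(nc), function(i) {
      a <- chimp$regions[[i]]; b <- human$regions[[i]]
      a$unit_size == b$unit_size && .rotation_equivalent(a$motif, b$motif)
    }, logical(1))
    if (!all(pairs_ok)) {
      bad <- which(!pairs_ok)[1]
      return(res("discordant", "both",
                 sprintf("region %d motifs %s/%s differ", bad,
                         chimp$regions[[bad]]$motif, human$regions[[bad]]$motif)))
    }
    cc <- vapply(chimp$regions, `[[`, integer(1), "repeat_count")
    hc <- vapply(human$regions, `[[`, integer(1), "repeat_count")
    short <- function(k) cc == k | hc == k
    affected_of <- function(k) {
      c_has <- any(cc == k); h_has <- any(hc == k)
      if (c_has && h_has) "both" else if (c_has) "chimpanzee" else "human"
    }
    if (any(short(2))) {
      return(res("two_repeat_variant", affected_of(2),
                 "an order-paired region has exactly 2 repeats"))
    }
    if (any(short(3))) {
      return(res("three_repeat_variant", affected_of(3),
                 "an order-paired region has exactly 3 repeats"))
    }
    return(res("identical", "none", "same STR structure"))
  }

  if (abs(nc - nh) == 1L) {
    if (nc > nh) {
      more <- chimp; fewer <- human; split_species <- "chimpanzee"
    } else {
      more <- human; fewer <- chimp; split_species <- "human"
    }
    nm <- length(more$regions)
    for (j in seq_len(nm - 1L)) {
      a1 <- more$regions[[j]]; a2 <- more$regions[[j + 1L]]
      gap <- a2$start - a1$end
      if (gap > max_interruption) next
      if (a1$unit_size != a2$unit_size ||
          !.rotation_equivalent(a1$motif, a2$motif)) next
      b <- fewer$regions[[j]]
      if (b$unit_size != a1$unit_size ||
          !.rotation_equivalent(a1$motif, b$motif)) next
      others <- vapply(seq_len(nm), function(i) {
        if (i %in% c(j, j + 1L)) return(TRUE)
        bi <- if (i < j) i else i - 1L
        bb <- fewer$regions[[bi]]
        ai <- more$regions[[i]]
        ai$unit_size == bb$unit_size && .rotation_equivalent(ai$motif, bb$motif)
      }, logical(1))
      if (all(others)) {
        return(res("disrupted_variant", split_species,
                   sprintf("region split by a %d-nt interruption in the %s fragment",
                           gap, split_species)))
      }
    }
  }
  res("discordant", "both",
      sprintf("region sets cannot be paired (%d vs %d regions)", nc, nh))
}
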