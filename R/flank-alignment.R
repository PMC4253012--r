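#' STR-anchored pairwise alignment of orthologous amplicons
#'
#' Aligns a chimpanzee and a human amplicon of the same putative ortholog.
#' STR regions with identical (harmonized) motifs are paired in order and
#' aligned unit by unit, with surplus repeat units of the longer array
#' gapped as whole units; only repeat units with identical motifs may align
#' within an STR region. Flank segments between anchors are aligned
#' globally with affine gap penalties (match +1, mismatch -1, gap open -3,
#' gap extend -1). All indels are treated as insertions in the respective
#' fragment, and gaps are kept outside STR blocks by construction.
#'
#' @name flank-alignment
NULL

.global_align <- function(a, b) {
  if (nchar(a) == 0L && nchar(b) == 0L) return(list(a = "", b = ""))
  if (nchar(a) == 0L) return(list(a = strrep("-", nchar(b)), b = b))
  if (nchar(b) == 0L) return(list(a = a, b = strrep("-", nchar(a))))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global", substitutionMatrix = .nuc_mat(),
    gapOpening = 2, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# Pair STR regions of the two structures in order, allowing a two-into-one
# grouping where a short interruption split a region in one species.
.pair_anchors <- function(cr, hr, max_interruption = 6L) {
  groups <- list()
  i <- 1L; j <- 1L
  while (i <= length(cr) && j <= length(hr)) {
    a <- cr[[i]]; b <- hr[[j]]
    if (a$unit_size == b$unit_size && .rotation_equivalent(a$motif, b$motif)) {
      two_c <- i < length(cr) &&
        cr[[i + 1L]]$unit_size == b$unit_size &&
        .rotation_equivalent(cr[[i + 1L]]$motif, b$motif) &&
        (cr[[i + 1L]]$start - a$end) <= max_interruption &&
        !(j < length(hr) && hr[[j + 1L]]$unit_size == a$unit_size &&
            .rotation_equivalent(hr[[j + 1L]]$motif, a$motif))
      two_h <- j < length(hr) &&
        hr[[j + 1L]]$unit_size == a$unit_size &&
        .rotation_equivalent(hr[[j + 1L]]$motif, a$motif) &&
        (hr[[j + 1L]]$start - b$end) <= max_interruption &&
        !(i < length(cr) && cr[[i + 1L]]$unit_size == b$unit_size &&
            .rotation_equivalent(cr[[i + 1L]]$motif, b$motif))
      if (two_c) {
        groups[[length(groups) + 1L]] <- list(chimp = c(i, i + 1L), human = j)
        i <- i + 2L; j <- j + 1L
      } else if (two_h) {
        groups[[length(groups) + 1L]] <- list(chimp = i, human = c(j, j + 1L))
        i <- i + 1L; j <- j + 2L
      } else {
        groups[[length(groups) + 1L]] <- list(chimp = i, human = j)
        i <- i + 1L; j <- j + 1L
      }
    } else {
      return(NULL)  # anchor ordering/motif conflict
    }
  }
  if (i <= length(cr) || j <= length(hr)) return(NULL)
  groups
}

# Unit-wise alignment of an anchor group. Each side is tokenized in
# sequence order into repeat units and interruption blocks; units pair
# one-to-one, interruption bases align against gaps at their genomic
# position (insertions in the split species' fragment), and surplus units
# of the longer array are gapped as whole units.
.align_anchor_group <- function(cseq, hseq, cregs, hregs) {
  tokenize <- function(seq, regs) {
    toks <- list()
    for (k in seq_along(regs)) {
      r <- regs[[k]]
      starts <- r$start + seq(1L, r$unit_size * r$repeat_count, by = r$unit_size)
      for (s in starts) {
        toks[[length(toks) + 1L]] <- list(type = "U",
                                          text = substr(seq, s, s + r$unit_size - 1L))
      }
      if (k < length(regs) && regs[[k + 1L]]$start > r$end) {
        toks[[length(toks) + 1L]] <- list(
          type = "I", text = substr(seq, r$end + 1L, regs[[k + 1L]]$start))
      }
    }
    toks
  }
  ta <- tokenize(cseq, cregs)
  tb <- tokenize(hseq, hregs)
  a <- character(0); b <- character(0)
  i <- 1L; j <- 1L
  while (i <= length(ta) || j <= length(tb)) {
    if (i <= length(ta) && ta[[i]]$type == "I") {
      a <- c(a, ta[[i]]$text); b <- c(b, strrep("-", nchar(ta[[i]]$text)))
      i <- i + 1L
    } else if (j <= length(tb) && tb[[j]]$type == "I") {
      b <- c(b, tb[[j]]$text); a <- c(a, strrep("-", nchar(tb[[j]]$text)))
      j <- j + 1L
    } else if (i <= length(ta) && j <= length(tb)) {
      a <- c(a, ta[[i]]$text); b <- c(b, tb[[j]]$text)
      i <- i + 1L; j <- j + 1L
    } else if (i <= length(ta)) {
      a <- c(a, ta[[i]]$text); b <- c(b, strrep("-", nchar(ta[[i]]$text)))
      i <- i + 1L
    } else {
      b <- c(b, tb[[j]]$text); a <- c(a, strrep("-", nchar(tb[[j]]$text)))
      j <- j + 1L
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

.count_imbalance <- function(ac, ah, cregs, hregs) {
  vc <- strsplit(ac, "")[[1]]
  vh <- strsplit(ah, "")[[1]]
  in_region <- function(pos0, regs) {
    for (r in regs) if (pos0 >= r$start && pos0 < r$end) return(TRUE)
    FALSE
  }
  ci <- 0L; hi <- 0L
  c_only_nonstr <- 0L; h_only_nonstr <- 0L
  c_only <- 0L; h_only <- 0L
  for (k in seq_along(vc)) {
    cg <- vc[k] == "-"; hg <- vh[k] == "-"
    if (!cg && hg) {
      c_only <- c_only + 1L
      if (!in_region(ci, cregs)) c_only_nonstr <- c_only_nonstr + 1L
    } else if (cg && !hg) {
      h_only <- h_only + 1L
      if (!in_region(hi, hregs)) h_only_nonstr <- h_only_nonstr + 1L
    }
    if (!cg) ci <- ci + 1L
    if (!hg) hi <- hi + 1L
  }
  list(chimp_only_nonstr_nt = c_only_nonstr, human_only_nonstr_nt = h_only_nonstr,
       chimp_only_total = c_only, human_only_total = h_only)
}

#' Align a chimpanzee and a human amplicon with STR anchors
#'
#' @param chimp_seq,human_seq Amplicon sequences.
#' @param chimp_structure,human_structure [str_structure()]s derived from
#'   the same sequences (defaults: detected at `min_repeats = 2` and
#'   harmonized). Structures are harmonized before anchoring.
#' @param marker Marker name carried through.
#' @return List of class `ortholog_alignment`: `aligned_chimp`/
#'   `aligned_human` (gapped strings), `anchored` (FALSE when anchor
#'   pairing failed and a plain global alignment was used), `str_blocks`
#'   (anchor-group summary data frame), `chimp_only_nonstr_nt`,
#'   `human_only_nonstr_nt` and the total per-species insertion counts.
#' @export
align_orthologs <- function(chimp_seq, human_seq,
                            chimp_structure = NULL, human_structure = NULL,
                            marker = NA_character_) {
  chimp_seq <- toupper(chimp_seq); human_seq <- toupper(human_seq)
  if (is.null(chimp_structure)) {
    chimp_structure <- find_str_regions(chimp_seq, min_repeats = 2L)
  }
  if (is.null(human_structure)) {
    human_structure <- find_str_regions(human_seq, min_repeats = 2L)
  }
  chimp_structure <- harmonize_boundaries(chimp_structure, chimp_seq)
  human_structure <- harmonize_boundaries(human_structure, human_seq)
  cr <- chimp_structure$regions; hr <- human_structure$regions

  groups <- if (length(cr) > 0L && length(hr) > 0L) .pair_anchors(cr, hr) else NULL
  blocks <- data.frame(group = integer(0), chimp_regions = character(0),
                       human_regions = character(0))
  if (is.null(groups)) {
    g <- .global_align(chimp_seq, human_seq)
    ac <- g$a; ah <- g$b
    anchored <- FALSE
  } else {
    anchored <- TRUE
    ac <- ""; ah <- ""
    cpos <- 0L; hpos <- 0L   # 0-based consumed prefix of each sequence
    for (gi in seq_along(groups)) {
      grp <- groups[[gi]]
      c_first <- cr[[grp$chimp[1]]]; h_first <- hr[[grp$human[1]]]
      c_last <- cr[[grp$chimp[length(grp$chimp)]]]
      h_last <- hr[[grp$human[length(grp$human)]]]
      fl <- .global_align(substr(chimp_seq, cpos + 1L, c_first$start),
                          substr(human_seq, hpos + 1L, h_first$start))
      blk <- .align_anchor_group(chimp_seq, human_seq,
                                 cr[grp$chimp], hr[grp$human])
      ac <- paste0(ac, fl$a, blk$a)
      ah <- paste0(ah, fl$b, blk$b)
      cpos <- c_last$end; hpos <- h_last$end
      blocks <- rbind(blocks, data.frame(
        group = gi,
        chimp_regions = paste(grp$chimp, collapse = "+"),
        human_regions = paste(grp$human, collapse = "+")))
    }
    fl <- .global_align(substr(chimp_seq, cpos + 1L, nchar(chimp_seq)),
                        substr(human_seq, hpos + 1L, nchar(human_seq)))
    ac <- paste0(ac, fl$a)
    ah <- paste0(ah, fl$b)
  }
  counts <- .count_imbalance(ac, ah, cr, hr)
  structure(c(list(marker = marker, aligned_chimp = ac, aligned_human = ah,
                   anchored = anchored, str_blocks = blocks),
              counts),
            class = "ortholog_alignment")
}

#' Non-STR length imbalance of an alignment
#'
#' Counts of gap-opposed positions outside either species' STR regions:
#' nucleotides present in only one species' amplicon that cannot reflect
#' repeat-number differences and therefore break fragment-length
#' commensurability.
#'
#' @param alignment An [align_orthologs()] result.
#' @return Named numeric vector `c(chimp_only_nt, human_only_nt)`.
#' @export
nonstr_imbalance <- function(alignment) {
  c(chimp_only_nt = alignment$chimp_only_nonstr_nt,
    human_only_nt = alignment$human_only_nonstr_nt)
}
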