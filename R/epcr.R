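#' In-silico PCR: primer scanning, amplicon demarcation and retention
#'
#' Primer hits are local alignments against either reference strand that
#' differ from the primer by at most `max_len_deficit` nucleotides in
#' alignment length and have at least `min_identity` sequence identity
#' (matches divided by alignment columns). Candidate amplicons are
#' demarcated by the 5'-terminal positions of a forward and a reverse hit,
#' length-adjusted for primer modifications, and passed through the
#' retention decision tree.
#'
#' @name epcr
NULL

.nuc_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = TRUE)
}

# Score-optimal clipped ungapped sub-alignment of `primer` placed with its
# first base at reference offset `o` (1-based; may extend past either end),
# under match +1 / mismatch -1 scoring — the window a local aligner would
# report on this diagonal. Ties broken toward longer, then leftmost.
.best_window <- function(pchars, rchars, o) {
  p_l <- length(pchars)
  n <- length(rchars)
  q_lo <- max(1L, 1L - o + 1L)
  q_hi <- min(p_l, n - o + 1L)
  if (q_hi < q_lo) return(NULL)
  m <- pchars[q_lo:q_hi] == rchars[(o + q_lo - 1L):(o + q_hi - 1L)]
  cs <- c(0L, cumsum(m))
  w <- length(m)
  best <- NULL
  for (q1 in seq_len(w)) {
    for (q2 in seq(q1, w)) {
      L <- q2 - q1 + 1L
      mm <- cs[q2 + 1L] - cs[q1]
      sc <- 2L * mm - L
      if (is.null(best) || sc > best$score ||
          (sc == best$score && L > best$len)) {
        best <- list(score = sc, len = L, identity = mm / L)
      }
    }
  }
  best
}

# longest exact-match run between the query and the reference along the
# diagonal that places query base 1 at reference offset o
.max_diag_run <- function(qchars, rchars, o) {
  p_l <- length(qchars)
  n <- length(rchars)
  q_lo <- max(1L, 1L - o + 1L)
  q_hi <- min(p_l, n - o + 1L)
  if (q_hi < q_lo) return(0L)
  m <- qchars[q_lo:q_hi] == rchars[(o + q_lo - 1L):(o + q_hi - 1L)]
  r <- rle(m)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 0L else max(runs)
}

.scan_strand <- function(primer, refseq, strand, chromosome,
                         max_len_deficit, min_identity, min_seed) {
  p_l <- nchar(primer)
  n <- nchar(refseq)
  query <- if (strand == "+") primer else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  qchars <- strsplit(query, "")[[1]]
  rchars <- strsplit(refseq, "")[[1]]
  mat <- .nuc_mat()
  s_min <- max(4, floor(0.8 * (p_l - max_len_deficit)))
  hits <- list()

  scan_segment <- function(lo, hi) {
    if (hi - lo + 1L < max(10L, p_l - max_len_deficit)) return(invisible())
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query),
      subject = Biostrings::DNAString(substr(refseq, lo, hi)),
      type = "local", substitutionMatrix = mat,
      gapOpening = 3, gapExtension = 1)
    if (Biostrings::score(pa) < s_min) return(invisible())
    sstart <- lo + BiocGenerics::start(Biostrings::subject(pa)) - 1L
    send <- lo + BiocGenerics::end(Biostrings::subject(pa)) - 1L
    qstart <- BiocGenerics::start(Biostrings::pattern(pa))
    qend <- BiocGenerics::end(Biostrings::pattern(pa))
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    matches <- Biostrings::nmatch(pa)

    accepts <- function(len, id) {
      len >= p_l - max_len_deficit && len <= p_l + 10L && id >= min_identity
    }
    o0 <- sstart - (qstart - 1L)
    # seeded search: the locus must carry an exact-match run long enough to
    # seed a word-based aligner (word size 11 by default)
    seeded <- min_seed <= 1L ||
      any(vapply((o0 - 3L):(o0 + 3L), function(o) {
        .max_diag_run(qchars, rchars, o) >= min_seed
      }, logical(1)))
    cand <- NULL
    if (seeded) {
      if (accepts(cols, matches / cols)) {
        cand <- list(len = cols, identity = matches / cols)
      }
      # the gapped optimum may fail where a diagonal's score-optimal
      # ungapped window passes (and vice versa); assess nearby diagonals too
      for (o in (o0 - 3L):(o0 + 3L)) {
        bw <- .best_window(qchars, rchars, o)
        if (!is.null(bw) && accepts(bw$len, bw$identity) &&
            (is.null(cand) || bw$len > cand$len ||
             (bw$len == cand$len && bw$identity > cand$identity))) {
          cand <- bw[c("len", "identity")]
        }
      }
    }
    if (!is.null(cand)) {
      five <- if (strand == "+") sstart - (qstart - 1L) else send + (p_l - qend)
      hits[[length(hits) + 1L]] <<- primer_hit(
        chromosome = chromosome, strand = strand, five_prime_pos = five,
        alignment_length = cand$len, identity = cand$identity,
        primer_length = p_l)
    }
    scan_segment(lo, sstart - 1L)
    scan_segment(send + 1L, hi)
    invisible()
  }
  scan_segment(1L, n)
  hits
}

#' Scan a primer against a reference sequence
#'
#' @param primer Genomic primer sequence (5'->3', >= 15 nt; non-genomic
#'   tails must not be included — they are excluded from alignment-length
#'   assessment by construction).
#' @param reference Reference sequence to scan (both strands are searched).
#' @param chromosome Name recorded on the hits.
#' @param max_len_deficit A hit may be at most this many nt shorter than the
#'   primer (default 10).
#' @param min_identity Minimum fraction of matching alignment columns
#'   (default 0.90).
#' @param min_seed Minimum exact-match run a locus must carry, emulating a
#'   word-based search (default 11, the classic BLASTN word size); set to 1
#'   to accept on the length/identity thresholds alone.
#' @return List of [primer_hit()] objects; `five_prime_pos` is the 1-based
#'   position of the primer's 5'-terminal base on the plus strand.
#' @export
scan_primer <- function(primer, reference, chromosome = "ref",
                        max_len_deficit = 10L, min_identity = 0.90,
                        min_seed = 11L) {
  primer <- toupper(primer)
  reference <- toupper(reference)
  .assert(nchar(primer) >= 15L, "primer shorter than 15 nt")
  .assert(!grepl("[^ACGT]", primer), "non-ACGT characters in primer")
  hits <- c(.scan_strand(primer, reference, "+", chromosome,
                         max_len_deficit, min_identity, min_seed),
            .scan_strand(primer, reference, "-", chromosome,
                         max_len_deficit, min_identity, min_seed))
  if (length(hits) < 2L) return(hits)
  key <- vapply(hits, function(h) paste(h$strand, h$five_prime_pos), character(1))
  hits[!duplicated(key)]
}

#' Demarcate candidate amplicons from primer hits
#'
#' Fragment length is the distance between the 5'-terminal nucleotide of
#' the forward hit and the 5'-terminal nucleotide of the reverse hit,
#' counted inclusively, so an amplicon equals the standard PCR product
#' spanning both primers. The inclusive (+1) convention is isolated here.
#'
#' @param forward_hits Hits of the forward primer (plus strand used).
#' @param reverse_hits Hits of the reverse primer (minus strand used).
#' @param reference Reference sequence (for amplicon extraction).
#' @param marker_name Marker identifier stamped on fragments.
#' @param species Species tag stamped on fragments.
#' @param max_amplicon Hard cap on plausible amplicon length in bp.
#' @return List of [epcr_fragment()] objects (possibly empty).
#' @export
demarcate_fragments <- function(forward_hits, reverse_hits, reference,
                                marker_name = "marker",
                                species = c("chimpanzee", "human"),
                                max_amplicon = 2000L) {
  species <- match.arg(species)
  n <- nchar(reference)
  out <- list()
  for (f in forward_hits) {
    if (f$strand != "+") next
    for (r in reverse_hits) {
      if (r$strand != "-") next
      if (!identical(f$chromosome, r$chromosome)) next
      raw <- r$five_prime_pos - f$five_prime_pos + 1L
      if (raw < 1L || raw > max_amplicon) next
      if (f$five_prime_pos < 1L || r$five_prime_pos > n) next
      out[[length(out) + 1L]] <- epcr_fragment(
        marker_name = marker_name, chromosome = f$chromosome,
        sequence = substr(reference, f$five_prime_pos, r$five_prime_pos),
        species = species, start = f$five_prime_pos)
    }
  }
  out
}

#' Adjust a fragment length for primer modifications
#'
#' Non-genomic pig-tails (7 bp) or extra adenines (1 bp) inflate the sized
#' PCR product, so the same amount is added to the in-silico length before
#' range comparison; dataset-merge corrections applied to the genotypes are
#' reversed (subtracted).
#'
#' @param fragment An [epcr_fragment()] (its `raw_length` is used).
#' @param primers The locus' [primer_pair()].
#' @param merge_correction Signed bp correction to reverse; defaults to the
#'   primer pair's `merge_offset`.
#' @return Adjusted length in bp (integer).
#' @export
adjust_length <- function(fragment, primers, merge_correction = primers$merge_offset) {
  as.integer(fragment$raw_length + primers$forward_extra_bp +
               primers$reverse_extra_bp - merge_correction)
}

#' Length-based retention filter
#'
#' Keeps a fragment iff its adjusted length lies within the observed
#' PCR-fragment-length range extended by `slack` bp on each side.
#'
#' @param x Adjusted ePCR fragment length in bp.
#' @param range Observed [length_range()] from the species' genotype data.
#' @param slack Extension in bp on each side of the range (default 6).
#' @return List with `keep` (logical) and `margin` (bp outside the
#'   unextended range; negative when inside).
#' @export
retention_filter <- function(x, range, slack = 6L) {
  margin <- max(range$lo - x, x - range$hi)
  list(keep = margin <= slack, margin = as.integer(margin))
}

#' Resolve candidate amplicons into a retention decision
#'
#' Implements the multiple-hit resolution rules: no candidates is a no-hit
#' rejection; two overlapping candidates that share the reverse-primer 5'
#' position are resolved to the smaller fragment (assumed to amplify more
#' efficiently) which is then length-filtered; more than one candidate
#' passing the length filter without that structure is a multi-hit
#' rejection; candidates that all fail the filter are a length rejection.
#'
#' @param fragments List of [epcr_fragment()] candidates for one marker,
#'   each carrying its `adjusted_length`.
#' @param range Observed [length_range()].
#' @param slack Retention slack in bp (default 6).
#' @return List of class `epcr_decision` with `marker`, `outcome`,
#'   `chosen_fragment`, `candidates_considered`, `margin_bp`.
#' @export
resolve_candidates <- function(fragments, range, slack = 6L) {
  decision <- function(outcome, chosen = NULL, margin = NA_integer_, marker = NA_character_) {
    structure(list(marker = marker, outcome = outcome, chosen_fragment = chosen,
                   candidates_considered = length(fragments),
                   margin_bp = margin),
              class = "epcr_decision")
  }
  if (length(fragments) == 0L) return(decision("rejected_no_hit"))
  marker <- fragments[[1]]$marker_name
  ends <- vapply(fragments, function(f) f$start + f$raw_length - 1L, integer(1))
  starts <- vapply(fragments, `[[`, integer(1), "start")
  lens <- vapply(fragments, `[[`, integer(1), "adjusted_length")

  filt <- lapply(lens, retention_filter, range = range, slack = slack)
  pass <- vapply(filt, `[[`, logical(1), "keep")
  margins <- vapply(filt, `[[`, integer(1), "margin")
  if (!any(pass)) {
    return(decision("rejected_length", margin = min(margins), marker = marker))
  }
  p <- which(pass)
  if (length(p) == 1L) {
    return(decision("retained", fragments[[p]], margins[p], marker))
  }
  # several plausible fragments: resolvable only when they overlap and
  # share the reverse 5' position, in which case the smallest is assumed
  # to amplify most efficiently
  if (length(unique(ends[p])) == 1L && max(starts[p]) <= ends[p][1]) {
    k <- p[which.min(lens[p])]
    return(decision("resolved_overlap", fragments[[k]], margins[k], marker))
  }
  decision("rejected_multi_hit", margin = min(margins), marker = marker)
}
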