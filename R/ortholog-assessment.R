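#' Interspecies range comparison and ortholog assessment
#'
#' Compares the chimpanzee and human PCR-fragment-length ranges observed in
#' the genotype data, places the two species' in-silico fragment lengths
#' within them, and applies the three ortholog-acceptance criteria with the
#' range overlap score (ROS) as the fallback similarity measure.
#'
#' @name ortholog-assessment
NULL

#' Classify the relationship of two fragment-length ranges
#'
#' @param chimp,human [length_range()] objects (closed bp intervals).
#' @return One of `"disjoint"`, `"identical"`, `"chimp_subsumed"`,
#'   `"human_subsumed"`, `"partial_chimp_lower"`, `"partial_chimp_higher"`.
#' @export
classify_ranges <- function(chimp, human) {
  if (chimp$hi < human$lo || human$hi < chimp$lo) return("disjoint")
  if (chimp$lo == human$lo && chimp$hi == human$hi) return("identical")
  if (chimp$lo >= human$lo && chimp$hi <= human$hi) return("chimp_subsumed")
  if (human$lo >= chimp$lo && human$hi <= chimp$hi) return("human_subsumed")
  if (chimp$lo < human$lo) "partial_chimp_lower" else "partial_chimp_higher"
}

#' Range overlap score
#'
#' Similarity of two closed bp intervals: size of their intersection
#' divided by size of their union, counting positions inclusively. 0 for
#' disjoint ranges, 1 for identical ranges.
#'
#' @param r1,r2 [length_range()] objects.
#' @return Number in `[0, 1]`.
#' @export
range_overlap_score <- function(r1, r2) {
  inter <- min(r1$hi, r2$hi) - max(r1$lo, r2$lo) + 1
  if (inter <= 0) return(0)
  uni <- max(r1$hi, r2$hi) - min(r1$lo, r2$lo) + 1
  inter / uni
}

#' Assess a putative ortholog's fragment lengths against both ranges
#'
#' The criteria are evaluated in order: (i) both species' in-silico
#' fragment lengths lie within the intersection of the two ranges; (ii) a
#' length lies outside its own species' range but within the union of the
#' two ranges; (iii) a length lies outside the union, in which case the
#' marker is kept only if the ROS of the two ranges is at least
#' `ros_threshold` and the offending length is no more than `slack` bp
#' outside the unified range.
#'
#' @param x_c,x_h Chimpanzee and human in-silico fragment lengths (bp).
#' @param chimp,human Observed [length_range()]s (must overlap; disjoint
#'   markers are excluded upstream as possible regressions/non-orthologs).
#' @param ros_threshold ROS acceptance threshold (default 0.289, the
#'   data-driven value; see [derive_ros_threshold()]).
#' @param slack Allowance outside the unified range under criterion iii, bp.
#' @param marker Marker name carried through to the result.
#' @return List of class `ortholog_assessment` with `marker`, `range_class`,
#'   `criterion` (`"i"`, `"ii"`, `"iii"` or `"fail"`), `ros` (present iff
#'   criterion iii was evaluated), `retained`, `reason`.
#' @export
assess_lengths <- function(x_c, x_h, chimp, human,
                           ros_threshold = 0.289, slack = 6L,
                           marker = NA_character_) {
  range_class <- classify_ranges(chimp, human)
  .assert(range_class != "disjoint",
          "ranges are disjoint; exclude the marker upstream")
  inter <- length_range(max(chimp$lo, human$lo), min(chimp$hi, human$hi))
  uni <- length_range(min(chimp$lo, human$lo), max(chimp$hi, human$hi))
  within <- function(x, r) x >= r$lo && x <= r$hi
  out <- function(criterion, retained, reason, ros = NA_real_) {
    structure(list(marker = marker, range_class = range_class,
                   criterion = criterion, ros = ros,
                   retained = retained, reason = reason),
              class = "ortholog_assessment")
  }
  if (within(x_c, inter) && within(x_h, inter)) {
    return(out("i", TRUE, "both ePCR lengths within the range intersection"))
  }
  c_in_uni <- within(x_c, uni)
  h_in_uni <- within(x_h, uni)
  if (c_in_uni && h_in_uni) {
    return(out("ii", TRUE,
               "an ePCR length outside its own range but within the union"))
  }
  ros <- range_overlap_score(chimp, human)
  offend <- max(uni$lo - c(x_c, x_h), c(x_c, x_h) - uni$hi)
  if (ros >= ros_threshold && offend <= slack) {
    return(out("iii", TRUE,
               sprintf("offending length %d bp outside the union; ROS %.3f >= %.3f",
                       offend, ros, ros_threshold), ros))
  }
  reason <- if (ros < ros_threshold) {
    sprintf("ROS %.3f < %.3f", ros, ros_threshold)
  } else {
    sprintf("offending length %d bp outside the union exceeds %d bp", offend, slack)
  }
  out("fail", FALSE, reason, ros)
}

#' Data-driven ROS threshold
#'
#' The threshold below which criterion-iii markers are rejected is the
#' lowest ROS among markers whose two in-silico fragment lengths both lie
#' within the intersection of the species' ranges (criterion i).
#'
#' @param assessments List of [assess_lengths()] results for a marker panel,
#'   each evaluated with its ROS recorded (use `ros_threshold = -Inf` and
#'   re-assess, or supply assessments whose `ros` was filled upstream).
#' @param ros_by_marker Optional named numeric vector of ROS values; when
#'   supplied it overrides the `ros` fields (criterion-i assessments do not
#'   evaluate ROS themselves).
#' @return The minimum ROS over criterion-i markers.
#' @export
derive_ros_threshold <- function(assessments, ros_by_marker = NULL) {
  crit <- vapply(assessments, `[[`, character(1), "criterion")
  keep <- crit == "i"
  .assert(any(keep), "no criterion-i markers to derive a threshold from")
  if (!is.null(ros_by_marker)) {
    markers <- vapply(assessments, `[[`, character(1), "marker")
    ros <- unname(ros_by_marker[markers])
  } else {
    ros <- vapply(assessments, `[[`, numeric(1), "ros")
  }
  .assert(!anyNA(ros[keep]), "ROS missing for a criterion-i marker")
  min(ros[keep])
}
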