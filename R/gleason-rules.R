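#' Gleason pattern classes
#'
#' The four tissue classes modelled by the package: benign tissue and Gleason
#' patterns 3, 4 and 5. Patterns 1 and 2 are not modelled (they do not occur
#' in modern practice). Under the "worse pattern" ordering GP3 < GP4 < GP5;
#' benign tissue is excluded from all cancer-area computations.
#'
#' @return Character vector of the four class names, ordered benign, gp3,
#'   gp4, gp5.
#' @export
#' @examples
#' pattern_classes()
pattern_classes <- function() c("benign", "gp3", "gp4", "gp5")

cancer_patterns <- function() c("gp3", "gp4", "gp5")

# pattern number (3/4/5) for a cancer class name
pattern_number <- function(class) {
  n <- c(gp3 = 3, gp4 = 4, gp5 = 5)[class]
  unname(n)
}

#' Map a Gleason score to its ISUP grade group
#'
#' Implements the five-tier prognostic grouping: grade group 1 = Gleason
#' score <= 6, group 2 = 3 + 4, group 3 = 4 + 3, group 4 = score 8, and
#' group 5 = scores 9 and 10. Grade group 0 is reserved for benign slides and
#' is never returned here (a score implies cancer).
#'
#' @param primary,secondary Gleason pattern numbers, each in {3, 4, 5}. The
#'   primary pattern is the most prevalent; the secondary is the worst other
#'   pattern retained by the reporting rules.
#' @return Integer grade group in 1..5.
#' @export
#' @examples
#' score_to_grade_group(3, 4) # 2
#' score_to_grade_group(4, 3) # 3
score_to_grade_group <- function(primary, secondary) {
  stopifnot(length(primary) == 1L, length(secondary) == 1L)
  if (!primary %in% 3:5 || !secondary %in% 3:5) {
    stop("invalid Gleason score: patterns must be 3, 4 or 5, got ",
         primary, " + ", secondary, call. = FALSE)
  }
  gs <- primary + secondary
  if (gs <= 6L) return(1L)
  if (gs == 7L) return(if (primary == 3L) 2L else 3L)
  if (gs == 8L) return(4L)
  5L
}

#' Validate an area composition
#'
#' An area composition gives the fraction of total slide area occupied by
#' each pattern class. Fractions must be non-negative and sum to 1.
#'
#' @param comp Named numeric vector; names must be a subset of
#'   [pattern_classes()]. Missing classes are treated as 0.
#' @param tol Tolerance on the sum-to-one constraint.
#' @return Full-length named numeric vector over all four classes.
#' @export
as_area_composition <- function(comp, tol = 1e-9) {
  if (is.null(names(comp)) || !all(names(comp) %in% pattern_classes())) {
    stop("composition must be named with classes among: ",
         paste(pattern_classes(), collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(numeric(4), pattern_classes())
  full[names(comp)] <- comp
  if (any(full < 0)) stop("invalid composition: negative fraction", call. = FALSE)
  if (abs(sum(full) - 1) > tol) {
    stop("invalid composition: fractions sum to ", format(sum(full)),
         ", expected 1", call. = FALSE)
  }
  full
}

#' Derive a slide's grade group from its area composition
#'
#' Applies the reporting rules used to turn per-pattern areas (from pixel or
#' patch counting) into a grade group:
#'
#' 1. Any cancer pattern occupying less than `noise_floor` of the *total*
#'    slide area is ignored (noise from label voting).
#' 2. If no cancer pattern survives, the slide is benign (grade group 0).
#' 3. The primary pattern is the surviving pattern with the largest area;
#'    on an exact tie the worse pattern wins (conservative choice).
#' 4. The secondary pattern is the worst surviving pattern when it is worse
#'    than the primary — any amount above the noise floor counts, so even a
#'    very small focus of pattern 5 raises the score. Otherwise the score is
#'    primary plus the worst remaining pattern whose share of the *cancer*
#'    area exceeds `secondary_min`; lower-grade patterns below that share
#'    are ignored. With no eligible secondary the primary is doubled. (The
#'    worst-eligible choice — rather than largest-area — keeps grading
#'    monotone in severity: upgrading cancer area can then never lower the
#'    grade group.)
#' 5. The Gleason score primary + secondary is mapped through
#'    [score_to_grade_group()].
#'
#' Note the two thresholds use different denominators: the noise floor is a
#' fraction of total slide area, the secondary minimum a fraction of cancer
#' area.
#'
#' @param comp Named numeric vector of area fractions (see
#'   [as_area_composition()]).
#' @param noise_floor Minimum fraction of total area for a pattern to be
#'   considered at all (default 0.01).
#' @param secondary_min Minimum share of the cancer area for a
#'   *lower*-grade pattern to be reported as secondary (default 0.05).
#' @return Integer grade group in 0..5.
#' @export
#' @examples
#' composition_to_grade_group(c(benign = 0.5, gp3 = 0.3, gp4 = 0.2)) # 2
#' composition_to_grade_group(c(benign = 1))                          # 0
composition_to_grade_group <- function(comp, noise_floor = 0.01,
                                       secondary_min = 0.05) {
  full <- as_area_composition(comp)
  cancer <- full[cancer_patterns()]
  cancer[cancer < noise_floor] <- 0
  if (all(cancer == 0)) return(0L)

  surviving <- names(cancer)[cancer > 0]
  # primary: largest area, worse pattern wins ties
  best <- max(cancer)
  tied <- names(cancer)[cancer == best]
  primary <- tied[length(tied)]          # classes ordered gp3 < gp4 < gp5

  worst <- surviving[length(surviving)]
  if (pattern_number(worst) > pattern_number(primary)) {
    secondary <- worst
  } else {
    total_cancer <- sum(cancer)
    rest <- setdiff(surviving, primary)
    eligible <- rest[cancer[rest] / total_cancer > secondary_min]
    secondary <- if (length(eligible)) {
      # worst eligible pattern (classes are ordered gp3 < gp4 < gp5)
      eligible[length(eligible)]
    } else {
      primary
    }
  }
  score_to_grade_group(pattern_number(primary), pattern_number(secondary))
}

#' Area composition from a grid of patch labels
#'
#' Computes the fraction of patches carrying each pattern label. Patch-level
#' labels stand in for pixel-level masks: the rule engine is denominated in
#' area units, so either granularity works.
#'
#' @param labels Matrix, vector or factor of patch labels drawn from
#'   [pattern_classes()].
#' @return Named numeric vector over the four classes summing to 1.
#' @export
#' @examples
#' composition_from_label_grid(matrix(c("gp3", "gp3", "gp4", "benign"), 2))
composition_from_label_grid <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("empty label grid", call. = FALSE)
  bad <- setdiff(unique(labels), pattern_classes())
  if (length(bad)) stop("unknown pattern label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts <- table(factor(labels, levels = pattern_classes()))
  stats::setNames(as.vector(counts) / length(labels), pattern_classes())
}
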