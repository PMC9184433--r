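# Grading systems for radical prostatectomy specimens: Gleason score /
# ISUP Grade Group from pattern percentages, the integrated quantitative
# Gleason score (IQ-Gleason, continuous and 5-tier), and the cribriform
# grade (cGrade) modification for invasive cribriform / intraductal
# carcinoma (IC/IDC).

# Tolerance for the p3 + p4 + p5 = 100 closure constraint.
.COMP_TOL <- 1e-9

#' Validate Gleason pattern compositions
#'
#' Checks that pattern percentages describe a valid composition of the
#' invasive carcinoma: each of `p3`, `p4`, `p5` lies in \[0, 100\] and the
#' three sum to 100 (tolerance 1e-9). Percentages refer to invasive
#' carcinoma only; intraductal carcinoma does not contribute.
#'
#' @param p3,p4,p5 Numeric vectors of percentages of Gleason pattern 3, 4
#'   and 5 within the invasive tumour.
#' @param what Label used in error messages (e.g. a record index).
#' @return Invisibly `TRUE`; errors name the offending field and records.
#' @keywords internal
validate_composition <- function(p3, p4, p5, what = "composition") {
  n <- length(p3)
  if (length(p4) != n || length(p5) != n)
    stop(what, ": p3, p4, p5 must have equal length", call. = FALSE)
  for (nm in c("p3", "p4", "p5")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop(what, ": field '", nm, "' must be finite numeric", call. = FALSE)
    bad <- which(v < 0 | v > 100)
    if (length(bad))
      stop(what, ": field '", nm, "' outside [0, 100] for record(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  s <- p3 + p4 + p5
  bad <- which(abs(s - 100) > .COMP_TOL)
  if (length(bad))
    stop(what, ": p3 + p4 + p5 must equal 100 (got ",
         paste(signif(s[utils::head(bad, 5L)], 10), collapse = ", "),
         " for record(s) ", paste(utils::head(bad, 5L), collapse = ", "), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Derive Gleason score and ISUP Grade Group from pattern percentages
#'
#' Applies the radical-prostatectomy grading conventions: the primary
#' pattern is the most extensive one (ties go to the higher grade); the
#' secondary pattern is the highest-grade remaining pattern occupying at
#' least 5% of the invasive tumour (if no other pattern reaches 5%, the
#' secondary equals the primary, e.g. 3+3 for a pure pattern-3 tumour).
#' Pattern 5 present below 5% and not selected as a grade component is
#' recorded as tertiary pattern 5. The Gleason score (primary + secondary)
#' maps to Grade Groups as GS <= 6 -> 1, 3+4 -> 2, 4+3 -> 3, GS 8 -> 4,
#' GS 9-10 -> 5.
#'
#' @inheritParams validate_composition
#' @return A data.frame with columns `primary`, `secondary`,
#'   `gleason_score`, `grade_group` (integers) and `tertiary5` (logical),
#'   one row per composition.
#' @examples
#' derive_gleason(70, 27, 3)   # GG2 with tertiary pattern 5
#' derive_gleason(70, 23, 7)   # pattern 5 reaches 5% -> secondary -> GG4
#' @export
derive_gleason <- function(p3, p4, p5) {
  validate_composition(p3, p4, p5)
  n <- length(p3)
  pm <- cbind(p3, p4, p5)                      # columns are grades 3,4,5
  # ties.method = "last" -> equal percentages resolve to the higher grade
  prim_col <- max.col(pm, ties.method = "last")
  primary <- prim_col + 2L

  elig <- pm >= 5
  elig[cbind(seq_len(n), prim_col)] <- FALSE
  # highest-grade eligible column; 0 if none
  idx <- matrix(rep(1:3, each = n), nrow = n)
  sec_col <- max.col(ifelse(elig, idx, 0L), ties.method = "last")
  none <- rowSums(elig) == 0
  secondary <- ifelse(none, primary, sec_col + 2L)

  gs <- primary + secondary
  gg <- integer(n)
  gg[gs <= 6] <- 1L
  gg[gs == 7 & primary == 3] <- 2L
  gg[gs == 7 & primary == 4] <- 3L
  gg[gs == 8] <- 4L
  gg[gs >= 9] <- 5L

  tertiary5 <- p5 > 0 & p5 < 5 & primary != 5L & secondary != 5L
  data.frame(primary = as.integer(primary), secondary = as.integer(secondary),
             gleason_score = as.integer(gs), grade_group = gg,
             tertiary5 = tertiary5)
}

#' Continuous IQ-Gleason score
#'
#' The integrated quantitative Gleason score sums the Gleason pattern 4 and
#' 5 percentages, adds 10 points if any pattern 5 is present and 7.5 more
#' if pattern 5 exceeds 20%, giving a continuous score from 0 to 117.5.
#' The score does not depend on IC/IDC status.
#'
#' @inheritParams validate_composition
#' @return Numeric vector of scores in \[0, 117.5\].
#' @examples
#' iq_gleason(70, 27, 3)  # 40
#' iq_gleason(70, 23, 7)  # also 40: robust to the 27/3 vs 23/7 split
#' @export
iq_gleason <- function(p3, p4, p5) {
  validate_composition(p3, p4, p5)
  p4 + p5 + 10 * (p5 > 0) + 7.5 * (p5 > 20)
}

#' Five-tier IQ-Gleason category
#'
#' Bins the continuous score into the a-priori ordinal groups 0-25, 26-50,
#' 51-75, 76-100 and 101-117.5. Because bonus points can produce
#' non-integer scores, the bins are implemented as \[0,25\], (25,50\],
#' (50,75\], (75,100\] and (100,117.5\] so every attainable score maps to
#' exactly one category.
#'
#' @param score Numeric vector of continuous IQ-Gleason scores.
#' @return Integer vector of categories 1-5.
#' @export
iq_category <- function(score) {
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score)))
    stop("score must be finite numeric", call. = FALSE)
  if (any(score < 0 | score > 117.5))
    stop("score outside [0, 117.5]", call. = FALSE)
  # left-open intervals (0,25],(25,50],... ; a score of exactly 0 falls
  # below the first cut and is pulled into category 1
  pmax(findInterval(score, c(0, 25, 50, 75, 100), left.open = TRUE), 1L)
}

#' Cribriform grade (cGrade)
#'
#' Modifies the Grade Group for invasive cribriform and/or intraductal
#' carcinoma: GG2-5 tumours without IC/IDC are downgraded by one point;
#' with IC/IDC they keep their Grade Group. A GG1 tumour with IDC is
#' upgraded to cGrade 2, otherwise stays 1.
#'
#' @param grade_group Integer vector of Grade Groups 1-5.
#' @param has_icidc Logical vector: invasive cribriform and/or intraductal
#'   carcinoma present.
#' @return Integer vector of cGrades 1-5.
#' @examples
#' cgrade(1, TRUE)   # IDC upgrades GG1 to cGrade 2
#' cgrade(2, FALSE)  # GG2 without IC/IDC becomes cGrade 1
#' @export
cgrade <- function(grade_group, has_icidc) {
  if (anyNA(grade_group) || any(grade_group != as.integer(grade_group)) ||
      any(grade_group < 1 | grade_group > 5))
    stop("grade_group must be an integer in 1..5", call. = FALSE)
  if (anyNA(has_icidc)) stop("has_icidc must be TRUE/FALSE", call. = FALSE)
  has_icidc <- as.logical(has_icidc)
  gg <- as.integer(grade_group)
  out <- ifelse(gg >= 2L, gg - as.integer(!has_icidc),
                ifelse(has_icidc, 2L, 1L))
  as.integer(out)
}

#' Grade a cohort under all three systems
#'
#' Element-wise application of [derive_gleason()], [iq_gleason()],
#' [iq_category()] and [cgrade()] to a cohort table. Order-preserving and
#' pure; a validation failure reports the offending record index.
#'
#' @param cohort A data.frame with columns `p3`, `p4`, `p5` and
#'   `has_icidc` (logical or 0/1); other columns are carried through.
#' @return The input with appended columns `primary`, `secondary`,
#'   `gleason_score`, `grade_group`, `tertiary5`, `iq_continuous`,
#'   `iq_category`, `cgrade`.
#' @export
grade_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("p3", "p4", "p5", "has_icidc")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0) {
    extra <- data.frame(primary = integer(), secondary = integer(),
                        gleason_score = integer(), grade_group = integer(),
                        tertiary5 = logical(), iq_continuous = numeric(),
                        iq_category = integer(), cgrade = integer())
    return(cbind(cohort, extra))
  }
  validate_composition(cohort$p3, cohort$p4, cohort$p5, what = "cohort")
  gl <- derive_gleason(cohort$p3, cohort$p4, cohort$p5)
  iq <- iq_gleason(cohort$p3, cohort$p4, cohort$p5)
  icidc <- as.logical(cohort$has_icidc)
  cg <- cgrade(gl$grade_group, icidc)
  n_gg1_idc <- sum(gl$grade_group == 1L & icidc)
  if (n_gg1_idc > 0)
    warning(n_gg1_idc, " record(s) with Grade Group 1 and IC/IDC; ",
            "interpreted as IDC-only (cribriform implies pattern 4)",
            call. = FALSE)
  out <- cbind(cohort, gl)
  out$iq_continuous <- iq
  out$iq_category <- iq_category(iq)
  out$cgrade <- cg
  out
}

#' Cross-tabulate two five-tier grading systems
#'
#' Builds the 5 x 5 contingency table of two categorical gradings of the
#' same patients, with margins and the concordance fraction (diagonal
#' share), mirroring the layout used to compare Grade Group, categorical
#' IQ-Gleason and cGrade.
#'
#' @param labels_a,labels_b Integer vectors of categories 1-5, equal
#'   length.
#' @param names_ab Optional character(2) naming the two systems.
#' @return An object of class `grade_crosstab`: list with `counts`
#'   (5 x 5 matrix), `row_totals`, `col_totals`, `total`, `concordance`.
#' @export
cross_tabulate <- function(labels_a, labels_b, names_ab = c("A", "B")) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  for (v in list(labels_a, labels_b))
    if (anyNA(v) || any(v != as.integer(v)) || any(v < 1 | v > 5))
      stop("labels must be integers in 1..5", call. = FALSE)
  fa <- factor(as.integer(labels_a), levels = 1:5)
  fb <- factor(as.integer(labels_b), levels = 1:5)
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(paste0(names_ab[1], 1:5),
                           paste0(names_ab[2], 1:5))
  total <- length(labels_a)
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 total = total,
                 concordance = if (total > 0) sum(diag(counts)) / total
                               else NA_real_),
            class = "grade_crosstab")
}

#' @export
print.grade_crosstab <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$total))
  print(m)
  cat(sprintf("Concordance (diagonal share): %.3f\n", x$concordance))
  invisible(x)
}
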