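# Mark-recapture estimation of the active-uORF population from overlapping
# experiment detections, the three-set overlap solver, and the printed-count
# report helpers.

#' Petersen population estimate
#'
#' `N = C * M / R`: sample size times marked population over recaptures.
#'
#' @param C sample size.
#' @param M number of marked individuals in the population.
#' @param R number of marked individuals recaptured in the sample.
#' @return The population estimate.
#' @export
#' @examples
#' petersen(50, 100, 25)  # 200
petersen <- function(C, M, R) {
  if (R < 1) stop("Petersen estimate undefined for R = 0 (infinite estimate)")
  C * M / R
}

#' Schnabel population estimate
#'
#' Weighted average of Petersen estimates over a sequential series:
#' `N = sum(C_t * M_t) / sum(R_t)`.
#'
#' @param series a [MarkRecaptureSeries-class].
#' @return The population estimate.
#' @export
schnabel <- function(series) {
  if (sum(series@R) < 1) stop("Schnabel estimate undefined: no recaptures")
  sum(series@C * series@M) / sum(series@R)
}

#' Schumacher-Eschmeyer population estimate
#'
#' Least-squares regression of recapture proportions `R_t / C_t` on `M_t`
#' through the origin; the slope estimates `1 / N`, so
#' `N = sum(C_t * M_t^2) / sum(R_t * M_t)`.
#'
#' @param series a [MarkRecaptureSeries-class].
#' @return The population estimate.
#' @export
schumacherEschmeyer <- function(series) {
  den <- sum(series@R * series@M)
  if (den < 1) stop("Schumacher-Eschmeyer estimate undefined: denominator 0")
  sum(series@C * series@M^2) / den
}

#' Build a mark-recapture series from detection sets
#'
#' Experiments examined sequentially: `C_t` is the size of set `t`, `M_t`
#' the size of the union of earlier sets, and `R_t` the overlap of set `t`
#' with that union.
#'
#' @param sets list of character vectors (detection keys over a common key
#'   space).
#' @param order evaluation order (indices or names into `sets`).
#' @return A [MarkRecaptureSeries-class].
#' @export
#' @examples
#' seriesFromSets(list(a = c("x", "y"), b = c("y", "z")))
seriesFromSets <- function(sets, order = seq_along(sets)) {
  sets <- sets[order]
  C <- lengths(sets)
  M <- R <- numeric(length(sets))
  seen <- character(0)
  for (t in seq_along(sets)) {
    M[t] <- length(seen)
    R[t] <- sum(sets[[t]] %in% seen)
    seen <- union(seen, sets[[t]])
  }
  markRecaptureSeries(C = C, R = R, M = M)
}

#' Schnabel estimates over every ordering of the sets
#'
#' The Schnabel estimate depends on the order in which samples are
#' examined; the spread across orders is part of the result.
#'
#' @param sets named list of detection-key vectors.
#' @param estimator `schnabel` or `schumacherEschmeyer`.
#' @return data.frame `order`, `estimate`, one row per permutation.
#' @export
estimateAllOrders <- function(sets, estimator = schnabel) {
  n <- length(sets)
  perms <- allPermutations(n)
  rows <- lapply(perms, function(p) {
    data.frame(order = paste(names(sets)[p], collapse = ">"),
               estimate = estimator(seriesFromSets(sets, p)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in allPermutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

#' Solve three-set overlaps from aggregate counts
#'
#' Given the three set sizes, the per-set counts of members found in at
#' least one other set, the triple intersection, and the union size,
#' recovers the pairwise intersections from the linear system
#' `AB + AC - ABC = inAtLeastOne_A` (and rotations), then verifies the
#' inclusion-exclusion identity against the union exactly.
#'
#' @param sizes named numeric vector of length 3 (set sizes).
#' @param inAtLeastOne per-set counts of members present in >= 1 other set
#'   (same order as `sizes`).
#' @param triple triple-intersection size.
#' @param unionSize size of the union.
#' @return list `sizes`, `pairwise` (named `AB`, `AC`, `BC` following the
#'   order of `sizes`), `triple`, `union`.
#' @export
#' @examples
#' solveOverlaps(c(Lee = 1738, Fritsch = 2485, Gao = 976),
#'               c(492, 662, 500), triple = 172, unionSize = 4286)
solveOverlaps <- function(sizes, inAtLeastOne, triple, unionSize) {
  stopifnot(length(sizes) == 3L, length(inAtLeastOne) == 3L)
  # inAtLeastOne_i = sum of the two pairwise intersections involving i,
  # minus the triple (counted twice otherwise)
  s <- inAtLeastOne + triple
  AB <- (s[1] + s[2] - s[3]) / 2
  AC <- s[1] - AB
  BC <- s[2] - AB
  pw <- c(AB = unname(AB), AC = unname(AC), BC = unname(BC))
  if (any(pw < triple) || any(pw != round(pw)))
    stop("inconsistent overlap system: pairwise solution ",
         paste(sprintf("%s=%g", names(pw), pw), collapse = ", "))
  resid <- sum(sizes) - sum(pw) + triple - unionSize
  if (resid != 0)
    stop("inclusion-exclusion residual ", resid, " against union ", unionSize)
  list(sizes = sizes, pairwise = pw, triple = triple, union = unionSize)
}

#' Cross-detection percentage report for three experiments
#'
#' The percentages as printed in the study summaries: per experiment, the
#' share of its detections found in at least one other experiment, plus
#' the triple overlap as a share of the union. Rounded to one decimal.
#'
#' @inheritParams solveOverlaps
#' @return list `perExperiment` (named percentages), `triplePct`.
#' @export
overlapReport <- function(sizes, inAtLeastOne, triple, unionSize) {
  list(perExperiment = stats::setNames(pct1(inAtLeastOne, sizes),
                                       names(sizes)),
       triplePct = pct1(triple, unionSize))
}

#' Classification accounting report
#'
#' Percentages of each partition classified as likely active, as printed:
#' `100 * positive / total` rounded to one decimal.
#'
#' @param positive numeric vector of positively classified counts.
#' @param total numeric vector of partition sizes (same length/names).
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' classificationReport(c(twoVoted = 590), c(twoVoted = 768))
classificationReport <- function(positive, total) {
  stats::setNames(pct1(positive, total), names(positive))
}

#' Simulate uniform mark-recapture sampling from a closed population
#'
#' Draws `length(sampleSizes)` samples uniformly without replacement from a
#' population of size `N` and returns the resulting sequential series.
#' Used to check estimator recovery when the Petersen assumptions hold by
#' construction.
#'
#' @param N true population size.
#' @param sampleSizes vector of sample sizes.
#' @return A [MarkRecaptureSeries-class].
#' @export
simulateRecapture <- function(N, sampleSizes) {
  sets <- lapply(sampleSizes, function(s) sample.int(N, s))
  seriesFromSets(lapply(sets, as.character))
}
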