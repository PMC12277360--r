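#' Cutotype (HH/HL/LH/LL) assignment and aging-group stratification
#'
#' Subjects are cut into tertiles on each of the two composite criteria
#' (tone/elasticity first, oil/moisture second). Subjects in the top tertile
#' of both are HH, bottom of both LL, and so on; a subject whose either
#' composite lands in the middle tertile is in the gray zone and is
#' reassigned by an above-/below-mean rule. Aging groups (Young / Aging I /
#' Old) come from two age cutpoints detected as crossings of the upper- and
#' lower-tertile proportion curves over age.
#'
#' @name ksc
NULL

#' Tertile band of each value
#'
#' Deterministic tertile cut at the ceiling(n/3)-th and ceiling(2n/3)-th
#' order statistics; values tied with a boundary share the lower band.
#'
#' @param x numeric vector.
#' @return character vector in \{"L","M","H"\}.
#' @export
tertile_band <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 subjects for tertiles")
  s <- sort(x)
  q1 <- s[ceiling(n / 3)]
  q2 <- s[ceiling(2 * n / 3)]
  ifelse(x <= q1, "L", ifelse(x <= q2, "M", "H"))
}

#' Strict tertile-based type assignment
#'
#' @param composites data.frame with columns `tone_elasticity` and
#'   `oil_moisture`.
#' @return character vector over \{"HH","HL","LH","LL","GRAY"\}; the first
#'   letter is the tone/elasticity band, the second oil/moisture; any
#'   middle-band composite yields GRAY.
#' @export
assign_type_strict <- function(composites) {
  te <- tertile_band(composites$tone_elasticity)
  om <- tertile_band(composites$oil_moisture)
  if (all(te == "M") || all(om == "M"))
    warning("degenerate composite: all subjects in the middle band")
  ifelse(te == "M" | om == "M", "GRAY", paste0(te, om))
}

#' Reassign gray-zone subjects by the above-mean rule
#'
#' A gray-zone subject is H on an axis iff their composite is strictly above
#' the cohort mean of that composite, else L (at-mean counts as not above).
#' Non-gray labels pass through unchanged.
#'
#' @param strict character vector from [assign_type_strict()].
#' @param composites the same composites data.frame.
#' @return character vector over \{"HH","HL","LH","LL"\}.
#' @export
reassign_gray <- function(strict, composites) {
  gray <- strict == "GRAY"
  if (!any(gray)) return(strict)
  h1 <- ifelse(composites$tone_elasticity > mean(composites$tone_elasticity), "H", "L")
  h2 <- ifelse(composites$oil_moisture > mean(composites$oil_moisture), "H", "L")
  out <- strict
  out[gray] <- paste0(h1[gray], h2[gray])
  out
}

#' Per-age upper/lower/middle tertile proportion curves
#'
#' For one composite criterion, computes at every integer age (with at least
#' one subject) the fraction of that age's subjects whose composite falls in
#' the cohort-wide top tertile (`upper`), bottom tertile (`lower`) or middle
#' band, then smooths each curve with a centered moving average of window `w`
#' over the observed ages.
#'
#' @param composite numeric vector of one composite criterion.
#' @param ages integer ages (years), same length.
#' @param window odd smoothing window in years (default 3; 1 = no smoothing).
#' @return data.frame with `age`, `n`, raw and smoothed `upper`, `lower`,
#'   `middle` columns, ordered by age.
#' @export
proportion_curves <- function(composite, ages, window = 3) {
  stopifnot(length(composite) == length(ages), window >= 1, window %% 2 == 1)
  band <- tertile_band(composite)
  ages <- as.integer(round(ages))
  tab <- table(age = ages, band = factor(band, c("H", "M", "L")))
  n <- rowSums(tab)
  keep <- n > 0
  out <- data.frame(
    age = as.integer(rownames(tab))[keep],
    n = as.vector(n[keep]),
    upper = as.vector(tab[keep, "H"] / n[keep]),
    middle = as.vector(tab[keep, "M"] / n[keep]),
    lower = as.vector(tab[keep, "L"] / n[keep]))
  out <- out[order(out$age), ]
  smooth1 <- function(v) {
    if (window == 1) return(v)
    half <- (window - 1) / 2
    vapply(seq_along(v), function(i) {
      mean(v[max(1, i - half):min(length(v), i + half)])
    }, numeric(1))
  }
  out$upper_s <- smooth1(out$upper)
  out$middle_s <- smooth1(out$middle)
  out$lower_s <- smooth1(out$lower)
  rownames(out) <- NULL
  out
}

#' Detect upper/lower proportion crossover ages
#'
#' A crossover is an age `a` where the smoothed lower- and upper-proportion
#' curves exchange order: `lower(a) >= upper(a)` with
#' `lower(a-1) < upper(a-1)` (the aging direction) or, with
#' `direction = "both"` (default), also the reverse exchange (as in a
#' unimodal oil path, which intersects once on the adolescent rise and once
#' on the decline). The new ordering must persist for the next `persistence`
#' observed ages (truncated at the end of the range).
#'
#' @param curves data.frame from [proportion_curves()].
#' @param persistence number of subsequent ages the reversal must hold
#'   (default 2).
#' @param direction `"both"` (default) or `"lower_over_upper"` to report
#'   only crossings where the lower curve overtakes the upper.
#' @return integer vector of crossover ages (possibly empty).
#' @export
detect_crossovers <- function(curves, persistence = 2,
                              direction = c("both", "lower_over_upper")) {
  direction <- match.arg(direction)
  if (nrow(curves) < 3) stop("curves must cover at least 3 ages")
  gap <- curves$lower_s - curves$upper_s  # >= 0 means lower on top
  hits <- integer(0)
  for (i in 2:nrow(curves)) {
    ahead <- seq(i, min(nrow(curves), i + persistence))
    if (gap[i] >= 0 && gap[i - 1] < 0 && all(gap[ahead] >= 0))
      hits <- c(hits, curves$age[i])
    else if (direction == "both" &&
             gap[i] < 0 && gap[i - 1] >= 0 && all(gap[ahead] < 0))
      hits <- c(hits, curves$age[i])
  }
  hits
}

#' Select the two aging cutpoints from per-criterion crossovers
#'
#' The first cutpoint is the first tone/elasticity crossover; the second is
#' the first oil crossover occurring after the age at which the smoothed oil
#' upper-proportion peaks (early crossings during the adolescent oil rise are
#' ignored). Requires `c2 > c1`.
#'
#' @param tone_crossovers integer vector from [detect_crossovers()] on the
#'   tone/elasticity criterion.
#' @param oil_crossovers integer vector for the oil criterion.
#' @param oil_peak_age age of maximal smoothed oil upper-proportion.
#' @return named numeric vector `c(c1 = ..., c2 = ...)`.
#' @export
select_cutpoints <- function(tone_crossovers, oil_crossovers, oil_peak_age) {
  if (length(tone_crossovers) == 0) stop("no tone/elasticity crossover detected")
  if (length(oil_crossovers) == 0) stop("no oil crossover detected")
  c1 <- min(tone_crossovers)
  post_peak <- oil_crossovers[oil_crossovers > oil_peak_age]
  if (length(post_peak) == 0)
    stop("no oil crossover after the oil peak age (", oil_peak_age, ")")
  c2 <- min(post_peak)
  if (c2 <= c1)
    stop("second cutpoint (", c2, ") not after the first (", c1, ")")
  c(c1 = c1, c2 = c2)
}

#' Assign aging group from age and cutpoints
#'
#' Young: age <= c1 - 1; Aging I: c1 <= age <= c2 - 1; Old: age >= c2.
#'
#' @param age vector of ages (years, non-negative).
#' @param c1,c2 cutpoint ages, `c1 < c2`.
#' @return character vector over \{"Young","AgingI","Old"\}.
#' @export
assign_aging_group <- function(age, c1, c2) {
  stopifnot(c1 < c2)
  if (any(age < 0, na.rm = TRUE)) stop("negative age")
  ifelse(age < c1, "Young", ifelse(age < c2, "AgingI", "Old"))
}

#' Combine aging group and final type into one of 12 strata
#'
#' @param final_type character over \{"HH","HL","LH","LL"\}.
#' @param aging_group character over \{"Young","AgingI","Old"\}.
#' @return character strata labels such as `"yHL"`, `"aLH"`, `"oLL"`.
#' @export
stratify <- function(final_type, aging_group) {
  prefix <- c(Young = "y", AgingI = "a", Old = "o")[aging_group]
  if (anyNA(prefix)) stop("unknown aging group label")
  paste0(unname(prefix), final_type)
}

#' End-to-end cutotype labeling for a cohort
#'
#' Runs the strict tertile assignment, gray-zone reassignment, and (given or
#' detected) cutpoint-based stratification in one call.
#'
#' @param composites data.frame with `tone_elasticity` and `oil_moisture`.
#' @param ages integer ages.
#' @param c1,c2 aging cutpoints; if `NULL` both are detected from the
#'   proportion-crossover procedure using the tone/elasticity criterion for
#'   `c1` and the oil/moisture criterion for `c2`.
#' @param window,persistence smoothing and persistence settings for
#'   detection, see [proportion_curves()] and [detect_crossovers()].
#' @return data.frame with `strict_type`, `final_type`, `aging_group`,
#'   `strata`, plus attributes `cutpoints` and (when detected) `curves`.
#' @export
assign_ksc <- function(composites, ages, c1 = NULL, c2 = NULL,
                       window = 3, persistence = 2) {
  strict <- assign_type_strict(composites)
  final <- reassign_gray(strict, composites)
  curves <- NULL
  if (is.null(c1) || is.null(c2)) {
    tone_curves <- proportion_curves(composites$tone_elasticity, ages, window)
    oil_curves <- proportion_curves(composites$oil_moisture, ages, window)
    peak <- oil_curves$age[which.max(oil_curves$upper_s)]
    cp <- select_cutpoints(detect_crossovers(tone_curves, persistence),
                           detect_crossovers(oil_curves, persistence),
                           peak)
    c1 <- cp[["c1"]]; c2 <- cp[["c2"]]
    curves <- list(tone_elasticity = tone_curves, oil_moisture = oil_curves)
  }
  group <- assign_aging_group(ages, c1, c2)
  out <- data.frame(strict_type = strict, final_type = final,
                    aging_group = group, strata = stratify(final, group),
                    stringsAsFactors = FALSE)
  attr(out, "cutpoints") <- c(c1 = c1, c2 = c2)
  attr(out, "curves") <- curves
  out
}
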