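#' Baumann-style questionnaire scoring
#'
#' The 60-item self-assessment instrument scores four dichotomous skin axes:
#' dryness/oiliness (O, 11 items), sensitivity/resistance (S, 18 items),
#' pigmentation/non-pigmentation (P, 10 items) and wrinkles/elasticity
#' (W, 20 items). Each item is answered 1-4; an unanswered item contributes
#' 2.5 points. Category totals, after any bonus points, are compared against
#' fixed thresholds to call one letter per axis; the four letters concatenate
#' to one of 16 types (e.g. "DRNT").
#'
#' @name bsti
NULL

# category sizes of the scored instrument (59 scored items; the instrument's
# 60th item is an unscored control and never enters a total)
.bsti_category_sizes <- c(O = 11L, S = 18L, P = 10L, W = 20L)

# axis thresholds ("high"-side letter is called when the adjusted total
# meets the threshold) and the letters either side of each cut
.bsti_thresholds <- c(O = 27, S = 30, P = 31, W = 41)
.bsti_high <- c(O = "O", S = "S", P = "P", W = "W")
.bsti_low  <- c(O = "D", S = "R", P = "N", W = "T")

.check_category <- function(category) {
  if (length(category) != 1L || !category %in% names(.bsti_category_sizes))
    stop("unknown category tag: ", paste(category, collapse = ","),
         " (expected one of O, S, P, W)")
  category
}

#' Score one questionnaire category
#'
#' Sums the present item values of a category and adds 2.5 points for every
#' missing (unanswered) item.
#'
#' @param items numeric vector of item responses for one category; values in
#'   \{1,2,3,4\} or `NA` for unanswered items.
#' @param category one of `"O"`, `"S"`, `"P"`, `"W"`. Used to validate the
#'   item count for that category.
#' @param check validate item count and value range (default `TRUE`).
#' @return the category total in points.
#' @examples
#' score_category(rep(1, 11), "O")        # 11, the floor
#' score_category(rep(NA_real_, 11), "O") # 27.5 = 11 * 2.5
#' @export
score_category <- function(items, category, check = TRUE) {
  .check_category(category)
  if (check) {
    if (length(items) != .bsti_category_sizes[[category]])
      stop("category ", category, " expects ",
           .bsti_category_sizes[[category]], " items, got ", length(items))
    present <- items[!is.na(items)]
    if (length(present) && !all(present %in% 1:4))
      stop("item values must be 1, 2, 3, 4 or NA")
  }
  sum(items, na.rm = TRUE) + 2.5 * sum(is.na(items))
}

#' Call one axis letter from a category total
#'
#' Bonus points are added to the raw total before the threshold comparison:
#' +4 on the S axis when the subject reports a listed skin condition, +5 on
#' the P axis when sunlight aggravates their moles, and +5 on the W axis when
#' the subject is older than 65. Cuts are: O >= 27 oily (else dry),
#' S >= 30 sensitive (else resistant), P >= 31 pigmented (else non-pigmented),
#' W >= 41 wrinkly (else tight/elastic).
#'
#' @param total raw category total in points.
#' @param category one of `"O"`, `"S"`, `"P"`, `"W"`.
#' @param has_listed_skin_condition logical, S-axis bonus flag.
#' @param sun_aggravates_moles logical, P-axis bonus flag.
#' @param age subject age in years (W-axis bonus when `age > 65`).
#' @return single letter: the high-side letter (`O`,`S`,`P`,`W`) or the
#'   low-side letter (`D`,`R`,`N`,`T`).
#' @examples
#' classify_axis(27, "O") # "O"  (oily)
#' classify_axis(26, "O") # "D"
#' classify_axis(26, "S", has_listed_skin_condition = TRUE) # "S" (26+4 >= 30)
#' classify_axis(36, "W", age = 70) # "W" (36+5 >= 41)
#' @export
classify_axis <- function(total, category,
                          has_listed_skin_condition = FALSE,
                          sun_aggravates_moles = FALSE,
                          age = NA_real_) {
  .check_category(category)
  stopifnot(is.finite(total))
  bonus <- switch(category,
    O = 0,
    S = if (isTRUE(has_listed_skin_condition)) 4 else 0,
    P = if (isTRUE(sun_aggravates_moles)) 5 else 0,
    W = if (!is.na(age) && age > 65) 5 else 0)
  if (total + bonus >= .bsti_thresholds[[category]])
    .bsti_high[[category]] else .bsti_low[[category]]
}

#' Classify a full questionnaire response into a 16-type label
#'
#' @param items numeric vector of 59 scored responses ordered O (11), S (18),
#'   P (10), W (20), or a list with components `O`, `S`, `P`, `W`. Values in
#'   \{1,2,3,4\} or `NA`.
#' @param has_listed_skin_condition,sun_aggravates_moles,age bonus inputs,
#'   see [classify_axis()].
#' @return a list with `raw` (named category totals), `adjusted` (totals after
#'   bonuses), `axes` (named letters) and `label` (4-character type).
#' @examples
#' classify_bsti(rep(1, 59), age = 30)$label # "DRNT"
#' @export
classify_bsti <- function(items,
                          has_listed_skin_condition = FALSE,
                          sun_aggravates_moles = FALSE,
                          age = NA_real_) {
  if (!is.list(items)) {
    if (length(items) != sum(.bsti_category_sizes))
      stop("expected ", sum(.bsti_category_sizes),
           " scored items, got ", length(items))
    idx <- rep(names(.bsti_category_sizes), .bsti_category_sizes)
    items <- split(as.numeric(items), factor(idx, names(.bsti_category_sizes)))
  }
  raw <- vapply(names(.bsti_category_sizes),
                function(cat) score_category(items[[cat]], cat),
                numeric(1))
  bonus <- c(O = 0,
             S = if (isTRUE(has_listed_skin_condition)) 4 else 0,
             P = if (isTRUE(sun_aggravates_moles)) 5 else 0,
             W = if (!is.na(age) && age > 65) 5 else 0)
  axes <- vapply(names(raw), function(cat)
    classify_axis(raw[[cat]], cat,
                  has_listed_skin_condition = has_listed_skin_condition,
                  sun_aggravates_moles = sun_aggravates_moles,
                  age = age), character(1))
  list(raw = raw, adjusted = raw + bonus[names(raw)], axes = axes,
       label = paste(axes, collapse = ""))
}

#' All 16 reachable type labels
#'
#' @return character vector of the 16 labels in O/D x S/R x P/N x W/T order.
#' @export
bsti_labels <- function() {
  g <- expand.grid(W = c("T", "W"), P = c("N", "P"),
                   S = c("R", "S"), O = c("D", "O"),
                   stringsAsFactors = FALSE)
  sort(paste0(g$O, g$S, g$P, g$W))
}

#' Tabulate type labels with percentages
#'
#' @param types character vector of 4-letter type labels.
#' @return data.frame with `label` (all 16, zero-filled), `n` and `percent`;
#'   percentages sum to 100.
#' @export
type_distribution <- function(types) {
  if (length(types) == 0) stop("empty type list")
  labels <- bsti_labels()
  bad <- setdiff(unique(types), labels)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  n <- as.vector(table(factor(types, levels = labels)))
  data.frame(label = labels, n = n,
             percent = 100 * n / length(types),
             stringsAsFactors = FALSE)
}

#' Score a questionnaire table
#'
#' Applies [classify_bsti()] row-wise to a table in the shipped layout:
#' columns `q01`..`q59` are the scored items (O items first, then S, P, W),
#' `q60` an unscored control item (ignored), plus `has_listed_skin_condition`,
#' `sun_aggravates_moles` and `age`.
#'
#' @param responses data.frame, one row per subject; a `subject_id` column is
#'   carried through if present.
#' @return data.frame with subject id, four raw totals, four adjusted totals
#'   and the 16-type `label`.
#' @export
score_questionnaire <- function(responses) {
  qcols <- sprintf("q%02d", 1:59)
  missing_cols <- setdiff(qcols, names(responses))
  if (length(missing_cols))
    stop("missing item columns: ", paste(missing_cols, collapse = ", "))
  ids <- if ("subject_id" %in% names(responses)) responses$subject_id
         else seq_len(nrow(responses))
  out <- lapply(seq_len(nrow(responses)), function(i) {
    r <- classify_bsti(
      as.numeric(unlist(responses[i, qcols])),
      has_listed_skin_condition = isTRUE(responses$has_listed_skin_condition[i]),
      sun_aggravates_moles = isTRUE(responses$sun_aggravates_moles[i]),
      age = if ("age" %in% names(responses)) responses$age[i] else NA_real_)
    c(as.list(stats::setNames(r$raw, paste0("raw_", names(r$raw)))),
      as.list(stats::setNames(r$adjusted, paste0("adj_", names(r$adjusted)))),
      label = r$label)
  })
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
        do.call(rbind, lapply(out, as.data.frame)))
}
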