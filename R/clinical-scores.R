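#' Nine-hole pegboard improvement
#'
#' The change in time-to-complete, POST minus PRE, in seconds. A negative
#' value means the patient completed the test faster after therapy.
#'
#' @param pre_s,post_s Completion times in seconds (may be vectors).
#' @return `post_s - pre_s`; `NA` wherever either time is missing.
#' @export
pegboard_improvement <- function(pre_s, post_s) {
  if (is.data.frame(pre_s)) {
    post_s <- pre_s$pegboard_post_s
    pre_s <- pre_s$pegboard_pre_s
  }
  ifelse(is.na(pre_s) | is.na(post_s), NA_real_, post_s - pre_s)
}

#' Long-format pegboard table for repeated-measures analysis
#'
#' Reshapes a cohort's PRE/POST nine-hole pegboard times into the long
#' format expected by [mixed_anova()].
#'
#' @param cohort A `cohort` object (or its `patients` data frame).
#' @return Data frame with columns `subject`, `group`, `timepoint`
#'   (factor, PRE then POST) and `time_s`.
#' @export
pegboard_long <- function(cohort) {
  pts <- if (inherits(cohort, "cohort")) cohort$patients else cohort
  out <- rbind(
    data.frame(subject = pts$patient_id, group = pts$group,
               timepoint = "PRE", time_s = pts$pegboard_pre_s),
    data.frame(subject = pts$patient_id, group = pts$group,
               timepoint = "POST", time_s = pts$pegboard_post_s)
  )
  out$timepoint <- factor(out$timepoint, levels = c("PRE", "POST"))
  out
}

#' Default POMS item-to-subscale mapping
#'
#' The 35-item short form loads onto four subscales: depression/anxiety
#' (14 items), fatigue (7), vigor (7) and hostility (7). The published
#' instrument does not fix a canonical item order for re-implementations,
#' so the default assigns items 1-14 to depression/anxiety, 15-21 to
#' fatigue, 22-28 to vigor and 29-35 to hostility; studies using a
#' different item order should pass their own mapping (a length-35
#' character vector, or a CSV with columns `item`, `subscale` via
#' [read_poms_mapping()]).
#'
#' @return Character vector of length 35 naming each item's subscale.
#' @export
poms_mapping <- function() {
  c(rep("depression_anxiety", 14), rep("fatigue", 7), rep("vigor", 7),
    rep("hostility", 7))
}

#' Read a POMS mapping from CSV
#'
#' @param path CSV with columns `item` (1..35) and `subscale`.
#' @return Character vector of length 35 (ordered by item).
#' @export
read_poms_mapping <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("item", "subscale") %in% names(df)) || nrow(df) != 35L ||
      !setequal(df$item, 1:35)) {
    stop("POMS mapping CSV must cover items 1..35 exactly once", call. = FALSE)
  }
  as.character(df$subscale[order(df$item)])
}

#' Score the POMS questionnaire into its four subscales
#'
#' Each subscale score is the sum of its items' ratings. Ratings run from 1
#' (not at all) to 5 (very strongly).
#'
#' @param items Numeric vector of exactly 35 ratings, each in 1..5.
#' @param mapping Item-to-subscale mapping (default [poms_mapping()]); must
#'   assign every item to exactly one of the four subscales.
#' @return Named list of class `poms_scores` with `depression_anxiety`,
#'   `fatigue`, `vigor`, `hostility`.
#' @export
score_poms <- function(items, mapping = poms_mapping()) {
  if (length(items) != 35L) {
    stop("validation error: POMS needs exactly 35 item ratings, got ",
         length(items), call. = FALSE)
  }
  if (anyNA(items) || any(items < 1 | items > 5) || any(items != round(items))) {
    stop("validation error: POMS ratings must be integers in 1..5", call. = FALSE)
  }
  subscales <- c("depression_anxiety", "fatigue", "vigor", "hostility")
  if (length(mapping) != 35L || !all(mapping %in% subscales)) {
    stop("validation error: mapping must assign all 35 items to the four subscales",
         call. = FALSE)
  }
  out <- lapply(subscales, function(s) sum(items[mapping == s]))
  names(out) <- subscales
  class(out) <- "poms_scores"
  out
}

#' Score every POMS row of a cohort
#'
#' @param poms A data frame with `patient_id`, `timepoint` and item columns
#'   `item_01` .. `item_35` (as produced by [generate_cohort()]).
#' @param mapping Item-to-subscale mapping.
#' @return Data frame with one row per input row and one column per subscale.
#' @export
score_poms_table <- function(poms, mapping = poms_mapping()) {
  item_cols <- sprintf("item_%02d", 1:35)
  stopifnot(all(item_cols %in% names(poms)))
  scores <- t(apply(as.matrix(poms[, item_cols]), 1L, function(items) {
    unlist(score_poms(as.numeric(items), mapping))
  }))
  cbind(poms[, c("patient_id", "timepoint")], as.data.frame(scores))
}

#' Default faces scale
#'
#' An ordered mood scale of 7 face drawings, coded by letter from saddest
#' (`"A"`, ordinal 1) to happiest (`"G"`, ordinal 7). The number of faces
#' and direction are conventions of this implementation and configurable.
#'
#' @param n_faces Number of faces (default 7).
#' @return Character vector of letter codes ordered from saddest to happiest.
#' @export
faces_scale <- function(n_faces = 7) {
  stopifnot(n_faces >= 2, n_faces <= 26)
  LETTERS[seq_len(n_faces)]
}

#' Convert a faces-scale letter code to its ordinal value
#'
#' Higher values mean happier; the saddest face maps to 1 and the happiest
#' to `length(scale)`.
#'
#' @param letter Letter code(s) written down by the therapist.
#' @param scale Ordered face list, saddest first (default [faces_scale()]).
#' @return Integer ordinal value(s).
#' @export
faces_to_numeric <- function(letter, scale = faces_scale()) {
  idx <- match(letter, scale)
  if (anyNA(idx)) {
    stop("validation error: unknown face letter code: ",
         paste(letter[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Convert an ordinal faces value back to its letter code
#'
#' @param value Ordinal value(s) in `1..length(scale)`.
#' @param scale Ordered face list, saddest first.
#' @return Letter code(s).
#' @export
numeric_to_faces <- function(value, scale = faces_scale()) {
  if (any(value < 1 | value > length(scale) | value != round(value))) {
    stop("validation error: ordinal outside the faces scale", call. = FALSE)
  }
  scale[value]
}
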