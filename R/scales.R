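#' Canonical item names for the six-item binary frailty screen (ZFS)
#'
#' The Zulfiqar Frailty Scale asks six yes/no questions: weight loss of at
#' least 5\% of body weight over six months, inability to hold a monopodal
#' stance for five seconds, living alone at home, presence of professional
#' aid at home, a subjective memory complaint, and polypharmacy (five or
#' more therapeutic classes).
#'
#' @return Character vector of the six item names, in canonical order.
#' @export
zfs_items <- function() {
  c("weight_loss", "monopodal", "lives_alone", "home_aid",
    "memory", "polypharmacy")
}

#' Canonical item names for the modified SEGA grid A
#'
#' Thirteen ordinal items, each coded 0 (no deficit), 1, or 2 (marked
#' deficit), summing to a total out of 26. The clinical rubric behind each
#' code is consumed pre-coded; this package works on the 0/1/2 values.
#'
#' @return Character vector of the thirteen item names, in canonical order.
#' @export
msega_items <- function() {
  c("age", "provenance", "medications", "mood", "perception_of_health",
    "fall_6_months", "nutrition", "sicknesses", "iadl", "mobility",
    "continence", "meals", "cognition")
}

# Normalize one binary answer to 0/1; accepts logicals, 0/1 numerics and
# yes/no (also oui/non) strings, case-insensitively. NA passes through.
normalize_binary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) {
      stop("binary item value out of {0,1}: ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    return(as.integer(x))
  }
  if (is.character(x) || is.factor(x)) {
    s <- tolower(trimws(as.character(x)))
    out <- rep(NA_integer_, length(s))
    out[s %in% c("yes", "oui", "y", "1", "true")] <- 1L
    out[s %in% c("no", "non", "n", "0", "false")] <- 0L
    bad <- !is.na(s) & s != "" & is.na(out)
    if (any(bad)) {
      stop("unrecognized binary answer: ", paste(unique(s[bad]), collapse = ", "),
           call. = FALSE)
    }
    return(out)
  }
  stop("cannot interpret value of class ", class(x)[1], " as a binary answer",
       call. = FALSE)
}

#' Score the six-item binary frailty screen
#'
#' The score is the number of "yes" answers. Patients scoring 0 are
#' classified robust, 1-2 pre-frail, and at or above `threshold`
#' (default 3) frail. Missing answers are rejected, never imputed: the
#' scale was designed for complete administration.
#'
#' @param responses Named list or vector with entries for each of
#'   [zfs_items()]; values may be logical, 0/1, or yes/no strings.
#' @param threshold Integer in 1..6; minimum score classified as frail.
#' @return A list of class `zfs_result` with `score` (0-6), `category`
#'   (`"robust"`, `"pre_frail"` or `"frail"`), and `frail` (logical).
#' @examples
#' score_zfs(c(weight_loss = 0, monopodal = 1, lives_alone = 1,
#'             home_aid = 0, memory = 0, polypharmacy = 1))
#' @export
score_zfs <- function(responses, threshold = 3L) {
  stopifnot(length(threshold) == 1L, threshold >= 1, threshold <= 6)
  items <- zfs_items()
  responses <- as.list(responses)
  missing_items <- setdiff(items, names(responses))
  if (length(missing_items)) {
    stop("missing ZFS item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(items, function(it) normalize_binary(responses[[it]])[1L],
                 integer(1))
  if (anyNA(vals)) {
    stop("ZFS item(s) answered NA: ",
         paste(items[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  score <- sum(vals)
  category <- zfs_category(score, threshold)
  structure(list(score = score, category = category,
                 frail = category == "frail", threshold = as.integer(threshold)),
            class = "zfs_result")
}

# Vectorized score -> category map shared by scoring and the cut-point sweep.
zfs_category <- function(score, threshold = 3L) {
  ifelse(score >= threshold, "frail", ifelse(score >= 1, "pre_frail", "robust"))
}

#' Score the modified SEGA grid A
#'
#' The total is the plain sum of the thirteen 0/1/2 items (out of 26).
#' Totals of 8 or less are classified not frail, 9-11 frail, and above 11
#' very frail; the binary frailty flag used for validation is total > 8.
#'
#' @param responses Named list or vector with an entry in \{0, 1, 2\} for
#'   each of [msega_items()].
#' @return A list of class `msega_result` with `total` (0-26), `category`
#'   (`"not_frail"`, `"frail"` or `"very_frail"`), and `frail` (logical,
#'   total > 8).
#' @examples
#' score_msega(stats::setNames(rep(1, 13), msega_items()))
#' @export
score_msega <- function(responses) {
  items <- msega_items()
  responses <- as.list(responses)
  missing_items <- setdiff(items, names(responses))
  if (length(missing_items)) {
    stop("missing mSEGA item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(items, function(it) {
    v <- responses[[it]][1L]
    if (is.na(v)) stop("mSEGA item answered NA: ", it, call. = FALSE)
    if (!is.numeric(v) || !(v %in% c(0, 1, 2))) {
      stop("mSEGA item '", it, "' has value ", v, " outside {0,1,2}",
           call. = FALSE)
    }
    as.integer(v)
  }, integer(1))
  total <- sum(vals)
  category <- msega_category(total)
  structure(list(total = total, category = category, frail = total > 8L),
            class = "msega_result")
}

msega_category <- function(total) {
  ifelse(total > 11, "very_frail", ifelse(total > 8, "frail", "not_frail"))
}

#' @export
print.zfs_result <- function(x, ...) {
  cat(sprintf("ZFS score %d/6 -> %s (frail threshold >= %d)\n",
              x$score, x$category, x$threshold))
  invisible(x)
}

#' @export
print.msega_result <- function(x, ...) {
  cat(sprintf("mSEGA grid A total %d/26 -> %s\n", x$total, x$category))
  invisible(x)
}

#' Score a whole cohort on both scales
#'
#' Takes a cohort table with the `zfs_`-prefixed binary columns and
#' `msega_`-prefixed ordinal columns (see [read_cohort()]) and returns one
#' row per patient with both totals and both binary frailty flags, in
#' input order.
#'
#' @param cohort Data frame with columns `zfs_<item>` for each of
#'   [zfs_items()] and `msega_<item>` for each of [msega_items()];
#'   an optional `patient_id` column is carried through.
#' @param threshold ZFS frailty threshold (default 3).
#' @param msega_cutoff mSEGA total above which a patient counts frail
#'   (default 8).
#' @param strict If `TRUE` (default) any incomplete row is an error; if
#'   `FALSE`, incomplete rows are dropped with a message listing their
#'   identifiers.
#' @return Data frame with `patient_id`, `zfs_score`, `zfs_frail`,
#'   `msega_total`, `msega_frail`.
#' @export
cohort_scores <- function(cohort, threshold = 3L, msega_cutoff = 8L,
                          strict = TRUE) {
  stopifnot(is.data.frame(cohort))
  zcols <- paste0("zfs_", zfs_items())
  mcols <- paste0("msega_", msega_items())
  missing_cols <- setdiff(c(zcols, mcols), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ids <- if ("patient_id" %in% names(cohort)) as.character(cohort$patient_id)
         else as.character(seq_len(nrow(cohort)))
  if (nrow(cohort) == 0L) {
    return(data.frame(patient_id = character(), zfs_score = integer(),
                      zfs_frail = logical(), msega_total = integer(),
                      msega_frail = logical(), stringsAsFactors = FALSE))
  }
  zmat <- sapply(cohort[zcols], normalize_binary)
  zmat <- matrix(zmat, nrow = nrow(cohort))
  mmat <- as.matrix(cohort[mcols])
  bad_m <- !is.na(mmat) & !(mmat %in% c(0, 1, 2))
  if (any(bad_m) && strict) {
    idx <- which(bad_m, arr.ind = TRUE)[1, ]
    stop("mSEGA value out of {0,1,2} at patient ", ids[idx[1]],
         ", item ", msega_items()[idx[2]], call. = FALSE)
  }
  incomplete <- apply(is.na(zmat), 1, any) | apply(is.na(mmat) | bad_m, 1, any)
  if (any(incomplete)) {
    if (strict) {
      stop("incomplete scale data for patient(s): ",
           paste(ids[incomplete], collapse = ", "), call. = FALSE)
    }
    message("dropping ", sum(incomplete), " incomplete patient record(s): ",
            paste(ids[incomplete], collapse = ", "))
    zmat <- zmat[!incomplete, , drop = FALSE]
    mmat <- mmat[!incomplete, , drop = FALSE]
    ids <- ids[!incomplete]
  }
  zfs_score <- as.integer(rowSums(zmat))
  msega_total <- as.integer(rowSums(mmat))
  data.frame(patient_id = ids,
             zfs_score = zfs_score,
             zfs_frail = zfs_score >= threshold,
             msega_total = msega_total,
             msega_frail = msega_total > msega_cutoff,
             stringsAsFactors = FALSE)
}
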