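cohort_scale_columns <- function() {
  c(paste0("zfs_", zfs_items()), paste0("msega_", msega_items()))
}

cohort_demographic_columns <- function() {
  c("age", "sex", "weight_kg", "height_cm", "adl", "iadl",
    "n_medications", "charlson")
}

#' Read a cohort table from a delimited file
#'
#' Expects a comma-separated file with a header, one row per patient:
#' `patient_id`, the six `zfs_*` binary columns (0/1; yes/no and oui/non
#' are accepted case-insensitively and normalized), the thirteen
#' `msega_*` ordinal columns (0/1/2), and optional demographics. In
#' strict mode any out-of-alphabet or missing scale value is an error
#' reported with its row and column; otherwise incomplete rows are
#' dropped with a message.
#'
#' @param path Input file.
#' @param strict Reject (`TRUE`) or drop-with-message (`FALSE`, default)
#'   rows with incomplete or invalid scale data.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", cohort_scale_columns())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$patient_id)) {
    stop("duplicate patient_id(s): ",
         paste(unique(raw$patient_id[duplicated(raw$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) < 1) stop("cohort file has no rows", call. = FALSE)

  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  bad_rows <- rep(FALSE, nrow(raw))
  for (col in paste0("zfs_", zfs_items())) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    parsed <- tryCatch(normalize_binary(v), error = function(e) e)
    if (inherits(parsed, "error")) {
      if (strict) {
        bad <- which(!tolower(trimws(v)) %in%
                       c("0", "1", "yes", "no", "oui", "non", "y", "n",
                         "true", "false") & !is.na(v))[1]
        stop("invalid binary value '", v[bad], "' at row ", bad,
             ", column ", col, call. = FALSE)
      }
      parsed <- suppressWarnings(vapply(v, function(x) {
        tryCatch(normalize_binary(x), error = function(e) NA_integer_)
      }, integer(1), USE.NAMES = FALSE))
    }
    if (strict && anyNA(parsed)) {
      stop("missing value at row ", which(is.na(parsed))[1], ", column ", col,
           call. = FALSE)
    }
    bad_rows <- bad_rows | is.na(parsed)
    out[[col]] <- parsed
  }
  for (col in paste0("msega_", msega_items())) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    invalid <- !is.na(v) & !(v %in% c(0, 1, 2))
    if (strict && any(invalid)) {
      stop("value '", raw[[col]][which(invalid)[1]], "' out of {0,1,2} at row ",
           which(invalid)[1], ", column ", col, call. = FALSE)
    }
    if (strict && anyNA(v)) {
      stop("missing value at row ", which(is.na(v))[1], ", column ", col,
           call. = FALSE)
    }
    v[invalid] <- NA
    bad_rows <- bad_rows | is.na(v)
    out[[col]] <- as.integer(v)
  }
  for (col in intersect(cohort_demographic_columns(), names(raw))) {
    out[[col]] <- if (col == "sex") raw[[col]]
                  else suppressWarnings(as.numeric(raw[[col]]))
  }
  if (any(bad_rows)) {
    message("dropping ", sum(bad_rows), " row(s) with incomplete scale data: ",
            paste(out$patient_id[bad_rows], collapse = ", "))
    out <- out[!bad_rows, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nrow(out) < 1) stop("no complete rows after validation", call. = FALSE)
  out
}

#' Write a cohort table to a delimited file
#'
#' Canonical column order (id, screening items, reference items,
#' demographics), UTF-8, dot decimal separator, newline-terminated.
#' Writing the same cohort twice produces identical bytes.
#'
#' @param cohort Cohort data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  cols <- c("patient_id", cohort_scale_columns(),
            intersect(cohort_demographic_columns(), names(cohort)))
  missing_cols <- setdiff(c("patient_id", cohort_scale_columns()), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(cohort[cols], con, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' Full validation report for a dual-scale cohort
#'
#' Assembles, from a cohort scored on both scales: cohort descriptives;
#' per-item diagnostic accuracy (Se/Sp/PPV/NPV, risk ratio, association
#' p-value) against reference frailty (mSEGA total > `msega_cutoff`) and
#' against the screening scale's own frailty classification; the full
#' integer cut-point table with AUC and the Youden-optimal threshold; and
#' the total-score correlation with its Fisher-z interval. Confidence
#' intervals are an extension beyond the published tables and are labeled
#' as such. A degenerate stratum (no frail, or no non-frail, patients by
#' either definition) flags the affected sections instead of aborting;
#' `status` is then `"degenerate"` rather than `"ok"`.
#'
#' @param cohort Cohort data frame.
#' @param zfs_threshold Screening-scale frailty threshold (default 3).
#' @param msega_cutoff Reference-scale frailty cutoff, frail iff total >
#'   cutoff (default 8).
#' @param level Confidence level for all intervals.
#' @return A list of class `validation_report`.
#' @export
validation_report <- function(cohort, zfs_threshold = 3L, msega_cutoff = 8L,
                              level = 0.95) {
  scores <- cohort_scores(cohort, threshold = zfs_threshold,
                          msega_cutoff = msega_cutoff)
  n <- nrow(scores)
  flags <- character()

  descriptives <- list(
    n = n,
    zfs_mean = mean(scores$zfs_score), zfs_sd = stats::sd(scores$zfs_score),
    msega_mean = mean(scores$msega_total),
    msega_sd = stats::sd(scores$msega_total),
    zfs_classification = table(factor(zfs_category(scores$zfs_score,
                                                   zfs_threshold),
                                      c("robust", "pre_frail", "frail"))),
    zfs_screen_positive = sum(scores$zfs_score >= 1),
    msega_classification = table(factor(msega_category(scores$msega_total),
                                        c("not_frail", "frail", "very_frail"))))

  item_diag <- function(condition, condition_name) {
    if (all(condition) || !any(condition)) {
      flags <<- c(flags, paste0("degenerate stratum: all patients are ",
                                if (all(condition)) "" else "non-",
                                "frail by ", condition_name))
      return(NULL)
    }
    zmat <- sapply(cohort[paste0("zfs_", zfs_items())], normalize_binary)
    rows <- lapply(zfs_items(), function(item) {
      tab <- crosstab(zmat[, paste0("zfs_", item)] == 1, condition)
      metrics <- diag_metrics(tab, level)
      assoc <- association_p(tab)
      list(item = item, table = tab, metrics = metrics,
           risk_ratio = risk_ratio(tab), rr_ci = rr_ci(tab, level),
           p_value = assoc$p_value, p_method = assoc$method)
    })
    stats::setNames(rows, zfs_items())
  }

  vs_reference <- item_diag(scores$msega_frail, "the reference scale")
  vs_self <- item_diag(scores$zfs_frail, "the screening scale")

  roc <- NULL
  if (!is.null(vs_reference)) {
    dist <- score_distribution(scores$zfs_score, scores$msega_frail)
    curve <- cutpoint_table(dist)
    roc <- list(distribution = dist, curve = curve, auc = auc(dist),
                optimal_cutpoint = optimal_cutpoint(curve))
  }

  corr <- tryCatch(item_matrix(cohort, level), error = function(e) NULL)
  totals <- if (!is.null(corr)) {
    list(r = attr(corr, "totals_r"), ci = attr(corr, "totals_ci"), n = n)
  } else {
    flags <- c(flags, "correlation section unavailable")
    NULL
  }

  structure(list(
    descriptives = descriptives,
    vs_reference = vs_reference,
    vs_self = vs_self,
    roc = roc,
    correlation = totals,
    item_matrix = corr,
    flags = flags,
    status = if (length(flags)) "degenerate" else "ok",
    meta = list(zfs_threshold = as.integer(zfs_threshold),
                msega_cutoff = as.integer(msega_cutoff), ci_level = level,
                package_version = as.character(utils::packageVersion("frailscreen")))),
    class = "validation_report")
}

fmt_pct <- function(p) if (is.na(p)) "undef" else sprintf("%.0f%%", 100 * p)

#' @export
print.validation_report <- function(x, ...) {
  d <- x$descriptives
  cat("== Frailty screening-scale validation report ==\n")
  cat(sprintf("n = %d patients; ZFS mean %.2f (sd %.2f); mSEGA mean %.2f (sd %.2f)\n",
              d$n, d$zfs_mean, d$zfs_sd, d$msega_mean, d$msega_sd))
  cat(sprintf("ZFS classification: robust %d / pre-frail %d / frail %d (screen-positive >=1: %d)\n",
              d$zfs_classification[["robust"]],
              d$zfs_classification[["pre_frail"]],
              d$zfs_classification[["frail"]], d$zfs_screen_positive))
  cat(sprintf("mSEGA classification: not frail %d / frail %d / very frail %d\n",
              d$msega_classification[["not_frail"]],
              d$msega_classification[["frail"]],
              d$msega_classification[["very_frail"]]))
  print_item_block <- function(block, label) {
    if (is.null(block)) return(invisible())
    cat(sprintf("\n-- Per-item accuracy vs %s --\n", label))
    cat(sprintf("%-14s %5s %5s %5s %5s %8s %8s %s\n",
                "item", "Se", "Sp", "PPV", "NPV", "RR", "p", "test"))
    for (row in block) {
      m <- row$metrics
      cat(sprintf("%-14s %5s %5s %5s %5s %8s %8.3f %s\n", row$item,
                  fmt_pct(m$sensitivity), fmt_pct(m$specificity),
                  fmt_pct(m$ppv), fmt_pct(m$npv),
                  if (is.na(row$risk_ratio)) "undef"
                  else sprintf("%.2f", row$risk_ratio),
                  row$p_value, row$p_method))
    }
  }
  print_item_block(x$vs_reference, "reference (mSEGA) frailty")
  print_item_block(x$vs_self, "screening-scale frailty")
  if (!is.null(x$roc)) {
    cat("\n-- ROC cut-point analysis vs reference frailty --\n")
    curve <- x$roc$curve
    cat(sprintf("%8s %8s %5s %5s %7s %5s %5s\n",
                "cutpoint", "1-Sp", "Se", "Sp", "Youden", "PPV", "NPV"))
    for (i in seq_len(nrow(curve))) {
      cat(sprintf("%8d %8.4f %5s %5s %7s %5s %5s\n", curve$cutpoint[i],
                  curve$one_minus_sp[i], fmt_pct(curve$se[i]),
                  fmt_pct(curve$sp[i]), fmt_pct(curve$youden[i]),
                  fmt_pct(curve$ppv[i]), fmt_pct(curve$npv[i])))
    }
    cat(sprintf("AUC = %.5f; optimal cut-point (max Youden) = %d\n",
                x$roc$auc, x$roc$optimal_cutpoint))
  }
  if (!is.null(x$correlation) && !is.na(x$correlation$r)) {
    cat(sprintf("\nTotal-score correlation r = %.2f [%.2f; %.2f] (Fisher z, %d%% CI)\n",
                x$correlation$r, x$correlation$ci[["lower"]],
                x$correlation$ci[["upper"]], round(100 * x$meta$ci_level)))
  }
  if (length(x$flags)) {
    cat("\nFLAGS:\n")
    for (fl in x$flags) cat("  - ", fl, "\n", sep = "")
  }
  cat(sprintf("\nstatus: %s (ZFS threshold >= %d, mSEGA cutoff > %d; CIs are an extension beyond the published tables)\n",
              x$status, x$meta$zfs_threshold, x$meta$msega_cutoff))
  invisible(x)
}

#' Machine-readable form of a validation report
#'
#' Mirrors every rendered number one-to-one (stored proportions, not the
#' rounded percentages), so there is no drift between the printed view
#' and downstream tooling.
#'
#' @param report A [validation_report()].
#' @return A nested list suitable for `jsonlite::toJSON()`.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  item_block <- function(block) {
    if (is.null(block)) return(NULL)
    lapply(block, function(row) {
      m <- row$metrics
      list(table = list(tp = row$table$tp, fp = row$table$fp,
                        fn = row$table$fn, tn = row$table$tn),
           sensitivity = m$sensitivity, specificity = m$specificity,
           ppv = m$ppv, npv = m$npv, youden = m$youden,
           ci = m$ci, undefined = m$undefined,
           risk_ratio = row$risk_ratio,
           rr_ci = as.list(row$rr_ci),
           p_value = row$p_value, p_method = row$p_method)
    })
  }
  d <- report$descriptives
  list(
    descriptives = list(
      n = d$n, zfs_mean = d$zfs_mean, zfs_sd = d$zfs_sd,
      msega_mean = d$msega_mean, msega_sd = d$msega_sd,
      zfs_classification = as.list(d$zfs_classification),
      zfs_screen_positive = d$zfs_screen_positive,
      msega_classification = as.list(d$msega_classification)),
    vs_reference = item_block(report$vs_reference),
    vs_self = item_block(report$vs_self),
    roc = if (!is.null(report$roc)) list(
      curve = report$roc$curve[, c("cutpoint", "one_minus_sp", "se", "sp",
                                   "youden", "ppv", "npv")],
      auc = report$roc$auc,
      optimal_cutpoint = report$roc$optimal_cutpoint),
    correlation = report$correlation,
    flags = report$flags, status = report$status, meta = report$meta)
}

#' Write a validation report as JSON
#'
#' @param report A [validation_report()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "string", pretty = TRUE)
  invisible(path)
}
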