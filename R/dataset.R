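#' Validate participant-level records
#'
#' Checks the column contract for participant records: `arm` (two-arm factor or
#' character), `age` (years), `sex` (1 = female), `diabetes` (1 = history),
#' `event` (1 = any qualifying event during follow-up), `fatal`,
#' `severity_attr` (free severity tag, `NA` when no event or fatal),
#' `time` (days from randomization to event or censoring) and `observed`
#' (1 iff the event was observed). `time`/`observed` may be absent, in which
#' case time-to-event methods are skipped downstream.
#'
#' Invariants enforced: `fatal = 1` implies `event = 1`; a non-missing
#' `severity_attr` implies `event = 1`; `time >= 0`; `observed = 1` iff
#' `event = 1`.
#'
#' @param records data frame of participant records.
#' @return `records`, invisibly, or an error describing the violation.
#' @export
validate_participants <- function(records) {
  required <- c("arm", "age", "sex", "diabetes", "event", "fatal", "severity_attr")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("participant records lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(records$fatal == 1L & records$event != 1L))
    stop("invariant violated: fatal = 1 implies event = 1")
  sa <- records$severity_attr
  if (any(!is.na(sa) & sa != "" & records$event != 1L))
    stop("invariant violated: non-missing severity_attr implies event = 1")
  if ("time" %in% names(records)) {
    if (any(records$time < 0, na.rm = TRUE))
      stop("invariant violated: time must be >= 0")
    if ("observed" %in% names(records) &&
        any(records$observed != records$event))
      stop("invariant violated: observed = 1 iff event = 1")
  }
  invisible(records)
}

#' Construct a comparator dataset
#'
#' One two-arm treatment-versus-control comparison. A multi-arm trial
#' contributes several comparator datasets (see [expand_comparisons()]), which
#' then share the control arm's records.
#'
#' @param id dataset identifier.
#' @param records participant records with `arm` taking exactly the two values
#'   `"treatment"` and `"control"`, each with at least 2 records.
#' @param tags named character vector of metadata (e.g.
#'   `c(prevention = "secondary", intervention = "APT")`) used by subgroup
#'   comparisons.
#' @param validate set `FALSE` to skip invariant checks (used internally for
#'   bootstrap resamples, where an arm may transiently fall below 2 records).
#' @return An object of class `comparator_dataset`.
#' @export
comparator_dataset <- function(id, records, tags = character(), validate = TRUE) {
  records$arm <- factor(as.character(records$arm), levels = c("control", "treatment"))
  if (validate) {
    validate_participants(records)
    if (anyNA(records$arm))
      stop("arm must be 'treatment' or 'control'")
    tab <- table(records$arm)
    if (length(tab) != 2L || any(tab < 2L))
      stop("a comparator dataset needs both arms with >= 2 records each")
  }
  structure(list(id = as.character(id), records = records,
                 tags = tags), class = "comparator_dataset")
}

#' @export
print.comparator_dataset <- function(x, ...) {
  tab <- table(x$records$arm)
  cat("Comparator dataset '", x$id, "': ",
      tab[["treatment"]], " treatment vs ", tab[["control"]], " control; ",
      sum(x$records$event), " events\n", sep = "")
  if (length(x$tags))
    cat("  tags: ", paste(names(x$tags), x$tags, sep = "=", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Expand a multi-arm trial into comparator datasets
#'
#' Trials with more than two treatment groups are analysed once per treatment
#' comparison; control records are shared between the resulting datasets. Arms
#' are relabelled `"treatment"`/`"control"`, observed outcome data are carried
#' over as-is and no imputation is performed.
#'
#' @param records participant records whose `arm` column holds the trial's
#'   original arm labels.
#' @param plan list of length-2 character vectors `c(treatment_arm, control_arm)`.
#' @param trial_id prefix for the generated dataset ids.
#' @param tags metadata tags copied onto every generated dataset.
#' @return named list of [comparator_dataset()] objects, one per plan pair.
#' @export
#' @examples
#' r <- data.frame(arm = rep(c("A", "B", "C"), each = 4),
#'                 age = 65, sex = 0, diabetes = 0, event = 0, fatal = 0,
#'                 severity_attr = NA_character_, time = 365, observed = 0)
#' length(expand_comparisons(r, list(c("A", "C"), c("B", "C"))))  # 2
expand_comparisons <- function(records, plan, trial_id = "trial", tags = character()) {
  validate_participants(records)
  arms <- unique(as.character(records$arm))
  out <- list()
  for (pair in plan) {
    if (length(pair) != 2L)
      stop("each plan entry must be c(treatment_arm, control_arm)")
    if (pair[1L] == pair[2L])
      stop("degenerate plan pair: treatment and control arm are both '",
           pair[1L], "'")
    unknown <- setdiff(pair, arms)
    if (length(unknown))
      stop("unknown arm(s) in plan: ", paste(sQuote(unknown), collapse = ", "))
    keep <- records[as.character(records$arm) %in% pair, , drop = FALSE]
    keep$arm <- ifelse(as.character(keep$arm) == pair[1L], "treatment", "control")
    id <- paste0(trial_id, "_", pair[1L], "_vs_", pair[2L])
    out[[id]] <- comparator_dataset(id, keep, tags = tags)
  }
  out
}

#' Read participant-level records from CSV
#'
#' Expects a UTF-8, comma-delimited file with a header row; columns named as in
#' [validate_participants()]; booleans coded 0/1; empty `severity_attr` read as
#' missing. Absent `time`/`observed` columns are allowed, but time-to-event
#' methods will then be flagged degenerate with a warning downstream.
#'
#' @param path CSV file path.
#' @return validated data frame of participant records.
#' @export
read_participants <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("severity_attr" %in% names(records)) {
    records$severity_attr <- as.character(records$severity_attr)
    records$severity_attr[records$severity_attr == ""] <- NA_character_
  }
  validate_participants(records)
  records
}

#' Write participant-level records to CSV
#'
#' @param records participant records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  validate_participants(records)
  out <- records
  out$severity_attr[is.na(out$severity_attr)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
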