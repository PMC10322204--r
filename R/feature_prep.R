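#' Assign clinical groups from MMSE scores
#'
#' Applies the standard clinical cutoffs: a score of 28 or more is healthy,
#' 24–27 is mild cognitive impairment (MCI), and 23 or less is cognitive
#' disease (CD).  CD subjects are merged into the MCI group for
#' discrimination, but flagged so cohort summaries can still report them.
#'
#' @param score Integer MMSE score(s) on the 0–30 scale.
#' @return Character vector in `{"healthy", "MCI"}` with a logical
#'   attribute `"cd"` marking scores of 23 or less.
#' @examples
#' classify_mmse(c(28, 27, 24, 23))
#' @export
classify_mmse <- function(score) {
  if (length(score) == 0) return(character(0))
  if (any(!is.finite(score)) || any(score != floor(score)))
    stopf("MMSE scores must be integers")
  if (any(score < 0 | score > 30))
    stopf("MMSE scores must lie in 0..30 (got %s)",
          paste(score[score < 0 | score > 30], collapse = ", "))
  group <- ifelse(score >= 28, "healthy", "MCI")
  attr(group, "cd") <- score <= 23
  group
}

#' Build a label table from subject MMSE scores
#'
#' @param subject_id Subject identifiers.
#' @param mmse Integer MMSE scores (0–30).
#' @return Data frame with columns `subject_id`, `mmse`, `group`, `cd`.
#' @export
labels_from_mmse <- function(subject_id, mmse) {
  grp <- classify_mmse(mmse)
  data.frame(subject_id = as.character(subject_id), mmse = as.integer(mmse),
             group = as.character(grp), cd = attr(grp, "cd"),
             stringsAsFactors = FALSE)
}

#' Validate an utterance-level feature table
#'
#' Checks the long-format contract: key columns present, states limited to
#' calculation/reading, every subject has at least one row in each state,
#' and all feature values finite.  Non-finite values fail fast rather than
#' being dropped.
#'
#' @param table Data frame with columns `subject_id`, `state`,
#'   `utterance_index` and numeric feature columns.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending subjects or columns.
#' @export
validate_utterance_table <- function(table) {
  need <- c("subject_id", "state", "utterance_index")
  missing_cols <- setdiff(need, colnames(table))
  if (length(missing_cols))
    stopf("utterance table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  bad_state <- setdiff(unique(table$state), c("calculation", "reading"))
  if (length(bad_state))
    stopf("unknown state value(s): %s", paste(bad_state, collapse = ", "))
  fc <- feature_cols(table)
  if (length(fc) == 0) stopf("utterance table has no feature columns")
  for (cl in fc) {
    v <- table[[cl]]
    if (!is.numeric(v)) stopf("feature column '%s' is not numeric", cl)
    if (any(!is.finite(v)))
      stopf("feature column '%s' contains non-finite values", cl)
  }
  tab <- table(table$subject_id,
               factor(table$state, levels = c("calculation", "reading")))
  have_both <- rownames(tab)[tab[, "calculation"] > 0 & tab[, "reading"] > 0]
  missing_state <- setdiff(unique(table$subject_id), have_both)
  if (length(missing_state))
    stopf("subject(s) missing a recording state: %s",
          paste(sort(missing_state), collapse = ", "))
  invisible(table)
}

#' Average utterance features within subject and state
#'
#' Each calculation voice sample is split into utterance intervals and the
#' reading sample is repeated; features are computed per utterance and then
#' averaged per (subject, state) with equal weight.  Any utterance count of
#' one or more is handled.
#'
#' @param table A validated utterance table (see
#'   [validate_utterance_table()], which is applied first).
#' @return Data frame of class `subject_state_means`: one row per
#'   (subject, state) with `n_utterances` and the averaged feature columns.
#' @export
average_by_state <- function(table) {
  validate_utterance_table(table)
  fc <- feature_cols(table)
  key <- interaction(table$subject_id, table$state, drop = TRUE, sep = "\r")
  means <- rowsum(as.matrix(table[fc]), key) / as.vector(table(key))
  parts <- do.call(rbind, strsplit(rownames(means), "\r", fixed = TRUE))
  out <- data.frame(subject_id = parts[, 1], state = parts[, 2],
                    n_utterances = as.vector(table(key)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means, row.names = FALSE))
  out <- out[order(out$subject_id, out$state), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("subject_state_means", "data.frame")
  out
}

#' Per-subject calculation-minus-reading feature differences
#'
#' The reading of the number sequence is the prosodic baseline; the feature
#' difference is the change from that baseline while the subject performs
#' the mental calculation.  This subject-by-feature matrix is the core
#' object of the analysis.
#'
#' @param means Output of [average_by_state()].
#' @param subject_order Optional character vector fixing the row order
#'   (e.g. a label table's `subject_id`); defaults to sorted subjects.
#' @return Numeric matrix (subjects x features) with `rownames` set to
#'   subject ids.
#' @export
compute_difference <- function(means, subject_order = NULL) {
  stopifnot(is.data.frame(means), all(c("subject_id", "state") %in% colnames(means)))
  fc <- feature_cols(setdiff_df(means))
  calc <- means[means$state == "calculation", , drop = FALSE]
  read <- means[means$state == "reading", , drop = FALSE]
  subjects <- if (is.null(subject_order)) sort(unique(means$subject_id))
              else as.character(subject_order)
  missing <- setdiff(subjects, intersect(calc$subject_id, read$subject_id))
  if (length(missing))
    stopf("subject(s) lack both states: %s", paste(missing, collapse = ", "))
  ci <- match(subjects, calc$subject_id)
  ri <- match(subjects, read$subject_id)
  d <- as.matrix(calc[ci, fc, drop = FALSE]) -
       as.matrix(read[ri, fc, drop = FALSE])
  rownames(d) <- subjects
  d
}

# drop the n_utterances bookkeeping column before feature detection
setdiff_df <- function(means) means[, setdiff(colnames(means), "n_utterances"),
                                    drop = FALSE]

#' Read / write utterance and label tables
#'
#' Delimited-text formats: utterances as CSV with header
#' `subject_id,state,utterance_index,f0001,...`; labels as CSV with header
#' `subject_id,mmse,group[,cd]`.  If `group` is absent it is derived from
#' `mmse` via [classify_mmse()].
#'
#' @param path File path.
#' @return `read_utterance_table`: a validated utterance data frame.
#'   `read_label_table`: a label data frame with `subject_id`, `mmse`,
#'   `group`, `cd`.
#' @export
read_utterance_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_utterance_table(tab)
  tab
}

#' @rdname read_utterance_table
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "mmse") %in% colnames(tab)))
    stopf("label table needs columns subject_id, mmse")
  if (is.null(tab$group)) {
    grp <- classify_mmse(tab$mmse)
    tab$group <- as.character(grp)
    tab$cd <- attr(grp, "cd")
  } else if (is.null(tab$cd)) {
    tab$cd <- tab$mmse <= 23
  }
  bad <- setdiff(unique(tab$group), c("healthy", "MCI"))
  if (length(bad)) stopf("unknown group value(s): %s", paste(bad, collapse = ", "))
  tab
}

#' Adapt a wide acoustic-extractor export to the utterance table layout
#'
#' Acoustic-feature extractors typically emit one row per audio segment with
#' named numeric functional columns.  This maps such a table onto the
#' long-format contract used here by renaming the key columns and recoding
#' the state labels.
#'
#' @param df The wide per-segment data frame.
#' @param subject_col,state_col,index_col Names of the columns holding the
#'   subject id, recording state and segment index.
#' @param state_map Named character vector mapping the source state labels
#'   to `"calculation"` and `"reading"`,
#'   e.g. `c(task = "calculation", base = "reading")`.
#' @return A validated utterance table.
#' @export
as_utterance_table <- function(df, subject_col = "subject_id",
                               state_col = "state",
                               index_col = "utterance_index",
                               state_map = NULL) {
  for (col in c(subject_col, state_col, index_col))
    if (!col %in% colnames(df)) stopf("column '%s' not found", col)
  out <- df
  names(out)[match(c(subject_col, state_col, index_col), names(out))] <-
    c("subject_id", "state", "utterance_index")
  if (!is.null(state_map)) {
    mapped <- state_map[as.character(out$state)]
    if (any(is.na(mapped)))
      stopf("state_map does not cover value(s): %s",
            paste(unique(out$state[is.na(mapped)]), collapse = ", "))
    out$state <- unname(mapped)
  }
  out$subject_id <- as.character(out$subject_id)
  validate_utterance_table(out)
  out
}
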