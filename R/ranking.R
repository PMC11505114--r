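# Score-threshold filtering of externally scored peptides.
#
# Bioactivity-likelihood scores (e.g. PeptideRanker probabilities in
# [0, 1]) are consumed as data, never computed here.

#' Load scored peptides from TSV
#'
#' Expects columns \code{sequence} and \code{score}; an optional
#' \code{activities} column carries semicolon-separated activity labels.
#' Scores must parse as numbers in [0, 1]; offending rows are reported by
#' number. Rows repeating a sequence are merged into one peptide with the
#' union of activities and flagged in the \code{merged} column (with a
#' warning), never silently dropped.
#'
#' @param path TSV file.
#' @return data frame with columns \code{sequence}, \code{score} (numeric),
#'   \code{activities} (";"-separated) and \code{merged} (logical).
#' @examples
#' sc <- load_scores(system.file("extdata", "table4_scores.tsv",
#'                               package = "zeinpep"))
#' sc[sc$sequence == "FCF", "score"]  # 0.9978
#' @export
load_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- .read_tsv(path)
  need <- c("sequence", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("score table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!("activities" %in% names(df))) df$activities <- character(nrow(df))
  if (nrow(df) == 0L) {
    return(data.frame(sequence = character(0), score = numeric(0),
                      activities = character(0), merged = logical(0),
                      stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad) > 0L) {
    stop(sprintf("invalid score(s) outside [0, 1] at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (s in unique(df$sequence)) {
    .check_alphabet(s, what = sprintf("peptide '%s'", s))
  }
  out <- list()
  for (s in unique(df$sequence)) {
    i <- which(df$sequence == s)
    acts <- unique(unlist(strsplit(df$activities[i], ";", fixed = TRUE)))
    acts <- acts[nzchar(acts)]
    if (length(i) > 1L && length(unique(score[i])) > 1L) {
      warning(sprintf(
        "peptide '%s' listed with different scores (%s); keeping the first",
        s, paste(unique(score[i]), collapse = ", ")), call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      sequence = s, score = score[i[1]],
      activities = paste(acts, collapse = ";"),
      merged = length(i) > 1L, stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, out)
  n_merged <- sum(merged$merged)
  if (n_merged > 0L) {
    warning(sprintf(
      "%d peptide(s) listed more than once; activities merged: %s",
      n_merged, paste(merged$sequence[merged$merged], collapse = ", ")),
      call. = FALSE)
  }
  rownames(merged) <- NULL
  merged
}

#' Filter scored peptides by threshold
#'
#' Keeps peptides with score strictly greater than the threshold, ordered
#' by descending score then sequence. Idempotent; raising the threshold
#' never adds peptides.
#'
#' @param peptides data frame from \code{\link{load_scores}}.
#' @param threshold inclusion threshold in [0, 1]; the study convention is
#'   0.8 (strict \code{>}).
#' @return the filtered, re-ordered data frame.
#' @export
filter_by_score <- function(peptides, threshold = 0.8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  keep <- peptides[peptides$score > threshold, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$sequence, method = "radix"), ,
               drop = FALSE]
  rownames(keep) <- NULL
  keep
}
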