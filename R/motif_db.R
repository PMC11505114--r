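# Bioactive-motif database: short peptides annotated with activity labels.

#' Controlled vocabulary of bioactivity labels
#'
#' The activity labels recognised by the motif database: the legend
#' abbreviations and long names of the screened bioactivities (ACE
#' inhibition, DPP-IV/DPP-III inhibition, antioxidative, ...) plus the
#' handful of activities that occur only in individual protein tables.
#'
#' @return data frame with columns \code{abbrev} and \code{label}.
#' @export
activity_vocabulary <- function() {
  .read_tsv(.zp_extdata("activity_vocabulary.tsv"))
}

# max motif length accepted by the database
.MOTIF_MAX <- 25L

.validate_motif_df <- function(df, source_name = "motif table") {
  need <- c("motif", "activity", "source")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s lacks column(s): %s", source_name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  vocab <- activity_vocabulary()$label
  bad_act <- setdiff(unique(df$activity), vocab)
  if (length(bad_act) > 0L) {
    stop(sprintf(
      "unknown activity label(s): %s\nrecognised labels are: %s",
      paste(sQuote(bad_act), collapse = ", "),
      paste(vocab, collapse = "; ")), call. = FALSE)
  }
  for (m in unique(df$motif)) {
    if (nchar(m) < 1L || nchar(m) > .MOTIF_MAX) {
      stop(sprintf("motif '%s' has length %d, outside 1..%d",
                   m, nchar(m), .MOTIF_MAX), call. = FALSE)
    }
    .check_alphabet(m, what = sprintf("motif '%s'", m))
  }
  dup <- duplicated(df[, c("motif", "activity")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (motif, activity) row(s)",
                    sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$activity, df$motif, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a motif database
#'
#' @param motifs data frame with columns \code{motif}, \code{activity},
#'   \code{source}. Motifs must be 1-25 residues over the canonical
#'   alphabet; activities must belong to \code{\link{activity_vocabulary}};
#'   duplicate (motif, activity) rows are collapsed with a warning. The same
#'   motif may carry several activities.
#' @return an object of class \code{motif_db}.
#' @export
motif_db <- function(motifs) {
  motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)
  if (nrow(motifs) > 0L) motifs <- .validate_motif_df(motifs)
  structure(list(entries = motifs), class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  cat(sprintf("<motif_db> %d motif-activity pair(s), %d activit(ies)\n",
              nrow(x$entries), length(unique(x$entries$activity))))
  invisible(x)
}

#' Load a motif database from TSV
#'
#' Expects the dialect \code{motif<TAB>activity<TAB>source} (UTF-8, header,
#' no quoting), as produced by \code{\link{save_motifs}} or by a
#' BIOPEP-style export. Larger user-supplied databases are accepted as long
#' as their activity labels are in the vocabulary.
#'
#' @param path TSV file.
#' @return a \code{\link{motif_db}}.
#' @examples
#' db <- load_motifs(system.file("extdata", "biopep_subset_tables23.tsv",
#'                               package = "zeinpep"))
#' @export
load_motifs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  motif_db(.read_tsv(path))
}

#' Save a motif database to TSV
#'
#' @param db a \code{\link{motif_db}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_motifs <- function(db, path) {
  stopifnot(inherits(db, "motif_db"))
  .write_tsv(db$entries, path)
  invisible(path)
}

#' The packaged motif database distilled from the printed reference tables
#'
#' The union, over the six printed alpha-zein table blocks, of every
#' (fragment, activity) pair listed in any mode column (profile,
#' gastrointestinal digest, subtilisin digest). Tokens containing
#' non-canonical letters (e.g. the OCR artefact "OS") are excluded with a
#' message rather than guessed. This is a strict subset of the BIOPEP-UWM
#' database; a full user-supplied export can be loaded with
#' \code{\link{load_motifs}} instead.
#'
#' @return a \code{\link{motif_db}}.
#' @examples
#' db <- build_fixture()
#' subset(db$entries, motif == "IR" & activity == "CaMPDE inhibitor")
#' @export
build_fixture <- function() {
  gold <- golden_tables()
  rows <- list()
  dropped <- character(0)
  aa_ok <- function(m) all(strsplit(m, "")[[1]] %in% .AA20)
  for (i in seq_len(nrow(gold))) {
    for (frag in .split_fragments(gold$fragments[i])) {
      if (!aa_ok(frag)) {
        dropped <- c(dropped, frag)
        next
      }
      key <- paste(frag, gold$activity[i], sep = "\r")
      if (is.null(rows[[key]])) {
        rows[[key]] <- data.frame(motif = frag,
                                  activity = gold$activity[i],
                                  source = gold$source[i],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  if (length(dropped) > 0L) {
    message("excluded non-canonical token(s): ",
            paste(unique(dropped), collapse = ", "))
  }
  motif_db(do.call(rbind, unname(rows)))
}

#' Motifs annotated with a given activity
#'
#' @param db a \code{\link{motif_db}}.
#' @param activity a vocabulary label.
#' @return character vector of motifs (sorted).
#' @export
motifs_for <- function(db, activity) {
  stopifnot(inherits(db, "motif_db"))
  .csort(db$entries$motif[db$entries$activity == activity])
}
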