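# Motif-occurrence search and the occurrence-frequency statistic A.
#
# A = a / N rounded half-up to 4 decimals, where N is the parent protein's
# residue count and a is, in profile mode, the total number of (possibly
# overlapping) positional occurrences of the activity's motifs in the
# intact sequence, and, in digest mode, the number of released peptide
# instances (with multiplicity) exactly equal to one of the activity's
# motifs.

#' Find all occurrences of a motif in a sequence
#'
#' Exact substring matching; overlapping matches are all reported
#' (\code{find_occurrences("AAA", "AA")} gives positions 0 and 1).
#'
#' @param sequence peptide string.
#' @param motif non-empty peptide string.
#' @return integer vector of 0-based start positions (empty when the motif
#'   is longer than the sequence).
#' @examples
#' find_occurrences("AAA", "AA")  # 0 1
#' @export
find_occurrences <- function(sequence, motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  if (nchar(motif) > nchar(sequence)) return(integer(0))
  # lookahead so that overlapping occurrences are all found; motifs are
  # validated plain residue strings, so no regex metacharacters occur
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# occurrence count of each motif (named integer vector)
.count_motifs <- function(sequence, motifs) {
  vapply(motifs, function(m) length(find_occurrences(sequence, m)),
         integer(1))
}

.profile_df <- function(accession, mode, enzymes, activity, fragments,
                        a, N) {
  data.frame(
    accession = accession, mode = mode, enzymes = enzymes,
    activity = activity, fragments = fragments,
    a = as.integer(a), N = as.integer(N),
    A = round_half_up(a / N, 4L),
    stringsAsFactors = FALSE)
}

#' Profile of potential biological activity (intact sequence)
#'
#' Matches every database motif as a substring of the intact protein and
#' reports, per activity with at least one match, the distinct matched
#' fragments, the total occurrence count a (overlapping occurrences, summed
#' over all motifs of the activity) and the frequency A = a/N rounded
#' half-up to 4 decimals.
#'
#' @param record a \code{\link{protein_record}}.
#' @param db a \code{\link{motif_db}}.
#' @return data frame with columns \code{accession}, \code{mode}
#'   ("profile"), \code{enzymes} (""), \code{activity}, \code{fragments}
#'   (comma-separated, sorted), \code{a}, \code{N}, \code{A}; one row per
#'   activity with a > 0, ordered by activity.
#' @examples
#' recs <- read_fasta(system.file("extdata", "alpha_zein_printed.fasta",
#'                                package = "zeinpep"))
#' db <- load_motifs(system.file("extdata", "biopep_subset_tables23.tsv",
#'                               package = "zeinpep"))
#' p <- profile_potential(recs$P06674, db)
#' p[p$activity == "CaMPDE inhibitor", c("fragments", "A")]  # IR, 0.0043
#' @export
profile_potential <- function(record, db) {
  stopifnot(inherits(record, "protein_record"), inherits(db, "motif_db"))
  out <- list()
  for (act in .csort(unique(db$entries$activity))) {
    motifs <- motifs_for(db, act)
    cnt <- .count_motifs(record$sequence, motifs)
    a <- sum(cnt)
    if (a == 0L) next
    frs <- names(cnt)[cnt > 0L]
    out[[length(out) + 1L]] <- .profile_df(
      record$accession, "profile", "", act,
      paste(.csort(frs), collapse = ", "), a, record$length)
  }
  if (length(out) == 0L) {
    return(.profile_df(character(0), character(0), character(0),
                       character(0), character(0), integer(0), integer(0)))
  }
  do.call(rbind, out)
}

#' Profile of released bioactive peptides (digest mode)
#'
#' Counts released peptide instances whose full sequence equals a motif of
#' the activity (whole-peptide equality, with multiplicity: a peptide
#' released twice counts twice; a longer released peptide merely containing
#' a motif does not count). N is the parent protein's residue count, not
#' the number of released peptides.
#'
#' @param x a \code{digest_result} from \code{\link{digest}}.
#' @param db a \code{\link{motif_db}}.
#' @return data frame as in \code{\link{profile_potential}}, with
#'   \code{mode = "digest"} and \code{enzymes} the joined enzyme names.
#' @export
profile_digest <- function(x, db) {
  stopifnot(inherits(x, "digest_result"), inherits(db, "motif_db"))
  tab <- table(x$peptides)
  enz <- paste(x$enzymes, collapse = "+")
  out <- list()
  for (act in .csort(unique(db$entries$activity))) {
    motifs <- motifs_for(db, act)
    rel <- motifs[motifs %in% names(tab)]
    if (length(rel) == 0L) next
    a <- sum(tab[rel])
    out[[length(out) + 1L]] <- .profile_df(
      x$accession, "digest", enz, act,
      paste(.csort(rel), collapse = ", "), a, x$parent_length)
  }
  if (length(out) == 0L) {
    return(.profile_df(character(0), character(0), character(0),
                       character(0), character(0), integer(0), integer(0)))
  }
  do.call(rbind, out)
}

#' Render activity profiles as a TSV report
#'
#' Deterministic ordering (accession, activity, then mode); A printed with
#' exactly 4 decimals.
#'
#' @param profiles data frame from \code{\link{profile_potential}} /
#'   \code{\link{profile_digest}} (rows may be concatenated).
#' @param path optional output file; when omitted the TSV lines are
#'   returned.
#' @return character vector of TSV lines (header first), invisibly when
#'   \code{path} is given.
#' @export
render_report <- function(profiles, path = NULL) {
  header <- paste(c("accession", "mode", "activity", "fragments",
                    "a", "N", "A"), collapse = "\t")
  if (nrow(profiles) > 0L) {
    ord <- order(profiles$accession, profiles$activity, profiles$mode,
                 method = "radix")
    profiles <- profiles[ord, , drop = FALSE]
    lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%.4f",
                     profiles$accession, profiles$mode, profiles$activity,
                     profiles$fragments, profiles$a, profiles$N,
                     profiles$A)
  } else {
    lines <- character(0)
  }
  out <- c(header, lines)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
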