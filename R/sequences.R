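# Protein records, FASTA I/O, pairwise identity and identity grouping.

#' Create a protein record
#'
#' A validated container for one amino-acid sequence. The derived length
#' \code{N = nchar(sequence)} is the denominator of the occurrence-frequency
#' statistic. When a catalogued length is supplied and disagrees with the
#' sequence, the record carries a \code{length_mismatch} flag; it is never
#' silently reconciled.
#'
#' @param accession short identifier (e.g. a UniProtKB accession).
#' @param sequence amino-acid sequence; uppercased, whitespace stripped,
#'   must contain only the 20 canonical one-letter codes.
#' @param name free-text protein name.
#' @param length_declared optional catalogued residue count.
#' @return an object of class \code{protein_record} with fields
#'   \code{accession}, \code{name}, \code{sequence}, \code{length}
#'   (derived), \code{length_declared} and \code{length_mismatch}.
#' @examples
#' protein_record("X1", "ACDE")
#' @export
protein_record <- function(accession, sequence, name = "",
                           length_declared = NULL) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  .check_alphabet(sequence, what = sprintf("record '%s'", accession))
  n <- nchar(sequence)
  mismatch <- !is.null(length_declared) &&
    as.integer(length_declared) != n
  structure(
    list(accession = accession, name = name, sequence = sequence,
         length = n,
         length_declared = if (is.null(length_declared)) NA_integer_
                           else as.integer(length_declared),
         length_mismatch = mismatch),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s%s  N=%d%s\n", x$accession,
              if (nzchar(x$name)) paste0(" (", x$name, ")") else "",
              x$length,
              if (isTRUE(x$length_mismatch))
                sprintf("  [catalogued %d -- MISMATCH]", x$length_declared)
              else ""))
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' Headers are parsed as \code{">accession name..."}. Sequence lines may be
#' wrapped and may contain stray whitespace (as in printed sequence blocks);
#' all whitespace is stripped and letters uppercased before validation.
#'
#' @param path FASTA file.
#' @param catalog optional data frame with columns \code{accession} and
#'   \code{length}; matching records get their declared length (and the
#'   mismatch flag when it disagrees with the sequence).
#' @return a named list of \code{\link{protein_record}} objects.
#' @examples
#' fa <- system.file("extdata", "alpha_zein_printed.fasta", package = "zeinpep")
#' recs <- read_fasta(fa)
#' recs$P06674$length  # 230
#' @export
read_fasta <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  recs <- vector("list", length(set))
  accs <- character(length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    acc <- sub("\\s.*$", "", header)
    nm <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    decl <- NULL
    if (!is.null(catalog)) {
      hit <- match(acc, catalog$accession)
      if (!is.na(hit)) decl <- catalog$length[hit]
    }
    recs[[i]] <- protein_record(acc, as.character(set[[i]]), name = nm,
                                length_declared = decl)
    accs[i] <- acc
  }
  names(recs) <- accs
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records list of \code{\link{protein_record}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  hdrs <- vapply(records, function(r)
    if (nzchar(r$name)) paste(r$accession, r$name) else r$accession,
    character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Load the packaged alpha-zein accession catalog
#'
#' Accessions, protein names, catalogued lengths and molecular-mass class
#' (19-kDa / 22-kDa) of the 17 alpha-zein entries used in the study design.
#'
#' @return data frame with columns \code{accession}, \code{name},
#'   \code{length} (integer) and \code{class}.
#' @export
zein_catalog <- function() {
  df <- .read_tsv(.zp_extdata("alpha_zein_catalog.tsv"))
  df$length <- as.integer(df$length)
  df
}

# Identity substitution matrix over the canonical alphabet:
# match +1, mismatch 0.
.identity_matrix <- function() {
  m <- diag(1, length(.AA20))
  dimnames(m) <- list(.AA20, .AA20)
  m
}

#' Percent identity from a global pairwise alignment
#'
#' Aligns two records globally (Needleman-Wunsch; identity scoring with
#' match +1 / mismatch 0 and affine gaps, opening 10 and extension 0.5) and
#' returns \code{100 * identical positions / alignment length}, the
#' alignment length excluding end gaps. Symmetric to floating tolerance and
#' exactly 100 for identical sequences.
#'
#' @param a,b \code{\link{protein_record}} objects (or plain sequences).
#' @return identity percentage in [0, 100].
#' @examples
#' percent_identity(protein_record("x", "AAAA"), protein_record("y", "AAAT"))
#' @export
percent_identity <- function(a, b) {
  sa <- if (inherits(a, "protein_record")) a$sequence else
    protein_record("a", a)$sequence
  sb <- if (inherits(b, "protein_record")) b$sequence else
    protein_record("b", b)$sequence
  if (identical(sa, sb)) return(100)
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global",
    substitutionMatrix = .identity_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pin <- which(p != "-")
  sin <- which(s != "-")
  # window covered by both sequences: drop end gaps from the denominator
  from <- max(min(pin), min(sin))
  to <- min(max(pin), max(sin))
  idx <- from:to
  ident <- sum(p[idx] == s[idx] & p[idx] != "-")
  100 * ident / length(idx)
}

#' Group sequences by an identity threshold
#'
#' Builds the pairwise identity graph (edge when identity >= threshold) and
#' partitions accessions into its connected components (single-linkage
#' closure): two sequences land in the same group iff they are connected by
#' a chain of pairs each meeting the threshold. The representative of each
#' group is its longest sequence, ties broken by lexicographically smallest
#' accession.
#'
#' @param records a named list of \code{\link{protein_record}} objects, or a
#'   data frame with columns \code{accession} and \code{length} (when
#'   \code{pairs} supplies precomputed identities).
#' @param threshold identity percentage; pairs at or above it are merged.
#' @param pairs optional data frame with columns \code{accession_a},
#'   \code{accession_b}, \code{identity}; computed with
#'   \code{\link{percent_identity}} when omitted.
#' @return an object of class \code{identity_grouping}: list with
#'   \code{threshold}, \code{pairs}, \code{groups} (list of accession
#'   vectors) and \code{representatives}.
#' @examples
#' pairs <- read.delim(system.file("extdata", "table1_identity.tsv",
#'                                 package = "zeinpep"))
#' grp <- group_by_identity(zein_catalog(), threshold = 90, pairs = pairs)
#' length(grp$groups)
#' @export
group_by_identity <- function(records, threshold = 90, pairs = NULL) {
  if (is.data.frame(records)) {
    accs <- records$accession
    lens <- as.integer(records$length)
  } else {
    accs <- vapply(records, function(r) r$accession, character(1))
    lens <- vapply(records, function(r) r$length, integer(1))
  }
  if (length(accs) < 1L) stop("need at least one record", call. = FALSE)
  names(lens) <- accs
  if (is.null(pairs)) {
    if (is.data.frame(records)) {
      stop("pairs must be supplied when records is a catalog data frame",
           call. = FALSE)
    }
    idx <- if (length(accs) > 1L) utils::combn(length(accs), 2L) else
      matrix(integer(0), nrow = 2)
    pairs <- data.frame(
      accession_a = accs[idx[1, ]],
      accession_b = accs[idx[2, ]],
      identity = apply(idx, 2L, function(ij)
        percent_identity(records[[ij[1]]], records[[ij[2]]])))
  }
  pairs$identity <- as.numeric(pairs$identity)
  # a pairs table may cover a superset of the supplied records
  pairs <- pairs[pairs$accession_a %in% accs & pairs$accession_b %in% accs,
                 , drop = FALSE]
  keep <- pairs[pairs$identity >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("accession_a", "accession_b")],
    directed = FALSE,
    vertices = data.frame(name = accs))
  memb <- igraph::components(g)$membership
  groups <- split(names(memb), memb)
  names(groups) <- NULL
  reps <- vapply(groups, function(g_accs) {
    l <- lens[g_accs]
    cand <- .csort(g_accs[l == max(l)])
    cand[1]
  }, character(1))
  # deterministic ordering: by representative accession
  ord <- order(reps, method = "radix")
  structure(
    list(threshold = threshold, pairs = pairs,
         groups = groups[ord], representatives = reps[ord]),
    class = "identity_grouping")
}

#' @export
print.identity_grouping <- function(x, ...) {
  cat(sprintf("<identity_grouping> threshold=%g%%, %d group(s)\n",
              x$threshold, length(x$groups)))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  [%s] %s\n", x$representatives[i],
                paste(.csort(x$groups[[i]]), collapse = ", ")))
  }
  invisible(x)
}
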