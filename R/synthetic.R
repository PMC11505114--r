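# Seeded synthetic sequences with known ground truth, so that every
# pipeline stage (occurrence counting, digestion, frequency recovery) can
# be tested end-to-end without external data.

#' Generate a random background sequence
#'
#' Draws residues i.i.d. from a given composition. Reproducible for a fixed
#' seed; the global RNG state is left untouched.
#'
#' @param length sequence length (>= 1).
#' @param composition named numeric vector of residue probabilities over
#'   (a subset of) the canonical alphabet, summing to 1 within 1e-9;
#'   uniform over the 20 residues when omitted.
#' @param seed integer seed.
#' @return peptide string.
#' @examples
#' synth_background(10, c(A = 0.5, G = 0.5), seed = 1)
#' @export
synth_background <- function(length, composition = NULL, seed) {
  if (!is.numeric(length) || length < 1L) {
    stop("length must be >= 1", call. = FALSE)
  }
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), .AA20)
  }
  if (is.null(names(composition)) ||
      !all(names(composition) %in% .AA20)) {
    stop("composition must be named by canonical residues", call. = FALSE)
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("composition probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  keep <- composition[composition > 0]
  .with_seed(seed, {
    paste(sample(names(keep), size = as.integer(length), replace = TRUE,
                 prob = as.numeric(keep)), collapse = "")
  })
}

.new_truth <- function(sequence, planted = list(), cut_sites = NULL,
                       seed = NA_integer_) {
  structure(list(sequence = sequence, planted = planted,
                 cut_sites = cut_sites, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> N=%d, %d planted motif(s)%s, seed=%s\n",
              nchar(x$sequence), length(x$planted),
              if (is.null(x$cut_sites)) "" else
                sprintf(", %d cut site(s)", length(x$cut_sites)),
              x$seed))
  invisible(x)
}

#' Plant motifs into a background sequence
#'
#' Overwrites non-overlapping windows of the background with the requested
#' motif copies at random positions, then re-scans the finished sequence so
#' that the recorded truth reflects actual occurrence positions -- including
#' accidental background matches and matches destroyed or created at window
#' boundaries. With motifs over an alphabet disjoint from the background's,
#' truth counts equal the planted counts exactly.
#'
#' @param background peptide string.
#' @param plan named integer vector or list, motif -> copy count.
#' @param seed integer seed.
#' @return a \code{synthetic_truth} with \code{planted} mapping each motif
#'   to its 0-based occurrence positions in the final sequence.
#' @examples
#' bg <- synth_background(60, c(A = 0.5, G = 0.5), seed = 1)
#' tr <- plant_motifs(bg, c(PL = 3), seed = 2)
#' length(tr$planted$PL) >= 3
#' @export
plant_motifs <- function(background, plan, seed) {
  .check_alphabet(background, what = "background")
  plan <- unlist(plan)
  if (is.null(names(plan)) || any(!nzchar(names(plan)))) {
    stop("plan must map motifs to counts", call. = FALSE)
  }
  for (m in names(plan)) .check_alphabet(m, what = sprintf("motif '%s'", m))
  n <- nchar(background)
  total_len <- sum(nchar(names(plan)) * plan)
  if (total_len > n) {
    stop(sprintf("sequence of length %d too short for plan (%d residues)",
                 n, total_len), call. = FALSE)
  }
  chars <- strsplit(background, "")[[1]]
  occupied <- logical(n)
  .with_seed(seed, {
    # place longer motifs first so short ones can fill the gaps
    for (m in names(plan)[order(-nchar(names(plan)))]) {
      w <- nchar(m)
      for (k in seq_len(plan[[m]])) {
        starts <- which(vapply(seq_len(n - w + 1L), function(s)
          !any(occupied[s:(s + w - 1L)]), logical(1)))
        if (length(starts) == 0L) {
          stop(sprintf(
            "could not place copy %d of motif '%s': no free window", k, m),
            call. = FALSE)
        }
        s <- if (length(starts) == 1L) starts else sample(starts, 1L)
        chars[s:(s + w - 1L)] <- strsplit(m, "")[[1]]
        occupied[s:(s + w - 1L)] <- TRUE
      }
    }
  })
  seq_out <- paste(chars, collapse = "")
  planted <- lapply(stats::setNames(names(plan), names(plan)),
                    function(m) find_occurrences(seq_out, m))
  .new_truth(seq_out, planted = planted, seed = as.integer(seed))
}

#' Build a sequence with known cleavage sites
#'
#' Concatenates fragments designed to be exactly the peptides a rule set
#' releases: every fragment but the last must end in a P1 residue of the
#' rules, no fragment may contain an internal cut site, and no junction may
#' fall in a blocked P1' context. Violations are reported with the
#' offending fragment index.
#'
#' @param fragments character vector of peptide strings.
#' @param rules a \code{\link{cleavage_rule}} or list of them.
#' @return a \code{synthetic_truth} whose \code{cut_sites} are the junction
#'   bonds; \code{digest(sequence, rules)} returns exactly
#'   \code{fragments}.
#' @examples
#' tr <- sequence_with_cuts(c("AAK", "GGR", "CC"),
#'                          default_enzymes("trypsin"))
#' tr$cut_sites  # 2 5
#' @export
sequence_with_cuts <- function(fragments, rules) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  if (length(fragments) < 1L) stop("need at least one fragment",
                                   call. = FALSE)
  for (i in seq_along(fragments)) {
    .check_alphabet(fragments[i], what = sprintf("fragment %d", i))
  }
  seq_full <- paste(fragments, collapse = "")
  lens <- nchar(fragments)
  junctions <- if (length(fragments) > 1L)
    cumsum(lens)[-length(lens)] - 1L else integer(0)
  sites <- cleavage_sites(seq_full, rules)
  # every junction must be cut; every cut must be a junction
  not_cut <- setdiff(junctions, sites)
  if (length(not_cut) > 0L) {
    i <- findInterval(not_cut[1], c(0L, cumsum(lens)))
    stop(sprintf(
      "fragment %d does not end at a cleavable bond (its terminal residue is not a P1 residue, or the junction is in a blocked context)",
      i), call. = FALSE)
  }
  internal <- setdiff(sites, junctions)
  if (length(internal) > 0L) {
    i <- findInterval(internal[1], c(0L, cumsum(lens)))
    stop(sprintf("fragment %d contains an internal cut site (bond %d)",
                 i, internal[1]), call. = FALSE)
  }
  .new_truth(seq_full, cut_sites = junctions)
}

#' Write a synthetic truth to FASTA plus a JSON sidecar
#'
#' @param truth a \code{synthetic_truth}.
#' @param fasta_path output FASTA file.
#' @param json_path output JSON sidecar (\code{sequence}, \code{planted},
#'   \code{cut_sites}, \code{seed}; positions and bond indices 0-based).
#' @param accession header used in the FASTA.
#' @return invisibly, a list with both paths.
#' @export
write_truth <- function(truth, fasta_path, json_path,
                        accession = "synthetic") {
  stopifnot(inherits(truth, "synthetic_truth"))
  write_fasta(list(protein_record(accession, truth$sequence)), fasta_path)
  jsonlite::write_json(
    list(sequence = truth$sequence,
         planted = truth$planted,
         cut_sites = if (is.null(truth$cut_sites)) integer(0) else
           truth$cut_sites,
         seed = truth$seed),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fasta = fasta_path, json = json_path))
}
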