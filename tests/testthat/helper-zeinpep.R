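# Shared test helpers and fixtures built in code.

zp_file <- function(...) {
  system.file("extdata", ..., package = "zeinpep", mustWork = TRUE)
}

zein_records <- function() read_fasta(zp_file("alpha_zein_printed.fasta"))

zein_db <- function() load_motifs(zp_file("biopep_subset_tables23.tsv"))

# Independent occurrence-count oracle: scan every start position.
brute_count <- function(sequence, motif) {
  n <- nchar(sequence); w <- nchar(motif)
  if (w > n) return(0L)
  sum(vapply(seq_len(n - w + 1L),
             function(i) substr(sequence, i, i + w - 1L) == motif,
             logical(1)))
}

brute_positions <- function(sequence, motif) {
  n <- nchar(sequence); w <- nchar(motif)
  if (w > n) return(integer(0))
  which(vapply(seq_len(n - w + 1L),
               function(i) substr(sequence, i, i + w - 1L) == motif,
               logical(1))) - 1L
}

random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a minimal in-memory motif database
tiny_db <- function(motifs, activity = "ACE inhibitor") {
  motif_db(data.frame(motif = motifs, activity = activity,
                      source = "test", stringsAsFactors = FALSE))
}
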