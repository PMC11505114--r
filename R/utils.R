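# Shared internal helpers.

# The 20 canonical one-letter amino-acid codes.
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Round half away from zero
#'
#' Decimal rounding with ties going up, matching the convention of the
#' reference frequency tables (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} places.
#' @examples
#' round_half_up(0.02175, 4)  # 0.0218
#' @export
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  # tiny eps guards against values like 0.5 stored as 0.4999...9
  floor(x * p + 0.5 + 1e-9) / p
}

# Validate a peptide string over the canonical alphabet.
# Returns invisibly; stops with a message naming `what` and the bad letters.
.check_alphabet <- function(sequence, what = "sequence") {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(chars) == 0L) {
    stop(sprintf("%s is empty", what), call. = FALSE)
  }
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-canonical residue(s): %s",
                 what, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(sequence)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# any pre-existing global state afterwards (no global side effects).
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Path to a packaged data file.
.zp_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "zeinpep")
  if (identical(path, "")) {
    stop(sprintf("packaged file not found: %s",
                 file.path(...)), call. = FALSE)
  }
  path
}

# Read a TSV written in the package's dialect (UTF-8, header, no quoting).
.read_tsv <- function(path) {
  # na.strings empty: "NA" is a real dipeptide (Asn-Ala), never missing
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), fileEncoding = "UTF-8")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

# Byte-order character sort, independent of the session locale.
.csort <- function(x) sort(x, method = "radix")

# Split a "A, B, C" fragment list into a character vector.
.split_fragments <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  strsplit(x, ",[ ]*")[[1]]
}
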