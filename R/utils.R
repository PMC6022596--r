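#' @importFrom stats phyper runif rnorm p.adjust setNames
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom data.table data.table rbindlist setkey :=
#' @importFrom methods as
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")
# 20 standard amino acids
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
PAV_STATUSES <- c("LOST", "CONSERVED", "INDETERMINATE", "NO_DATA")

#' Round half away from zero
#'
#' Reported percentages use conventional round-half-up at a fixed number of
#' decimals rather than R's default round-half-to-even.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_fraction <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > max)
    stop_param("'%s' must be a single number in [0, %s], got %s",
               name, format(max), format(x))
  invisible(x)
}

random_seq <- function(n, alphabet = DNA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# i.i.d. per-site substitution to a uniformly chosen *different* symbol;
# no indels, so coordinates and divergence stay exactly interpretable.
mutate_seq <- function(seq, divergence, alphabet = DNA_ALPHABET) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    sz <- length(alphabet)
    cur <- match(chars[hit], alphabet)
    step <- sample.int(sz - 1L, length(hit), replace = TRUE)
    chars[hit] <- alphabet[(cur - 1L + step) %% sz + 1L]
    seq <- paste(chars, collapse = "")
  }
  seq
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Collapse a character matrix (rows = positions) into one string per column.
collapse_columns <- function(m) {
  do.call(paste0, asplit(m, 1))
}
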