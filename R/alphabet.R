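# Symbol tables and encoding.
#
# All index machinery works on positive integer symbol codes under a fixed
# total order:
#   "0" (unit delimiter) < "#" (non-unique-extension sentinel) < "$"
#   (end marker) < query separators < A < C < G < T.
# Any fixed order works (the algorithms only use equality and occurrence
# semantics); this one is frozen for reproducibility.

#' Symbol table for DNA texts with sentinels
#'
#' Returns the ordered symbol alphabet used by the indexes: the unit
#' delimiter \code{"0"}, the extension sentinel \code{"#"}, the end marker
#' \code{"$"}, then \code{n_sep} unique query separators, then the DNA
#' letters A, C, G, T. Symbol rank in this vector is the integer code used
#' internally.
#'
#' @param n_sep number of unique query separators to reserve (for batched
#'   queries).
#' @return character vector of symbols in sorting order.
#' @export
dna_symtab <- function(n_sep = 0L) {
  seps <- if (n_sep > 0L) paste0("%", seq_len(n_sep)) else character()
  c("0", "#", "$", seps, "A", "C", "G", "T")
}

sym_code <- function(symtab, s) {
  i <- match(s, symtab)
  if (anyNA(i)) stop("unknown symbol(s): ", paste(s[is.na(i)], collapse = ", "))
  i
}

# Fixed codes for the three universal sentinels.
ZERO_CODE <- 1L
HASH_CODE <- 2L
DOLLAR_CODE <- 3L

# First plain-alphabet (letter) code for a given symbol table.
letter_start <- function(symtab) length(symtab) - 3L

# Encode a character string (or vector of single-symbol characters) to codes.
encode_chars <- function(x, symtab, what = "sequence") {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(x, symtab)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))
    stop(sprintf("%s contains symbols outside the alphabet at position(s) %s: %s",
                 what, paste(head(bad, 10L), collapse = ", "),
                 paste(unique(x[head(bad, 10L)]), collapse = ", ")))
  }
  codes
}

decode_codes <- function(codes, symtab) paste(symtab[codes], collapse = "")
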