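# Bidirectional text index: suffix arrays of the text and its reverse,
# Burrows-Wheeler transforms, cumulative occurrence tables, and synchronized
# forward/reverse interval search.

#' Build a bidirectional index over a text
#'
#' Appends the end marker \code{"$"}, builds the suffix arrays of the text
#' and of its reverse, the two Burrows-Wheeler transforms (with the circular
#' convention: the symbol preceding position 1 is the end marker), and the
#' occurrence tables supporting left/right extension of a matched substring
#' with synchronized suffix-array intervals.
#'
#' @param text a character string, a vector of single symbols, or an integer
#'   code vector (then \code{symtab} must be given). Must be nonempty and
#'   must not contain the end marker.
#' @param symtab symbol table (see [dna_symtab()]); defaults to the DNA table.
#' @return an object of class \code{bd_index}.
#' @examples
#' idx <- build_index("AGAAAG")
#' idx$sa_fwd
#' @export
build_index <- function(text, symtab = NULL) {
  if (is.character(text)) {
    if (is.null(symtab)) symtab <- dna_symtab()
    codes <- encode_chars(text, symtab, "text")
  } else {
    if (is.null(symtab)) stop("symtab is required for integer-coded texts")
    codes <- as.integer(text)
    if (any(codes < 1L | codes > length(symtab)))
      stop("integer codes outside the symbol table")
  }
  if (length(codes) == 0L) stop("text must be nonempty")
  if (any(codes == DOLLAR_CODE)) stop("text must not contain the end marker '$'")

  sigma <- length(symtab)
  txt_f <- c(codes, DOLLAR_CODE)
  txt_r <- c(rev(codes), DOLLAR_CODE)
  n <- length(txt_f)

  sa_f <- cpp_suffix_array(txt_f)
  sa_r <- cpp_suffix_array(txt_r)
  bwt_f <- txt_f[ifelse(sa_f == 1L, n, sa_f - 1L)]
  bwt_r <- txt_r[ifelse(sa_r == 1L, n, sa_r - 1L)]

  occ <- function(bwt) {
    m <- matrix(0L, nrow = n + 1L, ncol = sigma)
    for (c in seq_len(sigma)) m[-1L, c] <- cumsum(bwt == c)
    m
  }
  tab <- tabulate(txt_f, nbins = sigma)
  C <- as.integer(cumsum(c(0L, tab))[seq_len(sigma)])

  structure(list(
    symtab = symtab, codes = codes, n = n,
    sa_fwd = sa_f, sa_rev = sa_r,
    bwt_fwd = bwt_f, bwt_rev = bwt_r,
    core = list(of = occ(bwt_f), orv = occ(bwt_r), C = C, n = n)
  ), class = "bd_index")
}

#' @export
print.bd_index <- function(x, ...) {
  cat(sprintf("<bd_index> text length %d (incl. end marker), alphabet {%s}\n",
              x$n, paste(x$symtab, collapse = ", ")))
  invisible(x)
}

#' Synchronized interval pair
#'
#' A pair of 1-based inclusive intervals into the forward and reverse suffix
#' arrays representing the same substring, plus the matched length. Both
#' intervals always have the same width, which equals the substring's
#' occurrence count.
#'
#' @param fwd,rev length-2 integer vectors (start, end).
#' @param len matched string length.
#' @export
iv_pair <- function(fwd, rev, len = 0L) {
  structure(list(fwd = as.integer(fwd), rev = as.integer(rev),
                 len = as.integer(len)), class = "iv_pair")
}

#' Interval of the empty string (the whole suffix array)
#' @param idx a \code{bd_index}.
#' @export
root_interval <- function(idx) iv_pair(c(1L, idx$n), c(1L, idx$n), 0L)

#' Number of occurrences represented by an interval pair
#' @param iv an \code{iv_pair} (or NULL for an empty result).
#' @export
interval_width <- function(iv) if (is.null(iv)) 0L else iv$fwd[2L] - iv$fwd[1L] + 1L

#' Extend a matched substring by one symbol
#'
#' \code{extend_left(idx, c, iv)} returns the synchronized interval pair of
#' \code{cQ'} where \code{iv} represents \code{Q'}, or \code{NULL} when
#' \code{cQ'} does not occur. \code{extend_right} is symmetric.
#'
#' @param idx a \code{bd_index}.
#' @param c a single symbol (character) or its integer code.
#' @param iv an \code{iv_pair}.
#' @return an \code{iv_pair} or \code{NULL}.
#' @export
extend_left <- function(idx, c, iv) {
  code <- if (is.character(c)) sym_code(idx$symtab, c) else as.integer(c)
  occ <- idx$core$of
  i <- iv$fwd[1L]; j <- iv$fwd[2L]
  before <- occ[i, code]
  cnt <- occ[j + 1L, code] - before
  if (cnt == 0L) return(NULL)
  smaller <- if (code > 1L)
    sum(occ[j + 1L, seq_len(code - 1L)] - occ[i, seq_len(code - 1L)]) else 0L
  fi <- idx$core$C[code] + before + 1L
  ri <- iv$rev[1L] + smaller
  iv_pair(c(fi, fi + cnt - 1L), c(ri, ri + cnt - 1L), iv$len + 1L)
}

#' @rdname extend_left
#' @export
extend_right <- function(idx, c, iv) {
  code <- if (is.character(c)) sym_code(idx$symtab, c) else as.integer(c)
  occ <- idx$core$orv
  i <- iv$rev[1L]; j <- iv$rev[2L]
  before <- occ[i, code]
  cnt <- occ[j + 1L, code] - before
  if (cnt == 0L) return(NULL)
  smaller <- if (code > 1L)
    sum(occ[j + 1L, seq_len(code - 1L)] - occ[i, seq_len(code - 1L)]) else 0L
  ri <- idx$core$C[code] + before + 1L
  fi <- iv$fwd[1L] + smaller
  iv_pair(c(fi, fi + cnt - 1L), c(ri, ri + cnt - 1L), iv$len + 1L)
}

#' Symbols adjacent to all occurrences of a matched substring
#'
#' \code{enumerate_left} returns the distinct symbols preceding the
#' occurrences of the represented substring (the end marker stands for an
#' occurrence at position 1, by the circular convention);
#' \code{enumerate_right} is symmetric. \code{is_left_maximal} /
#' \code{is_right_maximal} are true iff the corresponding set has at least
#' two elements.
#'
#' @inheritParams extend_left
#' @return a character vector of symbols, or a logical.
#' @export
enumerate_left <- function(idx, iv) {
  occ <- idx$core$of
  cnt <- occ[iv$fwd[2L] + 1L, ] - occ[iv$fwd[1L], ]
  idx$symtab[cnt > 0L]
}

#' @rdname enumerate_left
#' @export
enumerate_right <- function(idx, iv) {
  occ <- idx$core$orv
  cnt <- occ[iv$rev[2L] + 1L, ] - occ[iv$rev[1L], ]
  idx$symtab[cnt > 0L]
}

#' @rdname enumerate_left
#' @export
is_left_maximal <- function(idx, iv) length(enumerate_left(idx, iv)) >= 2L

#' @rdname enumerate_left
#' @export
is_right_maximal <- function(idx, iv) length(enumerate_right(idx, iv)) >= 2L

#' Locate the forward suffix-array positions of an interval
#' @inheritParams extend_left
#' @return integer vector of 1-based text positions (suffix starts).
#' @export
locate_fwd <- function(idx, iv) idx$sa_fwd[seq.int(iv$fwd[1L], iv$fwd[2L])]

#' Count maximal equal-letter runs in a Burrows-Wheeler transform
#'
#' @param idx a \code{bd_index}.
#' @param which \code{"fwd"} or \code{"rev"}.
#' @return integer run count.
#' @export
count_bwt_runs <- function(idx, which = c("fwd", "rev")) {
  which <- match.arg(which)
  b <- if (which == "fwd") idx$bwt_fwd else idx$bwt_rev
  1L + sum(b[-1L] != b[-length(b)])
}

# Count occurrences of a pattern by repeated left extension (backward search).
count_occurrences <- function(idx, pattern) {
  codes <- if (is.character(pattern)) encode_chars(pattern, idx$symtab, "pattern")
           else as.integer(pattern)
  iv <- root_interval(idx)
  for (c in rev(codes)) {
    iv <- extend_left(idx, c, iv)
    if (is.null(iv)) return(0L)
  }
  interval_width(iv)
}

# ---------------------------------------------------------------------------
# Rank/select bitvector.

#' Bitvector with rank and select
#'
#' Precomputes prefix ranks and the positions of set bits so that
#' \code{bv_rank(b, i)} (number of 1s in \code{bits[1..i]}) and
#' \code{bv_select(b, r)} (position of the r-th 1) are O(1) lookups.
#'
#' @param bits logical or 0/1 integer vector.
#' @export
rs_bitvector <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  structure(list(bits = bits, rk = cumsum(bits), sel = which(bits == 1L)),
            class = "rs_bitvector")
}

#' @rdname rs_bitvector
#' @param b an \code{rs_bitvector}.
#' @param i position (vectorized); \code{i = 0} gives rank 0.
#' @export
bv_rank <- function(b, i) ifelse(i < 1L, 0L, b$rk[pmin(i, length(b$bits))])

#' @rdname rs_bitvector
#' @param r rank (vectorized).
#' @export
bv_select <- function(b, r) b$sel[r]

# ---------------------------------------------------------------------------
# Range-minimum threshold reporting.

#' Threshold reporter over an integer array
#'
#' Wraps an integer array (with \code{Inf}/\code{NA} allowed, treated as
#' plus infinity) for recursive range-minimum threshold reporting: all
#' positions \code{k} in a range with \code{values[k] <= delta} are listed
#' using at most \code{2 * output + 1} range-minimum probes.
#'
#' @param values numeric/integer vector; \code{Inf} and \code{NA} mean
#'   "undefined" (never reported).
#' @export
rmq_reporter <- function(values) {
  v <- suppressWarnings(as.integer(ifelse(is.finite(values), values, NA)))
  structure(list(values = v), class = "rmq_reporter")
}

#' @rdname rmq_reporter
#' @param rep an \code{rmq_reporter}.
#' @param lo,hi 1-based inclusive range (an empty range returns nothing).
#' @export
rmq_min <- function(rep, lo, hi) {
  v <- rep$values[lo:hi]
  lo - 1L + which.min(ifelse(is.na(v), .Machine$integer.max, v))
}

#' @rdname rmq_reporter
#' @param delta threshold.
#' @return \code{rmq_report_leq}: integer vector of indices (any order) with
#'   attribute \code{"rmq_calls"}, the number of range-minimum probes used.
#' @export
rmq_report_leq <- function(rep, lo, hi, delta) {
  stopifnot(lo >= 1L, hi <= length(rep$values))
  if (lo > hi) return(structure(integer(), rmq_calls = 0L))
  r <- cpp_rmq_report(rep$values, as.integer(lo), as.integer(hi), as.numeric(delta))
  structure(r$indices, rmq_calls = r$calls)
}
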