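# String-vs-string kappa-MEM enumeration: exploration of MEM candidates over
# the two bidirectional indexes, cross-product reporting, batched queries and
# the asymmetric (query-centric) MEM variant.

#' Concatenate queries with unique separators
#'
#' Builds the concatenation Q1 %1 Q2 %2 ... with one unique separator symbol
#' between consecutive queries. No MEM can span a unique separator, so MEMs
#' against the concatenation equal the union of per-query MEMs; use
#' [batch_project()] to map global coordinates back to (query, position).
#'
#' @param queries character vector of one or more DNA sequences.
#' @return an object of class \code{query_batch}.
#' @examples
#' b <- batch_queries(c("GA", "AT"))
#' batch_project(b, c(1, 2, 4, 5))
#' @export
batch_queries <- function(queries) {
  if (length(queries) < 1L) stop("need at least one query")
  if (any(nchar(queries) == 0L)) stop("queries must be nonempty")
  n_sep <- max(length(queries) - 1L, 0L)
  symtab <- dna_symtab(n_sep)
  parts <- lapply(queries, encode_chars, symtab = symtab, what = "query")
  codes <- integer(0)
  starts <- integer(length(queries))
  pos <- 1L
  for (k in seq_along(parts)) {
    starts[k] <- pos
    codes <- c(codes, parts[[k]])
    pos <- pos + length(parts[[k]])
    if (k < length(parts)) {
      codes <- c(codes, DOLLAR_CODE + k)  # k-th separator code
      pos <- pos + 1L
    }
  }
  ids <- if (!is.null(names(queries))) names(queries) else as.character(seq_along(queries))
  structure(list(codes = codes, symtab = symtab, starts = starts,
                 lengths = nchar(queries), ids = ids),
            class = "query_batch")
}

#' @rdname batch_queries
#' @param batch a \code{query_batch}.
#' @param pos global 1-based positions into the concatenation (vectorized).
#' @return data frame with columns \code{query} (index) and \code{pos}
#'   (local 1-based coordinate); separator positions are an error.
#' @export
batch_project <- function(batch, pos) {
  qid <- findInterval(pos, batch$starts)
  local <- pos - batch$starts[qid] + 1L
  if (any(qid < 1L) || any(local > batch$lengths[qid]))
    stop("position falls on a separator or outside the concatenation")
  data.frame(query = qid, pos = local)
}

# Shared driver: run the exploration between a query index and a text index
# and return raw suffix-array coordinates plus statistics.
explore_mems <- function(idxQ, idxT, kappa, exclude_t = integer(0),
                         d_array = NULL, collect_candidates = FALSE) {
  cpp_explore(idxQ$core, idxT$core, as.integer(kappa),
              letter_start(idxQ$symtab), as.integer(exclude_t),
              DOLLAR_CODE, d_array, collect_candidates)
}

check_kappa <- function(kappa) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < 1L)
    stop("kappa must be a single integer >= 1")
  as.integer(kappa)
}

#' Find maximal exact matches between two strings
#'
#' Enumerates all MEMs of length at least \code{kappa} between query Q and
#' text T: triples (x1, x2, len) with Q[x1..x1+len-1] = T[x2..x2+len-1] that
#' can be extended neither left nor right (reaching either string's boundary
#' counts as maximal). Candidate MEM strings are explored over the two
#' bidirectional indexes as the left extensions of right-maximal common
#' substrings; each candidate that is also left-maximal in the virtual
#' concatenation T#Q is expanded by a cross product of its one-symbol
#' extension classes (a, b) in Q and (c, d) in T with a != c, b != d.
#'
#' @param Q query sequence(s); a character vector of length > 1 is batched
#'   with unique separators and reported per query.
#' @param T text sequence.
#' @param kappa minimum MEM length (>= 1).
#' @param compact if TRUE, report one occurrence pair per extension class
#'   (a, b, c, d) instead of all occurrence pairs.
#' @param collect_candidates if TRUE, also return the explored MEM-candidate
#'   strings (useful for inspecting the pruning behaviour).
#' @return a list of class \code{mem_search}: \code{mems} (data frame with
#'   query_id, qstart, qend, tstart, tend, length), \code{stats}
#'   (recursion_nodes, candidates) and optionally \code{candidates}.
#' @examples
#' find_string_mems("GAAT", "AGAAAG", kappa = 2)$mems
#' @export
find_string_mems <- function(Q, T, kappa, compact = FALSE,
                             collect_candidates = FALSE) {
  kappa <- check_kappa(kappa)
  batched <- length(Q) > 1L
  if (batched) {
    batch <- batch_queries(Q)
    symtab <- batch$symtab
    idxQ <- build_index(batch$codes, symtab)
  } else {
    symtab <- dna_symtab()
    idxQ <- build_index(Q, symtab)
  }
  idxT <- build_index(encode_chars(T, symtab, "text"), symtab)

  r <- explore_mems(idxQ, idxT, kappa, collect_candidates = collect_candidates)
  x1 <- (idxQ$sa_fwd[r$kq] %% idxQ$n) + 1L
  x2 <- (idxT$sa_fwd[r$kt] %% idxT$n) + 1L
  len <- r$len
  keep <- if (compact) !duplicated(r$cls) else rep(TRUE, length(x1))
  x1 <- x1[keep]; x2 <- x2[keep]; len <- len[keep]

  if (batched) {
    pr <- if (length(x1) > 0L) batch_project(batch, x1)
          else data.frame(query = integer(), pos = integer())
    mems <- data.frame(query_id = pr$query, qstart = pr$pos,
                       qend = pr$pos + len - 1L,
                       tstart = x2, tend = x2 + len - 1L, length = len)
  } else {
    mems <- data.frame(query_id = rep(1L, length(x1)), qstart = x1,
                       qend = x1 + len - 1L,
                       tstart = x2, tend = x2 + len - 1L, length = len)
  }
  mems <- unique(mems)
  mems <- mems[order(mems$query_id, mems$qstart, mems$tstart, mems$length), ,
               drop = FALSE]
  rownames(mems) <- NULL

  out <- list(mems = mems,
              stats = list(recursion_nodes = r$nodes, candidates = r$candidates))
  if (collect_candidates) {
    starts <- idxQ$sa_fwd[r$cand_k]
    out$candidates <- vapply(seq_along(starts), function(k) {
      decode_codes(idxQ$codes[seq.int(starts[k], starts[k] + r$cand_len[k] - 1L)],
                   symtab)
    }, character(1))
  }
  class(out) <- "mem_search"
  out
}

#' @export
print.mem_search <- function(x, ...) {
  cat(sprintf("<mem_search> %d MEM(s), %d recursion node(s), %d candidate(s)\n",
              nrow(x$mems), x$stats$recursion_nodes, x$stats$candidates))
  invisible(x)
}

#' Find asymmetric (query-centric) MEMs
#'
#' The asymmetric variant reports the maximal substrings of the query that
#' occur in the text: Q[x..y] occurs in T but neither Q[x-1..y] nor
#' Q[x..y+1] does (string boundaries count as non-extendable). One record is
#' emitted per query interval regardless of the occurrence count in T.
#'
#' @inheritParams find_string_mems
#' @return data frame with columns query_id, qstart, qend, length.
#' @export
find_asymmetric_mems <- function(Q, T, kappa) {
  kappa <- check_kappa(kappa)
  symtab <- dna_symtab()
  idxT <- build_index(T, symtab)
  one <- function(q) {
    qc <- encode_chars(q, symtab, "query")
    m <- length(qc)
    search_iv <- function(x, y) {
      iv <- root_interval(idxT)
      if (y < x) return(iv)
      for (p in x:y) {
        iv <- extend_right(idxT, qc[p], iv)
        if (is.null(iv)) return(NULL)
      }
      iv
    }
    xs <- integer(); ys <- integer()
    x <- 1L; y <- 1L
    iv <- root_interval(idxT)  # interval of Q[x..y-1]
    while (y <= m) {
      ext <- extend_right(idxT, qc[y], iv)
      if (!is.null(ext)) { iv <- ext; y <- y + 1L; next }
      if (y - 1L >= x) { xs <- c(xs, x); ys <- c(ys, y - 1L) }
      repeat {
        x <- x + 1L
        if (x > y) { iv <- root_interval(idxT); y <- y + 1L; break }
        iv2 <- search_iv(x, y)
        if (!is.null(iv2)) { iv <- iv2; y <- y + 1L; break }
      }
    }
    if (m >= x) { xs <- c(xs, x); ys <- c(ys, m) }
    data.frame(qstart = xs, qend = ys, length = ys - xs + 1L)
  }
  res <- lapply(seq_along(Q), function(k) {
    d <- one(Q[[k]])
    if (nrow(d) > 0L) d$query_id <- k else d$query_id <- integer(0)
    d
  })
  out <- do.call(rbind, res)
  out <- out[out$length >= kappa, c("query_id", "qstart", "qend", "length"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}
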