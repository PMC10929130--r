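# kappa-MEMs between a query and a labeled graph: node MEMs over the
# delimiter-separated node-label concatenation, and MEMs spanning exactly L
# nodes over the sentinel-wrapped length-L path concatenation with a
# D-array/RMQ filter keeping only matches that reach the last node.
# (The D threshold is |Q'|, not |Q'|+1: D counts from the character before
# the match, and a match whose last symbol stops at the first-node boundary
# spans fewer than L nodes; the definitional oracle fixes this convention.)

#' Node-label concatenation text
#'
#' Builds the text \code{0 l(v1) 0 l(v2) 0 ...} (one unit per node, the
#' \code{"0"} symbol acting as a delimiter so no match spans two labels),
#' its bidirectional index, and the delimiter bitvector used to map text
#' coordinates back to (node, offset).
#'
#' @param g a \code{labeled_graph}.
#' @param n_sep number of query-separator symbols the companion query index
#'   will use (the two indexes must share one symbol table).
#' @return object of class \code{path_concat}.
#' @export
build_t_nodes <- function(g, n_sep = 0L) {
  symtab <- dna_symtab(n_sep)
  parts <- lapply(g$ids, function(v) c(encode_chars(g$labels[[v]], symtab), ZERO_CODE))
  codes <- c(ZERO_CODE, unlist(parts))
  idx <- build_index(codes, symtab)
  structure(list(idx = idx, bv = rs_bitvector(codes == ZERO_CODE),
                 kind = "nodes", nodes = g$ids, symtab = symtab),
            class = "path_concat")
}

#' Length-L path concatenation text with extension sentinels and D array
#'
#' Builds the text \code{0 (left(P) l(P) right(P) 0)*} over all length-L
#' paths P, where \code{left(P)} is the unique last character of the first
#' node's in-neighbors when that set is a singleton and \code{"#"}
#' otherwise (and symmetrically \code{right(P)}); these sentinels suppress
#' matches that could only be extended along a longer path. For L > 1 the D
#' array is attached: per suffix-array position k, the distance from the
#' suffix start (one position before the match, at its left-extension
#' character, when the position one later falls inside the first node of its
#' path) to the start of the path's last node, and infinity otherwise. The
#' MEM finder keeps only text-side occurrences with D[k] <= |Q'|: since D
#' counts from the extension character, that is exactly the matches whose
#' own span reaches the last node.
#'
#' @inheritParams build_t_nodes
#' @param L number of nodes each unit spans (>= 1).
#' @param max_paths cap forwarded to [enumerate_paths()].
#' @return object of class \code{path_concat} (with \code{d} for L > 1), or
#'   \code{NULL} when the graph has no length-L path.
#' @export
build_t_l <- function(g, L, n_sep = 0L, max_paths = 100000L) {
  symtab <- dna_symtab(n_sep)
  paths <- enumerate_paths(g, L, max_paths)
  if (length(paths) == 0L) return(NULL)

  sent <- function(set) {
    if (length(set) == 1L) sym_code(symtab, set) else HASH_CODE
  }
  parts <- lapply(paths, function(p) {
    c(sent(node_lext(g, p[1L])),
      encode_chars(paste(g$labels[p], collapse = ""), symtab),
      sent(node_rext(g, p[length(p)])),
      ZERO_CODE)
  })
  codes <- c(ZERO_CODE, unlist(parts))
  idx <- build_index(codes, symtab)
  bv <- rs_bitvector(codes == ZERO_CODE)

  firstlen <- vapply(paths, function(p) node_len(g, p[1L]), integer(1))
  lastlen <- vapply(paths, function(p) node_len(g, p[length(p)]), integer(1))
  pathlen <- vapply(paths, function(p) sum(nchar(g$labels[p])), integer(1))

  d <- NULL
  if (L > 1L) {
    n <- idx$n                       # text length incl. end marker
    s <- idx$sa_fwd
    p <- s + 1L
    r <- bv_rank(bv, pmin(p, n - 1L))
    valid <- p <= (n - 1L) & r >= 1L & r <= length(paths)
    i <- rep(NA_integer_, n)
    i[valid] <- p[valid] - bv$sel[r[valid]] - 1L
    inside <- valid & !is.na(i) & i >= 1L & i <= firstlen[r]
    d <- rep(NA_integer_, n)
    d[inside] <- pathlen[r[inside]] - lastlen[r[inside]] - i[inside] + 2L
  }

  structure(list(idx = idx, bv = bv, kind = "paths", paths = paths,
                 firstlen = firstlen, lastlen = lastlen, pathlen = pathlen,
                 d = d, L = as.integer(L), symtab = symtab),
            class = "path_concat")
}

#' @export
print.path_concat <- function(x, ...) {
  cat(sprintf("<path_concat> kind=%s, %d unit(s), text length %d\n",
              x$kind,
              if (x$kind == "nodes") length(x$nodes) else length(x$paths),
              x$idx$n))
  invisible(x)
}

# Build the query index; returns list(idx, batch or NULL, n_sep).
query_index <- function(Q) {
  if (length(Q) > 1L) {
    batch <- batch_queries(Q)
    list(idx = build_index(batch$codes, batch$symtab), batch = batch,
         n_sep = length(Q) - 1L)
  } else {
    list(idx = build_index(Q, dna_symtab()), batch = NULL, n_sep = 0L)
  }
}

graph_mem_df <- function(query_id, qstart, len, i, paths, j) {
  nnodes <- lengths(paths)
  data.frame(query_id = query_id, qstart = qstart, qend = qstart + len - 1L,
             i = i,
             path = vapply(paths, paste, character(1), collapse = ">"),
             j = j, length = len, nodes = nnodes,
             mem_class = ifelse(nnodes == 1L, "node",
                         ifelse(nnodes == 2L, "edge", paste0("path-", nnodes))))
}

finish_mem_df <- function(df) {
  df <- unique(df)
  df <- df[order(df$query_id, df$qstart, df$path, df$i, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

project_query_side <- function(qi, saQ, nQ, kq) {
  xg <- (saQ[kq] %% nQ) + 1L
  if (is.null(qi$batch)) {
    list(query_id = rep(1L, length(xg)), qstart = xg)
  } else {
    pr <- if (length(xg) > 0L) batch_project(qi$batch, xg)
          else data.frame(query = integer(), pos = integer())
    list(query_id = pr$query, qstart = pr$pos)
  }
}

#' Find node MEMs between a query and a graph
#'
#' A node MEM is a plain string MEM between Q and a single node label
#' (maximality in the string sense, ignoring graph context). Computed by
#' running the MEM exploration between the query index and the
#' node-concatenation index; the delimiter bitvector maps text coordinates
#' back to (node, offset).
#'
#' @param g a \code{labeled_graph}.
#' @param Q query sequence(s); a vector is batched with unique separators.
#' @param kappa minimum MEM length.
#' @param tn optional prebuilt [build_t_nodes()] result (must match the
#'   batching of Q).
#' @param qi optional prebuilt query index (internal reuse).
#' @return graph-MEM data frame (columns query_id, qstart, qend, i, path, j,
#'   length, nodes, mem_class), with attribute \code{"stats"}.
#' @export
find_node_mems <- function(g, Q, kappa, tn = NULL, qi = NULL) {
  kappa <- check_kappa(kappa)
  if (is.null(qi)) qi <- query_index(Q)
  if (is.null(tn) || length(tn$symtab) != length(qi$idx$symtab))
    tn <- build_t_nodes(g, qi$n_sep)
  r <- explore_mems(qi$idx, tn$idx, kappa)
  x2 <- (tn$idx$sa_fwd[r$kt] %% tn$idx$n) + 1L
  rk <- bv_rank(tn$bv, x2)
  i <- x2 - bv_select(tn$bv, rk)
  qs <- project_query_side(qi, qi$idx$sa_fwd, qi$idx$n, r$kq)
  df <- graph_mem_df(qs$query_id, qs$qstart, r$len, i,
                     as.list(tn$nodes[rk]), i + r$len - 1L)
  df <- finish_mem_df(df)
  attr(df, "stats") <- list(recursion_nodes = r$nodes, candidates = r$candidates)
  df
}

#' Find kappa-MEMs spanning exactly L graph nodes
#'
#' Runs the MEM exploration between the query index and the length-L path
#' concatenation. The cross product skips extensions with the \code{"0"}
#' delimiter on the text side (such occurrences start or end on a sentinel
#' character and are artifacts of the unique-extension wrapping), and for
#' L > 1 filters text-side suffix-array positions through recursive
#' range-minimum reporting on the D array with threshold |Q'|, so that
#' only matches spanning all L nodes survive (see [build_t_l()] for the
#' off-by-one convention).
#'
#' @inheritParams find_node_mems
#' @param L exact number of nodes spanned.
#' @param tl optional prebuilt [build_t_l()] result.
#' @param max_paths cap forwarded to [enumerate_paths()].
#' @return graph-MEM data frame with attribute \code{"stats"}.
#' @export
find_l_mems <- function(g, Q, kappa, L, tl = NULL, qi = NULL,
                        max_paths = 100000L) {
  kappa <- check_kappa(kappa)
  stopifnot(L >= 1L)
  if (is.null(qi)) qi <- query_index(Q)
  if (is.null(tl) || length(tl$symtab) != length(qi$idx$symtab))
    tl <- build_t_l(g, L, qi$n_sep, max_paths)
  if (is.null(tl)) {
    df <- finish_mem_df(graph_mem_df(integer(), integer(), integer(),
                                     integer(), list(), integer()))
    attr(df, "stats") <- list(recursion_nodes = 0, candidates = 0)
    return(df)
  }
  r <- explore_mems(qi$idx, tl$idx, kappa, exclude_t = ZERO_CODE,
                    d_array = tl$d)
  x2 <- tl$idx$sa_fwd[r$kt] + 1L
  rk <- bv_rank(tl$bv, x2)
  pos <- x2 - bv_select(tl$bv, rk) - 1L   # offset within the path label
  i <- pos
  j <- pos + r$len - 1L - (tl$pathlen[rk] - tl$lastlen[rk])
  stopifnot(all(i >= 1L), all(i <= tl$firstlen[rk]),
            all(j >= 1L), all(j <= tl$lastlen[rk]))
  qs <- project_query_side(qi, qi$idx$sa_fwd, qi$idx$n, r$kq)
  df <- graph_mem_df(qs$query_id, qs$qstart, r$len, i, tl$paths[rk], j)
  df <- finish_mem_df(df)
  attr(df, "stats") <- list(recursion_nodes = r$nodes, candidates = r$candidates)
  df
}

#' Keep only MEMs whose spelled string occurs in a set of rows
#'
#' Occurrence filtering against the original sequence collection (e.g. the
#' rows of the MSA a founder graph was built from): a graph MEM is kept
#' exactly when its spelled graph string occurs in the concatenation of the
#' rows (gaps stripped, rows joined by separators so no match crosses a row
#' boundary).
#'
#' @param mems graph-MEM data frame.
#' @param g the \code{labeled_graph} the MEMs refer to.
#' @param rows_text character vector of rows (gaps \code{"-"} are stripped).
#' @return the filtered data frame.
#' @export
filter_by_text <- function(mems, g, rows_text) {
  if (nrow(mems) == 0L) return(mems)
  hay <- paste(gsub("-", "", rows_text, fixed = TRUE), collapse = "|")
  spelled <- vapply(seq_len(nrow(mems)), function(k) {
    spell_substring(g, mems$i[k],
                    strsplit(mems$path[k], ">", fixed = TRUE)[[1]], mems$j[k])
  }, character(1))
  keep <- vapply(spelled, function(s) grepl(s, hay, fixed = TRUE), logical(1),
                 USE.NAMES = FALSE)
  out <- mems[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
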