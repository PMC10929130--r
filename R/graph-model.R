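# Labeled graphs: data model, GFA subset I/O, substring extensions,
# path enumeration, and the definitional brute-force MEM oracle.

#' Construct a labeled graph
#'
#' @param labels named character vector: node id -> nonempty A/C/G/T label.
#' @param edges data frame (or 2-column matrix) of directed edges with
#'   columns \code{from}, \code{to}; may be empty.
#' @return object of class \code{labeled_graph} with precomputed adjacency,
#'   total label length \code{n} and maximum in/out degree \code{d}.
#' @export
labeled_graph <- function(labels, edges = NULL) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("labels must be a named character vector")
  if (anyDuplicated(names(labels))) stop("duplicate node ids")
  if (any(nchar(labels) == 0L)) stop("node labels must be nonempty")
  bad <- grepl("[^ACGT]", labels)
  if (any(bad))
    stop("non-ACGT label(s) at node(s): ",
         paste(head(names(labels)[bad], 5L), collapse = ", "))
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  miss <- setdiff(unique(c(edges$from, edges$to)), names(labels))
  if (length(miss)) stop("edge endpoint(s) not in node set: ",
                         paste(head(miss, 5L), collapse = ", "))
  edges <- unique(edges[, c("from", "to")])
  ids <- sort(names(labels))
  fac <- function(x) factor(x, levels = ids)
  out_adj <- lapply(split(edges$to, fac(edges$from)), sort)
  in_adj <- lapply(split(edges$from, fac(edges$to)), sort)
  structure(list(
    labels = labels[ids], edges = edges, ids = ids,
    out_adj = out_adj, in_adj = in_adj,
    n = sum(nchar(labels)),
    d = max(c(0L, lengths(out_adj), lengths(in_adj)))
  ), class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph> %d node(s), %d edge(s), total label length %d, max degree %d\n",
              length(x$ids), nrow(x$edges), x$n, x$d))
  invisible(x)
}

node_len <- function(g, v) nchar(g$labels[[v]])

# Last/first characters of a node's in-/out-neighbor labels (node-level
# extension sets, duplicates removed).
node_lext <- function(g, v) {
  nb <- g$in_adj[[v]]
  if (length(nb) == 0L) return(character())
  unique(vapply(nb, function(u) substr(g$labels[[u]], node_len(g, u), node_len(g, u)),
                character(1), USE.NAMES = FALSE))
}

node_rext <- function(g, v) {
  nb <- g$out_adj[[v]]
  if (length(nb) == 0L) return(character())
  unique(vapply(nb, function(u) substr(g$labels[[u]], 1L, 1L),
                character(1), USE.NAMES = FALSE))
}

check_substring <- function(g, i, path, j) {
  stopifnot(length(path) >= 1L, all(path %in% g$ids))
  if (length(path) > 1L) {
    for (k in seq_len(length(path) - 1L))
      if (!path[k + 1L] %in% g$out_adj[[path[k]]])
        stop(sprintf("(%s,%s) is not an edge", path[k], path[k + 1L]))
  }
  if (i < 1L || i > node_len(g, path[1L])) stop("offset i out of range")
  if (j < 1L || j > node_len(g, path[length(path)])) stop("offset j out of range")
  if (length(path) == 1L && i > j) stop("i must not exceed j on a single node")
  invisible(TRUE)
}

#' Left and right extension sets of a graph substring
#'
#' For a graph substring (i, P, j), the left extension is the singleton
#' label character before offset i when i > 1, and otherwise the set of last
#' characters of the in-neighbors of the first node; the right extension is
#' symmetric. Either set is empty exactly when the substring starts (ends)
#' at a label boundary of a source (sink) node.
#'
#' @param g a \code{labeled_graph}.
#' @param i 1-based offset into the first node's label.
#' @param path character vector of node ids forming a path.
#' @param j 1-based offset into the last node's label.
#' @return character vector (a set of symbols, possibly empty).
#' @export
lext <- function(g, i, path, j) {
  check_substring(g, i, path, j)
  if (i > 1L) substr(g$labels[[path[1L]]], i - 1L, i - 1L)
  else node_lext(g, path[1L])
}

#' @rdname lext
#' @export
rext <- function(g, i, path, j) {
  check_substring(g, i, path, j)
  v <- path[length(path)]
  if (j < node_len(g, v)) substr(g$labels[[v]], j + 1L, j + 1L)
  else node_rext(g, v)
}

#' Spell the string of a graph substring
#' @inheritParams lext
#' @export
spell_substring <- function(g, i, path, j) {
  full <- paste(g$labels[path], collapse = "")
  last <- node_len(g, path[length(path)])
  substr(full, i, nchar(full) - (last - j))
}

#' Enumerate all length-L paths
#'
#' Lists every path of exactly L nodes (node repeats allowed in cyclic
#' graphs), each exactly once, in lexicographic order of node ids.
#'
#' @param g a \code{labeled_graph}.
#' @param L path length in nodes (>= 1).
#' @param max_paths hard cap on the number of paths; exceeding it is an
#'   error (path explosion guard).
#' @return list of character vectors of node ids.
#' @export
enumerate_paths <- function(g, L, max_paths = 100000L) {
  stopifnot(L >= 1L)
  paths <- lapply(g$ids, function(v) v)
  for (step in seq_len(L - 1L)) {
    nxt <- vector("list", 0L)
    for (p in paths) {
      for (u in g$out_adj[[p[length(p)]]]) nxt[[length(nxt) + 1L]] <- c(p, u)
      if (length(nxt) > max_paths)
        stop(sprintf("more than %d paths of length %d; raise max_paths", max_paths, L))
    }
    paths <- nxt
  }
  paths
}

#' Brute-force graph MEM oracle
#'
#' Enumerates, directly from the definition, every pair ([x..y], (i, P, j))
#' with |P| <= Lmax and y - x + 1 >= kappa such that Q[x..y] equals the
#' spelled string of (i, P, j), the pair is left-maximal or its left graph
#' extension is not a singleton, and right-maximal or its right graph
#' extension is not a singleton. Matching starts are filtered by the left
#' condition, then extended along the graph by depth-first search; at each
#' node boundary the right condition decides reporting. Independent of the
#' index-based finders; intended as a testing oracle and for desk-scale use.
#'
#' @param g a \code{labeled_graph}.
#' @param Q query sequence (single string).
#' @param kappa minimum MEM length.
#' @param Lmax maximum number of nodes a reported match may span.
#' @return data frame with columns query_id, qstart, qend, i, path
#'   (ids joined by \code{">"}), j, length, nodes, mem_class.
#' @export
brute_force_graph_mems <- function(g, Q, kappa, Lmax) {
  kappa <- check_kappa(kappa)
  stopifnot(Lmax >= 1L)
  qc <- strsplit(Q, "", fixed = TRUE)[[1]]
  m <- length(qc)
  ids <- g$ids
  labs <- lapply(g$labels, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  slen <- lengths(labs)

  # within-node maximal match length of Q[x..] vs label[i..]
  M <- lapply(ids, function(v) {
    lc <- labs[[v]]; s <- length(lc)
    eq <- outer(qc, lc, "==")
    Mm <- matrix(0L, m, s)
    for (i in s:1) {
      nxt <- if (i < s) c(Mm[-1L, i + 1L], 0L) else integer(m)
      Mm[, i] <- ifelse(eq[, i], 1L + nxt, 0L)
    }
    Mm
  })
  names(M) <- ids
  lext1 <- lapply(ids, node_lext, g = g); names(lext1) <- ids
  rext1 <- lapply(ids, node_rext, g = g); names(rext1) <- ids
  first_char <- vapply(ids, function(v) labs[[v]][1L], character(1))

  rows <- new.env(parent = emptyenv())
  rows$x <- integer(); rows$y <- integer(); rows$i <- integer()
  rows$p <- character(); rows$j <- integer()
  emit <- function(x, y, i, path, j) {
    rows$x <- c(rows$x, x); rows$y <- c(rows$y, y); rows$i <- c(rows$i, i)
    rows$p <- c(rows$p, paste(path, collapse = ">")); rows$j <- c(rows$j, j)
  }

  # matched to the end of the last node of `path` at query position y
  descend <- function(x, i, path, y) {
    v <- path[length(path)]
    rset <- rext1[[v]]
    rightmax <- (y == m) || length(rset) == 0L || !(qc[y + 1L] %in% rset)
    if ((rightmax || length(rset) >= 2L) && (y - x + 1L) >= kappa)
      emit(x, y, i, path, slen[[v]])
    if (y == m || length(path) >= Lmax) return(invisible())
    for (u in g$out_adj[[v]]) {
      if (first_char[[u]] != qc[y + 1L]) next
      w <- M[[u]][y + 1L, 1L]
      if (w < slen[[u]]) {
        if (w >= 1L && (y + w - x + 1L) >= kappa) emit(x, y + w, i, c(path, u), w)
      } else descend(x, i, c(path, u), y + w)
    }
    invisible()
  }

  for (v in ids) {
    Mm <- M[[v]]; s <- slen[[v]]
    for (i in seq_len(s)) {
      xs <- which(Mm[, i] > 0L)
      if (length(xs) == 0L) next
      ok <- if (i > 1L) {
        lchar <- labs[[v]][i - 1L]
        xs == 1L | qc[pmax(xs - 1L, 1L)] != lchar
      } else {
        lset <- lext1[[v]]
        if (length(lset) == 0L || length(lset) >= 2L) rep(TRUE, length(xs))
        else xs == 1L | qc[pmax(xs - 1L, 1L)] != lset
      }
      xs <- xs[ok]
      if (length(xs) == 0L) next
      w <- Mm[xs, i]
      nb <- (i + w - 1L) < s  # match ends inside the node: right-maximal
      sel <- nb & w >= kappa
      if (any(sel))
        for (k in which(sel)) emit(xs[k], xs[k] + w[k] - 1L, i, v, i + w[k] - 1L)
      for (x in xs[!nb]) descend(x, i, v, x + (s - i + 1L) - 1L)
    }
  }

  nnodes <- lengths(strsplit(rows$p, ">", fixed = TRUE))
  out <- data.frame(query_id = rep(1L, length(rows$x)),
                    qstart = rows$x, qend = rows$y, i = rows$i,
                    path = rows$p, j = rows$j,
                    length = rows$y - rows$x + 1L, nodes = nnodes,
                    mem_class = ifelse(nnodes == 1L, "node",
                                ifelse(nnodes == 2L, "edge",
                                       paste0("path-", nnodes))))
  out <- unique(out)
  out <- out[order(out$qstart, out$path, out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# GFA v1 subset I/O: S-lines with explicit sequences, L-lines with 0M
# overlaps and '+' orientations; optional bl:i:<block> tags on S-lines.

#' Read a labeled graph from GFA (v1 subset)
#'
#' Accepts S-lines with explicit sequences and L-lines with 0M overlap and
#' '+' orientations only. \code{bl:i:<k>} tags on S-lines are collected into
#' a \code{"blocks"} attribute (named integer vector). H and P lines are
#' skipped; other line types are skipped with a warning.
#'
#' @param path GFA file.
#' @return a \code{labeled_graph}, possibly with attribute \code{blocks}.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  labels <- character(); blocks <- integer()
  from <- character(); to <- character()
  for (ln in seq_along(lines)) {
    if (lines[ln] == "") next
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    type <- f[1]
    if (type == "S") {
      if (length(f) < 3L || f[3] == "*" || f[3] == "")
        stop(sprintf("GFA line %d: S-line without an explicit sequence", ln))
      labels[f[2]] <- toupper(f[3])
      tag <- grep("^bl:i:", f, value = TRUE)
      if (length(tag)) blocks[f[2]] <- as.integer(sub("^bl:i:", "", tag[1]))
    } else if (type == "L") {
      if (length(f) < 6L) stop(sprintf("GFA line %d: malformed L-line", ln))
      if (f[3] != "+" || f[5] != "+")
        stop(sprintf("GFA line %d: only '+' orientations are supported", ln))
      if (f[6] != "0M")
        stop(sprintf("GFA line %d: only 0M overlaps are supported (got '%s')", ln, f[6]))
      from <- c(from, f[2]); to <- c(to, f[4])
    } else if (type %in% c("H", "P")) {
      # header / path lines carry no information we use
    } else {
      warning(sprintf("GFA line %d: skipping unknown line type '%s'", ln, type))
    }
  }
  g <- labeled_graph(labels, data.frame(from = from, to = to))
  if (length(blocks)) attr(g, "blocks") <- blocks
  g
}

#' Write a labeled graph to GFA (v1 subset)
#' @param g a \code{labeled_graph}.
#' @param path output file.
#' @param blocks optional named integer vector of block indices, written as
#'   \code{bl:i:} tags.
#' @export
write_gfa <- function(g, path, blocks = NULL) {
  s <- vapply(g$ids, function(v) {
    tag <- if (!is.null(blocks) && v %in% names(blocks))
      sprintf("\tbl:i:%d", blocks[[v]]) else ""
    sprintf("S\t%s\t%s%s", v, g$labels[[v]], tag)
  }, character(1))
  l <- if (nrow(g$edges) > 0L)
    sprintf("L\t%s\t+\t%s\t+\t0M", g$edges$from, g$edges$to) else character()
  writeLines(c("H\tVN:Z:1.0", s, l), path)
  invisible(path)
}
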