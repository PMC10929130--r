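# Independent oracles and small generators shared by the test files. These
# deliberately avoid the package's index machinery: string MEMs by dynamic
# programming on the equality matrix, BWTs by rotation sorting, occurrence
# counts by naive scanning, path counts by adjacency-matrix powers, and
# semi-repeat-free checking by enumerating path strings.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All string MEMs (x1, x2, len >= kappa) by brute force: equality matrix,
# diagonal run lengths, report runs starting at a left-maximal cell.
oracle_string_mems <- function(Q, T, kappa) {
  qc <- strsplit(Q, "", fixed = TRUE)[[1]]
  tc <- strsplit(T, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(tc)
  eq <- outer(qc, tc, "==")
  M <- matrix(0L, m, n)
  for (i in n:1) {
    nxt <- if (i < n) c(M[-1L, i + 1L], 0L) else integer(m)
    M[, i] <- ifelse(eq[, i], 1L + nxt, 0L)
  }
  res <- list()
  for (i in seq_len(n)) {
    xs <- which(M[, i] > 0L)
    lm <- xs == 1L | i == 1L | qc[pmax(xs - 1L, 1L)] != tc[max(i - 1L, 1L)]
    xs <- xs[lm]
    w <- M[xs, i]
    k <- w >= kappa
    if (any(k))
      res[[length(res) + 1L]] <-
        data.frame(qstart = xs[k], tstart = i, length = w[k])
  }
  if (length(res) == 0L)
    data.frame(qstart = integer(), tstart = integer(), length = integer())
  else do.call(rbind, res)
}

str_mem_key <- function(d) paste(d$qstart, d$tstart, d$length)

# BWT by rotation sorting (C collation so "$" < letters).
oracle_bwt <- function(s) {
  t <- paste0(s, "$"); n <- nchar(t)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(t, i, n), substr(t, 1, i - 1)), character(1))
  rots <- sort(rots, method = "radix")
  paste(vapply(rots, function(r) substr(r, n, n), character(1)), collapse = "")
}

count_runs_str <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  1L + sum(ch[-1L] != ch[-length(ch)])
}

# Naive occurrence count of a pattern in a text (overlaps counted).
naive_count <- function(pattern, text) {
  k <- nchar(pattern); n <- nchar(text)
  if (k > n) return(0L)
  sum(vapply(seq_len(n - k + 1L), function(i)
    substr(text, i, i + k - 1L) == pattern, logical(1)))
}

# Asymmetric MEM oracle: all maximal query substrings occurring in T.
oracle_asym_mems <- function(Q, T, kappa) {
  m <- nchar(Q)
  occ <- function(x, y) x >= 1L && y <= m && y >= x &&
    grepl(substr(Q, x, y), T, fixed = TRUE)
  rows <- list()
  for (x in seq_len(m)) for (y in x:m) {
    if (y - x + 1L < kappa) next
    if (!occ(x, y)) next
    if ((x == 1L || !occ(x - 1L, y)) && (y == m || !occ(x, y + 1L)))
      rows[[length(rows) + 1L]] <- data.frame(qstart = x, qend = y)
  }
  if (length(rows) == 0L) data.frame(qstart = integer(), qend = integer())
  else unique(do.call(rbind, rows))
}

# Number of length-L paths by adjacency-matrix power.
oracle_path_count <- function(g, L) {
  ids <- g$ids
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(g$edges) > 0L)
    A[cbind(g$edges$from, g$edges$to)] <- 1
  if (L == 1L) return(length(ids))
  P <- A
  for (s in seq_len(L - 2L)) P <- P %*% A
  sum(P)
}

# Semi-repeat-free oracle: enumerate all path strings (every start node,
# up to `maxlen` nodes) and demand that every occurrence of every label
# aligns with the start of a same-block node.
oracle_semi_repeat_free <- function(bg, maxlen = NULL) {
  g <- bg$graph
  if (is.null(maxlen)) maxlen <- bg$k
  ok <- TRUE
  paths <- list()
  grow <- lapply(g$ids, function(v) v)
  for (L in seq_len(maxlen)) {
    paths <- c(paths, grow)
    nxt <- list()
    for (p in grow)
      for (u in g$out_adj[[p[length(p)]]]) nxt[[length(nxt) + 1L]] <- c(p, u)
    if (length(nxt) == 0L) break
    grow <- nxt
  }
  all_pos <- function(pattern, text) {  # overlapping occurrence positions
    k <- nchar(pattern); n <- nchar(text)
    if (k > n) return(integer())
    which(vapply(seq_len(n - k + 1L), function(i)
      substr(text, i, i + k - 1L) == pattern, logical(1)))
  }
  for (p in paths) {
    s <- paste(g$labels[p], collapse = "")
    starts <- c(0L, cumsum(nchar(g$labels[p])))[seq_along(p)] + 1L
    for (v in g$ids) {
      for (pos in all_pos(g$labels[[v]], s)) {
        at <- match(pos, starts)
        if (is.na(at) || bg$blocks[[p[at]]] != bg$blocks[[v]]) ok <- FALSE
      }
    }
  }
  ok
}

# Canonical row keys for MEM set comparison.
mem_key <- function(d) paste(d$query_id, d$qstart, d$qend, d$i, d$path, d$j)

# Independent re-check of the graph MEM definition for one data-frame row
# (own extension computation, not the package's lext/rext).
def1_holds <- function(g, Q, row, kappa) {
  qc <- strsplit(Q, "", fixed = TRUE)[[1]]
  p <- strsplit(row$path, ">", fixed = TRUE)[[1]]
  lens <- nchar(g$labels[p])
  full <- paste(g$labels[p], collapse = "")
  sp <- substr(full, row$i, nchar(full) - (lens[length(lens)] - row$j))
  if (sp != substr(Q, row$qstart, row$qend)) return(FALSE)
  if (row$qend - row$qstart + 1L < kappa) return(FALSE)
  lxt <- if (row$i > 1L) substr(g$labels[[p[1]]], row$i - 1L, row$i - 1L)
  else unique(vapply(g$in_adj[[p[1]]], function(u)
    substr(g$labels[[u]], nchar(g$labels[[u]]), nchar(g$labels[[u]])),
    character(1), USE.NAMES = FALSE))
  rxt <- if (row$j < lens[length(lens)])
    substr(g$labels[[p[length(p)]]], row$j + 1L, row$j + 1L)
  else unique(vapply(g$out_adj[[p[length(p)]]], function(u)
    substr(g$labels[[u]], 1L, 1L), character(1), USE.NAMES = FALSE))
  lok <- row$qstart == 1L || length(lxt) == 0L ||
    !(qc[row$qstart - 1L] %in% lxt) || length(lxt) >= 2L
  rok <- row$qend == length(qc) || length(rxt) == 0L ||
    !(qc[row$qend + 1L] %in% rxt) || length(rxt) >= 2L
  lok && rok
}

# The guaranteed piece decomposition of >=3-node MEMs (suffix-edge piece,
# interior whole-edge pieces, prefix-edge piece); returns, per row of
# `long`, whether every implied piece occurs in the relaxed special-MEM
# output `sp`.
pieces_cover_mems <- function(g, long, sp) {
  spk <- paste(sp$qstart, sp$qend, sp$i, sp$path, sp$j)
  vapply(seq_len(nrow(long)), function(k) {
    p <- strsplit(long$path[k], ">", fixed = TRUE)[[1]]
    L <- length(p)
    lens <- nchar(g$labels[p])
    qstart <- long$qstart[k]; i <- long$i[k]
    node_start <- function(t)  # query position where node t starts
      qstart + (lens[1] - i + 1L) +
        (if (t > 2L) sum(lens[seq(2L, t - 1L)]) else 0L)
    want <- paste(qstart, node_start(3L) - 1L, i,
                  paste(p[1:2], collapse = ">"), lens[2])
    if (L >= 4L) for (t in 2:(L - 2L))
      want <- c(want, paste(node_start(t), node_start(t + 2L) - 1L, 1L,
                            paste(p[t:(t + 1L)], collapse = ">"), lens[t + 1L]))
    want <- c(want, paste(node_start(L - 1L), long$qend[k], 1L,
                          paste(p[(L - 1L):L], collapse = ">"), long$j[k]))
    all(want %in% spk)
  }, logical(1))
}
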