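# Seeded synthetic data: random texts, random labeled graphs,
# semi-repeat-free block graphs, mutated path queries, and the two worked
# toy fixtures used throughout the documentation and tests.

#' Generator configuration
#'
#' A single seeded configuration object driving all generators; identical
#' configurations produce identical outputs.
#'
#' @param seed RNG seed.
#' @param alphabet symbol set (default DNA).
#' @param n_nodes node count for unstructured random graphs.
#' @param label_len length-2 vector: node label length range.
#' @param degree maximum in/out degree for unstructured random graphs.
#' @param edge_prob edge retention probability for unstructured graphs.
#' @param k block count for block graphs.
#' @param height maximum nodes per block.
#' @param n_queries,query_len,mutations query sampling: count, length, and
#'   number of substituted positions per query (substitution draws uniformly
#'   from the alphabet, so it may be silent).
#' @param max_tries rejection-sampling cap for semi-repeat-free graphs.
#' @export
generator_config <- function(seed = 1L, alphabet = c("A", "C", "G", "T"),
                             n_nodes = 10L, label_len = c(4L, 8L),
                             degree = 3L, edge_prob = 0.4,
                             k = 20L, height = 4L,
                             n_queries = 30L, query_len = 100L,
                             mutations = 2L, max_tries = 50L) {
  structure(list(seed = as.integer(seed), alphabet = alphabet,
                 n_nodes = as.integer(n_nodes), label_len = as.integer(label_len),
                 degree = as.integer(degree), edge_prob = edge_prob,
                 k = as.integer(k), height = as.integer(height),
                 n_queries = as.integer(n_queries),
                 query_len = as.integer(query_len),
                 mutations = as.integer(mutations),
                 max_tries = as.integer(max_tries)),
            class = "generator_config")
}

#' Random DNA string
#' @param n length.
#' @param seed RNG seed.
#' @param alphabet symbol set.
#' @export
random_dna <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  with_seed(seed, paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

#' Toy graph fixture
#'
#' A minimal four-node graph with a worked query: node v = "ACCGTA" has two
#' in-neighbors (one ending in A, one — node u, label length 5 — ending in
#' C) and one out-neighbor starting with G, so the substring covering all of
#' v has left-extension \{A, C\} and right-extension \{G\}. With query
#' "CACCGTAT", ([1..7], (5, u>v, 6)) and ([2..7], (1, v, 6)) are MEMs.
#'
#' @return list with \code{graph} (a \code{labeled_graph}) and \code{query}.
#' @export
toy_graph_fixture <- function() {
  g <- labeled_graph(
    c(w = "GATTA", u = "GATTC", v = "ACCGTA", s = "GTT"),
    data.frame(from = c("w", "u", "v"), to = c("v", "v", "s")))
  list(graph = g, query = "CACCGTAT")
}

#' Toy string fixture
#'
#' The worked string pair used in the documentation: query "GAAT" against
#' text "AGAAAG". With kappa = 2 the MEMs are (1, 2, 3) for "GAA" and
#' (2, 4, 2) for "AA"; the candidate "GA" is pruned because the same
#' character follows all of its occurrences in both strings.
#'
#' @return list with \code{Q} and \code{T}.
#' @export
toy_string_fixture <- function() list(Q = "GAAT", T = "AGAAAG")

rand_label <- function(cfg) {
  rng <- cfg$label_len
  len <- if (rng[1L] == rng[2L]) rng[1L]
         else sample(seq.int(rng[1L], rng[2L]), 1L)
  paste(sample(cfg$alphabet, len, replace = TRUE), collapse = "")
}

#' Random unstructured labeled graph
#'
#' General directed graph (cycles allowed) with random labels; used for
#' exercising the exact-L MEM machinery on arbitrary graphs.
#'
#' @param cfg a [generator_config()].
#' @return a \code{labeled_graph}.
#' @export
random_labeled_graph <- function(cfg) {
  with_seed(cfg$seed, {
    ids <- sprintf("n%02d", seq_len(cfg$n_nodes))
    labels <- setNames(vapply(ids, function(.) rand_label(cfg), character(1)), ids)
    cand <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    cand <- cand[runif(nrow(cand)) < cfg$edge_prob, , drop = FALSE]
    # enforce the degree cap
    keep <- logical(nrow(cand))
    outd <- setNames(integer(length(ids)), ids)
    ind <- setNames(integer(length(ids)), ids)
    for (r in seq_len(nrow(cand))) {
      f <- cand$from[r]; t <- cand$to[r]
      if (outd[[f]] < cfg$degree && ind[[t]] < cfg$degree) {
        keep[r] <- TRUE
        outd[[f]] <- outd[[f]] + 1L
        ind[[t]] <- ind[[t]] + 1L
      }
    }
    labeled_graph(labels, cand[keep, , drop = FALSE])
  })
}

#' Random semi-repeat-free block graph
#'
#' Draws k blocks of 1..height nodes with distinct random labels and random
#' edges between consecutive blocks (every node connected). Labels are drawn
#' by rejection: each candidate label is redrawn until it occurs nowhere in
#' the labels placed so far (other than as allowed same-block prefixes) and
#' contains no placed label off-start; after edges are drawn the whole graph
#' is validated and any label still violating the semi-repeat-free property
#' (e.g. via an edge-crossing occurrence) is redrawn, up to
#' \code{cfg$max_tries} repair rounds. The result is always accepted by
#' [validate_semi_repeat_free()].
#'
#' @param cfg a [generator_config()].
#' @return a \code{block_graph} accepted by [validate_semi_repeat_free()].
#' @export
random_block_graph <- function(cfg) {
  with_seed(cfg$seed, {
    sizes <- sample(seq_len(cfg$height), cfg$k, replace = TRUE)
    ids <- unlist(lapply(seq_len(cfg$k), function(b)
      sprintf("b%02dn%d", b, seq_len(sizes[b]))))
    blocks <- setNames(rep(seq_len(cfg$k), sizes), ids)
    labels <- setNames(rep(NA_character_, length(ids)), ids)

    # candidate label is clean w.r.t. currently placed labels
    clean_candidate <- function(cand, b) {
      placed <- labels[!is.na(labels)]
      if (length(placed) == 0L) return(TRUE)
      if (cand %in% placed) return(FALSE)
      # no placed label inside the candidate off-start; a placed label at
      # the start is only allowed from the same block
      for (pos in seq_len(nchar(cand))) {
        for (len in seq.int(cfg$label_len[1L],
                            min(cfg$label_len[2L], nchar(cand) - pos + 1L))) {
          sub <- substr(cand, pos, pos + len - 1L)
          hit <- names(placed)[placed == sub]
          if (length(hit) && (pos > 1L || any(blocks[hit] != b))) return(FALSE)
        }
      }
      # the candidate occurs in placed labels only as a same-block prefix
      for (w in names(placed)) {
        hits <- gregexpr(cand, placed[[w]], fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        if (any(hits > 1L) || blocks[[w]] != b) return(FALSE)
      }
      TRUE
    }
    draw_label <- function(v) {
      for (try in seq_len(500L)) {
        cand <- rand_label(cfg)
        if (clean_candidate(cand, blocks[[v]])) return(cand)
      }
      stop("cannot draw a conflict-free label; loosen parameters")
    }
    for (v in ids) labels[v] <- draw_label(v)

    from <- character(); to <- character()
    for (b in seq_len(cfg$k - 1L)) {
      left <- ids[blocks[ids] == b]; right <- ids[blocks[ids] == b + 1L]
      # every right node gets a parent, every left node a child, plus extras
      f <- sample(left, length(right), replace = TRUE)
      from <- c(from, f); to <- c(to, right)
      orphan <- setdiff(left, f)
      if (length(orphan)) {
        from <- c(from, orphan)
        to <- c(to, sample(right, length(orphan), replace = TRUE))
      }
      extra <- expand.grid(from = left, to = right, stringsAsFactors = FALSE)
      extra <- extra[stats::runif(nrow(extra)) < 0.25, , drop = FALSE]
      from <- c(from, extra$from); to <- c(to, extra$to)
    }
    edges <- unique(data.frame(from = from, to = to))

    # whole-graph validation with targeted repair (edge-crossing occurrences
    # are not visible to the label-local screen above)
    for (round in seq_len(cfg$max_tries)) {
      bg <- block_graph(labeled_graph(labels, edges), blocks)
      chk <- validate_semi_repeat_free(bg)
      if (chk$valid) return(bg)
      for (v in unique(chk$violations$label_node)) {
        labels[v] <- NA_character_
        labels[v] <- draw_label(v)
      }
    }
    stop("no semi-repeat-free graph found within max_tries; loosen parameters")
  })
}

#' Sample mutated path queries from a graph
#'
#' Each query is a random substring of the string spelled by a random
#' maximal path, of length \code{cfg$query_len}, with \code{cfg$mutations}
#' uniformly chosen positions substituted by a uniformly random alphabet
#' symbol (possibly the original one).
#'
#' @param g a \code{labeled_graph} or \code{block_graph}.
#' @param cfg a [generator_config()].
#' @return character vector of queries.
#' @export
sample_queries <- function(g, cfg) {
  g <- as_graph(g)
  if (length(g$ids) == 0L) stop("empty graph")
  with_seed(cfg$seed + 1L, {
    sources <- g$ids[lengths(g$in_adj) == 0L]
    if (length(sources) == 0L) sources <- g$ids
    spell_walk <- function() {
      v <- sample(sources, 1L)
      s <- g$labels[[v]]
      while (nchar(s) < cfg$query_len + cfg$label_len[2L]) {
        nb <- g$out_adj[[v]]
        if (length(nb) == 0L) break
        v <- if (length(nb) == 1L) nb else sample(nb, 1L)
        s <- paste0(s, g$labels[[v]])
      }
      s
    }
    out <- character(cfg$n_queries)
    for (q in seq_len(cfg$n_queries)) {
      s <- ""
      for (try in seq_len(cfg$max_tries)) {
        s <- spell_walk()
        if (nchar(s) >= cfg$query_len) break
      }
      if (nchar(s) < cfg$query_len)
        stop("requested query length exceeds the longest path string")
      at <- sample(nchar(s) - cfg$query_len + 1L, 1L)
      qs <- strsplit(substr(s, at, at + cfg$query_len - 1L), "", fixed = TRUE)[[1]]
      pos <- sample(cfg$query_len, min(cfg$mutations, cfg$query_len))
      qs[pos] <- sample(cfg$alphabet, length(pos), replace = TRUE)
      out[q] <- paste(qs, collapse = "")
    }
    out
  })
}
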