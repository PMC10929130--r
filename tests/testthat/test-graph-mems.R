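# Path-concatenation texts, the D array, node MEMs, exact-L MEMs, and the
# occurrence filter.

test_that("concatenation texts follow the construction formulas", {
  st <- dna_symtab()
  # single node, no edges: both extension sets empty => '#' sentinels
  g1 <- labeled_graph(c(a = "AC"))
  tn <- build_t_nodes(g1)
  expect_equal(paste(st[tn$idx$codes], collapse = ""), "0AC0")
  t1 <- build_t_l(g1, 1)
  expect_equal(paste(st[t1$idx$codes], collapse = ""), "0#AC#0")

  # chain a(A) -> b(C), L = 2: lext(a) and rext(b) empty => '#'
  g2 <- labeled_graph(c(a = "A", b = "C"), data.frame(from = "a", to = "b"))
  t2 <- build_t_l(g2, 2)
  expect_equal(paste(st[t2$idx$codes], collapse = ""), "0#AC#0")

  # unique extensions become concrete sentinel letters
  g3 <- toy_graph_fixture()$graph
  t3 <- build_t_l(g3, 2)
  units <- strsplit(paste(st[t3$idx$codes], collapse = ""), "0", fixed = TRUE)[[1]]
  units <- units[nzchar(units)]
  expect_setequal(units, c("#GATTCACCGTAG",   # u>v: lext(u) empty, rext(v)={G}
                           "#ACCGTAGTT#",     # v>s: lext(v)={A,C}, rext(s) empty
                           "#GATTAACCGTAG"))  # w>v
  # size bound: |T_L| <= 1 + sum over paths of (||P|| + 3)
  expect_lte(t3$idx$n - 1L,
             1L + sum(vapply(t3$paths, function(p)
               sum(nchar(g3$labels[p])) + 3L, numeric(1))))

  # no length-L path: NULL
  expect_null(build_t_l(g1, 2))
})

test_that("the D array marks first-node suffixes with their last-node distance", {
  g <- toy_graph_fixture()$graph
  t2 <- build_t_l(g, 2)
  st <- t2$symtab
  n <- t2$idx$n
  txt <- c(st[t2$idx$codes], "$")
  # recompute D per definition, directly from the text layout
  zero_pos <- which(txt == "0")
  for (k in seq_len(n)) {
    s <- t2$idx$sa_fwd[k]
    p <- s + 1L
    expected <- NA_integer_
    if (p <= n - 1L) {
      r <- sum(zero_pos <= p)
      if (r >= 1L && r <= length(t2$paths)) {
        i <- p - zero_pos[r] - 1L
        if (!is.na(i) && i >= 1L && i <= t2$firstlen[r])
          expected <- t2$pathlen[r] - t2$lastlen[r] - i + 2L
      }
    }
    expect_equal(t2$d[k], expected)
  }
  # suffixes not starting inside a first node are infinite (NA)
  expect_true(anyNA(t2$d))
})

test_that("node MEMs are the per-label string MEMs, mapped to graph coordinates", {
  # one node labeled AGAAAG, query GAAT: the string-MEM set mapped to (i, v, j)
  g <- labeled_graph(c(v = "AGAAAG"))
  nm <- find_node_mems(g, "GAAT", 2)
  expect_setequal(mem_key(nm), c("1 1 3 2 v 4", "1 2 3 4 v 5"))
  expect_setequal(str_mem_key(data.frame(qstart = nm$qstart, tstart = nm$i,
                                         length = nm$length)),
                  str_mem_key(oracle_string_mems("GAAT", "AGAAAG", 2)))

  # two nodes with identical labels: one copy of each MEM per node
  g2 <- labeled_graph(c(v1 = "AGAAAG", v2 = "AGAAAG"))
  nm2 <- find_node_mems(g2, "GAAT", 2)
  expect_equal(nrow(nm2), 2L * nrow(nm))
  expect_setequal(unique(nm2$path), c("v1", "v2"))

  # kappa beyond every label and the query: empty
  expect_equal(nrow(find_node_mems(g, "GAAT", 10)), 0L)
})

test_that("node MEMs equal the per-node string oracle on random graphs", {
  set.seed(41)
  for (r in 1:15) {
    cfg <- generator_config(seed = 410 + r, n_nodes = sample(3:8, 1),
                            label_len = c(2, 6), edge_prob = 0.3)
    g <- random_labeled_graph(cfg)
    Q <- rand_seq(sample(10:30, 1))
    got <- find_node_mems(g, Q, 1)
    exp <- do.call(rbind, lapply(g$ids, function(v) {
      o <- oracle_string_mems(Q, g$labels[[v]], 1)
      if (nrow(o) == 0L) return(NULL)
      data.frame(query_id = 1L, qstart = o$qstart, qend = o$qstart + o$length - 1L,
                 i = o$tstart, path = v, j = o$tstart + o$length - 1L)
    }))
    if (is.null(exp)) exp <- data.frame(query_id = integer(), qstart = integer(),
                                        qend = integer(), i = integer(),
                                        path = character(), j = integer())
    expect_setequal(mem_key(got), mem_key(exp))
  }
})

test_that("exact-L MEMs on the toy graph match the worked examples", {
  fx <- toy_graph_fixture()
  l2 <- find_l_mems(fx$graph, fx$query, 1, 2)
  expect_true("1 1 7 5 u>v 6" %in% mem_key(l2))
  l1 <- find_l_mems(fx$graph, fx$query, 1, 1)
  expect_true("1 2 7 1 v 6" %in% mem_key(l1))
  # its left extension is the non-singleton {A, C}
  expect_setequal(lext(fx$graph, 1, "v", 6), c("A", "C"))
})

test_that("exact-L MEMs equal the definitional oracle on random graphs", {
  set.seed(42)
  for (r in 1:30) {
    cfg <- generator_config(seed = 420 + r, n_nodes = sample(3:12, 1),
                            label_len = c(1, 6), degree = 3, edge_prob = 0.3)
    g <- random_labeled_graph(cfg)
    Q <- rand_seq(sample(10:40, 1))
    bf3 <- brute_force_graph_mems(g, Q, 1, 3)
    union_keys <- character()
    for (L in 1:3) {
      got <- find_l_mems(g, Q, 1, L)
      expect_setequal(mem_key(got), mem_key(bf3[bf3$nodes == L, , drop = FALSE]))
      union_keys <- c(union_keys, mem_key(got))
    }
    # union over L = 1..3 equals the oracle with Lmax = 3
    expect_setequal(union_keys, mem_key(bf3))
  }
})

test_that("L = 1 MEMs are a subset of the node MEMs", {
  set.seed(43)
  for (r in 1:20) {
    cfg <- generator_config(seed = 430 + r, n_nodes = sample(3:10, 1),
                            label_len = c(2, 6), edge_prob = 0.3)
    g <- random_labeled_graph(cfg)
    Q <- rand_seq(sample(10:30, 1))
    for (kappa in 1:2) {
      l1 <- find_l_mems(g, Q, kappa, 1)
      nm <- find_node_mems(g, Q, kappa)
      expect_true(all(mem_key(l1) %in% mem_key(nm)))
    }
  }
})

test_that("occurrence filtering keeps exactly the MEMs spelled by the rows", {
  g <- labeled_graph(c(a = "ACGT", b = "TTGA", c = "CCCC"),
                     data.frame(from = c("a", "a"), to = c("b", "c")))
  Q <- "ACGTTTGA"
  mems <- rbind(find_l_mems(g, Q, 2, 1), find_l_mems(g, Q, 2, 2))
  # rows contain every node label but only the a->b concatenation
  rows_ab <- c("ACGTTTGA", "CCCC")
  kept <- filter_by_text(mems, g, rows_ab)
  expect_true(all(mem_key(kept) %in% mem_key(mems)))
  full_edge <- "1 1 8 1 a>b 4"   # spells ACGTTTGA across the a->b junction
  expect_true(full_edge %in% mem_key(mems))
  expect_true(full_edge %in% mem_key(kept))
  # rows with every label but no a->b junction: that edge MEM is dropped
  # (short junction strings like "TT" may still occur inside single rows)
  rows_no_ab <- c("ACGT", "TTGA", "CCCC")
  kept2 <- filter_by_text(mems, g, rows_no_ab)
  expect_false(full_edge %in% mem_key(kept2))
  expect_true(all(vapply(seq_len(nrow(kept2)), function(k)
    grepl(spell_substring(g, kept2$i[k],
                          strsplit(kept2$path[k], ">", fixed = TRUE)[[1]],
                          kept2$j[k]),
          paste(rows_no_ab, collapse = "|"), fixed = TRUE), logical(1))))
  # rows spelling every short path: identity
  paths <- unlist(lapply(1:2, function(L)
    vapply(enumerate_paths(g, L), function(p)
      paste(g$labels[p], collapse = ""), character(1))))
  expect_equal(nrow(filter_by_text(mems, g, paths)), nrow(mems))
  # empty set stays empty
  expect_equal(nrow(filter_by_text(mems[0, ], g, rows_ab)), 0L)
})
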