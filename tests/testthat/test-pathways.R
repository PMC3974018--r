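test_that("auto-adjusted anchor counts follow the 124000 * n^-3/2 rule", {
  expect_identical(auto_k(100), 124L)
  expect_identical(auto_k(1), 124000L)
  expect_identical(auto_k(500), 11L)   # 124000/500^1.5 = 11.09
  expect_identical(auto_k(1e6), 1L)    # floored at 1
})

test_that("fuzzy related hishapes apply the helix-index distance rule", {
  got <- fuzzy_related_hishapes("[10]", "[20]", theta = 1,
                                universe = c("[11]", "[15]", "[_]", "[19,9]"))
  expect_equal(got, c("[11]", "[_]", "[19,9]"),
                   ignore_attr = TRUE)
  # theta = 0: only indices drawn from phi(alpha) u phi(beta)
  got0 <- fuzzy_related_hishapes("[10]", "[20]", theta = 0,
                                 universe = c("[10,20]", "[10.5]", "[_]"))
  expect_equal(got0, c("[10,20]", "[_]"), ignore_attr = TRUE)
  # both anchors open: only the open chain qualifies
  gotO <- fuzzy_related_hishapes("[_]", "[_]", theta = 2,
                                 universe = c("[3]", "[_]"))
  expect_equal(gotO, "[_]", ignore_attr = TRUE)
})

test_that("theta = 0 reduces to exact related hishapes on an enumerated universe", {
  sq <- random_sequences(1, 25, gc = 0.65, seed = 61)[[1]]
  cls <- classify(sq)
  alpha <- cls$hishape[1]
  beta <- cls$hishape[min(2, nrow(cls))]
  ref <- union(extract_hairpin_indices(parse_hishape(alpha)),
               extract_hairpin_indices(parse_hishape(beta)))
  got <- fuzzy_related_hishapes(alpha, beta, theta = 0, universe = cls)
  sel <- attr(got, "selected")
  manual <- vapply(cls$hishape, function(tx) {
    ph <- extract_hairpin_indices(parse_hishape(tx))
    all(ph %in% ref)
  }, logical(1))
  expect_identical(unname(sel), unname(manual))
})

test_that("minimax Dijkstra minimizes the path maximum", {
  w1 <- matrix(c(NA, 4, 4, NA), 2, 2)
  got <- minimax_dijkstra(w1, 1, 2)
  expect_identical(got$path, c(1L, 2L))
  expect_identical(got$bottleneck, 4)

  # detour through X (saddles 5 and 3) beats the direct edge (6)
  w <- matrix(NA_real_, 3, 3, dimnames = list(c("S", "X", "T"),
                                              c("S", "X", "T")))
  w["S", "X"] <- w["X", "S"] <- 5
  w["X", "T"] <- w["T", "X"] <- 3
  w["S", "T"] <- w["T", "S"] <- 6
  got <- minimax_dijkstra(w, "S", "T")
  expect_identical(got$path, c(1L, 2L, 3L))
  expect_identical(got$bottleneck, 5)

  w2 <- matrix(NA_real_, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 1
  expect_error(minimax_dijkstra(w2, 1, 3), "unreachable")
})

test_that("minimax Dijkstra equals brute force on random graphs", {
  set.seed(62)
  for (rep in 1:25) {
    nv <- sample(3:8, 1)
    w <- random_weight_matrix(nv)
    ref <- oracle_minimax(w, 1, nv)
    if (!is.finite(ref)) {
      expect_error(minimax_dijkstra(w, 1, nv), "unreachable")
    } else {
      expect_equal(minimax_dijkstra(w, 1, nv)$bottleneck, ref)
    }
  }
})

test_that("direct-path BFS returns sound paths with oracle-consistent barriers", {
  fp0 <- direct_path_bfs("GGAAACC", "((...))", "((...))")
  expect_identical(fp0$steps, "((...))")
  expect_equal(fp0$barrier, 0)

  sq <- "GGAAACC"
  fp <- direct_path_bfs(sq, ".......", "((...))")
  expect_identical(fp$steps, c(".......", "((...))"))
  expect_equal(fp$barrier, E_HAIRPIN7)
  expect_sound_path(rna_sequence(sq), fp)
})

test_that("wider beams never hurt and all estimates dominate the exact barrier", {
  for (seed in c(63, 64, 65)) {
    sq <- random_sequences(1, 24, gc = 0.65, seed = seed)[[1]]
    sp <- enumerate_structures(sq)
    open <- strrep(".", sq$n)
    mfe <- sp$structure[1]
    if (mfe == open) next
    g <- landscape_graph(sq)
    eb <- as.numeric(exact_barrier(sq, open, mfe, graph = g))
    b1 <- direct_path_bfs(sq, open, mfe, k = 1)
    bw <- direct_path_bfs(sq, open, mfe, k = 20)
    expect_lte(bw$barrier, b1$barrier + 1e-9)
    expect_gte(b1$barrier + 1e-9, eb)
    expect_gte(bw$barrier + 1e-9, eb)
    expect_sound_path(sq, b1)
    expect_sound_path(sq, bw)
  }
})

test_that("anchored pathway search obeys the sandwich and falls back cleanly", {
  sq <- random_sequences(1, 24, gc = 0.65, seed = 66)[[1]]
  sp <- enumerate_structures(sq)
  open <- strrep(".", sq$n)
  mfe <- sp$structure[1]

  trivial <- hipath2(sq, mfe, mfe)
  expect_equal(trivial$barrier, 0)

  hp <- hipath2(sq, open, mfe)
  direct <- direct_path_bfs(sq, open, mfe, k = 10)
  g <- landscape_graph(sq)
  eb <- as.numeric(exact_barrier(sq, open, mfe, graph = g))
  expect_gte(hp$barrier + 1e-9, eb)
  expect_lte(hp$barrier, direct$barrier + 1e-9)
  expect_sound_path(sq, hp)

  # anchor admissibility: every anchor satisfies the fuzzy rule at pi_h
  cls <- classify(sq)
  nodes <- attr(hp, "nodes")
  rel <- fuzzy_related_hishapes(map_structure(sq, open, "h"),
                                map_structure(sq, mfe, "h"),
                                theta = 1, universe = cls)
  expect_true(all(nodes[-(1:2)] %in% rel$hishrep))

  # N = 0 anchors: exactly the direct-path estimate
  hp0 <- hipath2(sq, open, mfe, anchors = 0)
  expect_equal(hp0$barrier, direct$barrier)
})

test_that("degenerate pathway searches with no direct route report Inf", {
  # a 3-node toy with an Inf matrix entry cannot happen between enumerable
  # structures of one sequence; exercise via the matrix API instead
  w <- matrix(NA_real_, 2, 2)
  expect_error(minimax_dijkstra(w, 1, 2), "unreachable")
})
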