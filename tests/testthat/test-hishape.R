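test_that("structures map to hishapes at all four abstraction levels", {
  for (lv in c("h", "h+", "m", "a")) {
    expect_identical(map_structure("AAAA", "....", lv)$text, "[_]")
  }
  # innermost pair (2,6): helix index (2+6)/2 = 4
  expect_identical(map_structure("GGAAACC", "((...))", "h")$text, "[4]")

  # multiloop fixture: outer helix center 9.5 (marker m), hairpins 6 and 13
  expect_identical(map_structure(ML_SEQ, ML_DB, "a")$text, "[9.5m(6,13)]")
  expect_identical(map_structure(ML_SEQ, ML_DB, "m")$text, "[9.5m(6,13)]")
  expect_identical(map_structure(ML_SEQ, ML_DB, "h+")$text, "[(6,13)]")
  expect_identical(map_structure(ML_SEQ, ML_DB, "h")$text, "[6,13]")

  # bulge fixture: interrupted helix center 6.5 (marker b), hairpin 7
  expect_identical(map_structure(BULGE_SEQ, BULGE_DB, "a")$text, "[6.5b,7]")
  expect_identical(map_structure(BULGE_SEQ, BULGE_DB, "m")$text, "[7]")
  expect_identical(map_structure(BULGE_SEQ, BULGE_DB, "h")$text, "[7]")

  # numeric level aliases
  expect_identical(map_structure(ML_SEQ, ML_DB, 1)$text, "[6,13]")
  expect_identical(map_structure(ML_SEQ, ML_DB, 4)$text, "[9.5m(6,13)]")
})

test_that("hishape text round-trips and phi extracts hairpin indices only", {
  for (tx in c("[_]", "[4]", "[6.5b,7]", "[9.5m(6,13)]", "[2,17.5,30]")) {
    expect_identical(parse_hishape(tx, "a")$text, tx)
  }
  expect_identical(extract_hairpin_indices(parse_hishape("[2]")), 2)
  expect_length(extract_hairpin_indices(parse_hishape("[_]")), 0)
  expect_identical(extract_hairpin_indices(parse_hishape("[6.5b,7]", "a")), 7)
  expect_identical(extract_hairpin_indices(parse_hishape("[9.5m(6,13)]", "a")),
                   c(6, 13))
  expect_error(parse_hishape("[x]"), "malformed")
})

test_that("pi_a indices equal independently extracted helix centers and loop types", {
  sq <- random_sequences(1, 24, gc = 0.65, seed = 41)[[1]]
  sp <- enumerate_structures(sq)
  pts <- attr(sp, "pt_list")
  for (v in seq_len(nrow(sp))) {
    tree <- hishapes:::helix_tree(pts[[v]])
    hx <- tree$helices
    ord <- order(hx[, "oi"])
    centers <- (hx[ord, "ii"] + hx[ord, "ij"]) / 2
    markers <- c(hairpin = "none", multiloop = "m",
                 bulge = "b", internal = "i")[tree$kind[ord]]
    h <- map_structure(sq, sp$structure[v], "a")
    expect_equal(h$indices$value, unname(centers))
    expect_identical(h$indices$marker, unname(markers))
  }
})

test_that("strictly negative filtering removes costly substructures", {
  expect_true(is_strictly_negative("GGAAACC", "......."))
  # the small hairpin helix costs +2.44 under the bundled table
  expect_false(is_strictly_negative("GGAAACC", "((...))"))
  # a long GC helix is stabilizing
  expect_true(is_strictly_negative("GGGGAAACCCC", "((((...))))"))

  sq <- random_sequences(1, 25, gc = 0.65, seed = 42)[[1]]
  sp <- enumerate_structures(sq)
  sn <- vapply(sp$structure, function(db) is_strictly_negative(sq, db),
               logical(1))
  expect_true(sn[[which(sp$structure == strrep(".", sq$n))]])
  expect_lte(sum(sn), length(sn))
  # classify() under SN uses exactly this subset
  cls <- classify(sq, strictly_negative = TRUE, space = sp)
  expect_identical(sum(cls$members), sum(sn))
})

test_that("classification partitions the space with Boltzmann bookkeeping", {
  cls1 <- classify("AAAA")
  expect_identical(cls1$hishape, "[_]")
  expect_identical(cls1$probability, 1)

  cls2 <- classify("GGAAACC")
  expect_identical(cls2$hishape, c("[_]", "[4]"))
  z <- exp(-E_HAIRPIN7 / hishapes:::kT(TOY_PARAMS))
  expect_equal(cls2$probability, c(1, z) / (1 + z))
  expect_equal(cls2$ensemble_energy, c(0, E_HAIRPIN7))

  sq <- random_sequences(1, 26, gc = 0.6, seed = 43)[[1]]
  sp <- enumerate_structures(sq)
  ktv <- hishapes:::kT(TOY_PARAMS)
  ztotal <- sum(exp(-sp$energy / ktv))
  for (lv in c("h", "h+", "m", "a")) {
    cls <- classify(sq, level = lv, space = sp)
    expect_identical(sum(cls$members), nrow(sp))
    expect_equal(sum(cls$Z), ztotal, tolerance = 1e-9)
    expect_equal(sum(cls$probability), 1, tolerance = 1e-12)
    expect_equal(cls$ensemble_energy, -ktv * log(cls$Z), tolerance = 1e-9)
  }
})

test_that("class counts refine monotonically and k_best truncates deterministically", {
  sq <- random_sequences(1, 26, gc = 0.6, seed = 44)[[1]]
  sp <- enumerate_structures(sq)
  counts <- vapply(c("h", "h+", "m", "a"), function(lv) {
    nrow(classify(sq, level = lv, space = sp))
  }, integer(1))
  expect_false(is.unsorted(counts))
  sn_counts <- vapply(c("h", "h+", "m", "a"), function(lv) {
    nrow(classify(sq, level = lv, strictly_negative = TRUE, space = sp))
  }, integer(1))
  expect_true(all(sn_counts <= counts))

  full <- classify(sq, space = sp)
  top3 <- classify(sq, k_best = 3, space = sp)
  expect_identical(top3$hishape, full$hishape[1:3])
  expect_identical(top3$probability, full$probability[1:3])
})

test_that("hishreps are the minimum-energy members of their class", {
  sq <- random_sequences(1, 25, gc = 0.65, seed = 45)[[1]]
  sp <- enumerate_structures(sq)
  for (lv in c("h", "a")) {
    cls <- classify(sq, level = lv, space = sp)
    texts <- vapply(sp$structure, function(db) {
      map_structure(sq, db, lv)$text
    }, character(1))
    for (r in seq_len(nrow(cls))) {
      members <- sp$energy[texts == cls$hishape[r]]
      expect_equal(cls$hishrep_energy[r], min(members))
      expect_identical(cls$members[r], length(members))
    }
  }
})
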