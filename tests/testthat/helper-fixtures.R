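# shared hand-built fixtures
# two-helix multiloop: ((((...))((...))))  on GGGGAAACCGGAAACCCC
ML_SEQ <- "GGGGAAACCGGAAACCCC"
ML_DB <- "((((...))((...))))"
# bulged helix: ((.((...))))  on GGAGGAAACCCC
BULGE_SEQ <- "GGAGGAAACCCC"
BULGE_DB <- "((.((...))))"

# energy of the GGAAACC hairpin helix under the bundled table:
# stack(GC/GC) + hairpin initiation of size 3 = -3.26 + 5.70
E_HAIRPIN7 <- 2.44

# walk a folding path and check it is a sound neighbor chain whose
# energies and barrier match the reported values
expect_sound_path <- function(sq, fp) {
  expect_s3_class(fp, "folding_path")
  expect_gte(length(fp$steps), 1)
  for (q in seq_along(fp$steps)) {
    expect_equal(structure_energy(sq, fp$steps[q]), fp$energies[q])
  }
  if (length(fp$steps) > 1) {
    for (q in seq_len(length(fp$steps) - 1)) {
      nbs <- vapply(neighbors(sq, fp$steps[q]), format, character(1))
      expect_true(fp$steps[q + 1] %in% nbs,
                  label = paste("step", q + 1, "is a neighbor of step", q))
    }
  }
  expect_equal(fp$saddle, max(fp$energies))
  expect_equal(fp$barrier, fp$saddle - fp$energies[1])
}

# independent loop-model evaluator: walks the pair table pair by pair,
# classifying each closed loop by a fresh interior scan
oracle_energy <- function(sq, db, params = TOY_PARAMS) {
  pt <- hishapes:::parse_dotbracket(db)$pt
  chars <- sq$chars
  total <- 0
  prs <- which(pt > seq_along(pt))
  for (i in prs) {
    j <- pt[i]
    # interior scan
    branches <- list()
    unp <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        branches[[length(branches) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else {
        unp <- unp + 1L
        k <- k + 1L
      }
    }
    ptype <- paste0(chars[i], chars[j])
    au <- function(tp) if (tp %in% c("AU", "UA", "GU", "UG"))
      params$terminal_au else 0
    init <- function(tab, size) hishapes:::loop_initiation(tab, size, params$lxc)
    nb <- length(branches)
    total <- total + if (nb == 0L) {
      init(params$hairpin, unp) + au(ptype)
    } else if (nb == 1L && unp == 0L) {
      params$stack[ptype, paste0(chars[i + 1], chars[j - 1])]
    } else if (nb == 1L) {
      b <- branches[[1]]
      tab <- if (b[1] == i + 1L || b[2] == j - 1L) params$bulge
             else params$internal
      init(tab, unp) + au(ptype) + au(paste0(chars[b[1]], chars[b[2]]))
    } else {
      params$ml_offset + params$ml_branch * (nb + 1L) +
        params$ml_unpaired * unp + au(ptype) +
        sum(vapply(branches,
                   function(b) au(paste0(chars[b[1]], chars[b[2]])),
                   numeric(1)))
    }
  }
  total
}
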