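#' Enumerate the lonely-pair-free folding space
#'
#' Exhaustively enumerates all pseudoknot-free secondary structures without
#' lonely pairs that are compatible with a sequence (canonical pairs AU, GC,
#' GU; hairpin loops of at least 3 unpaired bases). The enumeration is a
#' memoized interval recursion over maximal helices, so each structure is
#' produced exactly once; an optional energy band restricts the returned set
#' to structures within `energy_band` kcal/mol of the optimum.
#'
#' @inheritParams structure_energy
#' @param energy_band Optional band in kcal/mol above the minimum free
#'   energy; `NULL` (default) returns the complete space.
#' @param max_len Refusal limit for exhaustive enumeration (default 60 nt).
#' @return A data frame with columns `structure` (dot-bracket) and `energy`
#'   (kcal/mol), sorted by energy with lexicographic dot-bracket tie-break.
#'   The matching pair tables are attached as attribute `"pt_list"`.
#' @examples
#' enumerate_structures("GGAAACC")
#' @export
enumerate_structures <- function(seq, params = energy_parameters(),
                                 energy_band = NULL, max_len = 60) {
  sq <- as_rna_sequence(seq)
  if (sq$n > max_len && is.null(energy_band)) {
    stop("sequence length ", sq$n, " exceeds the exhaustive enumeration ",
         "limit (", max_len, " nt); supply energy_band to accept the cost ",
         "of banded exhaustive enumeration, or shorten the input")
  }
  frags <- enumerate_pairsets(sq$chars)
  n <- sq$n
  db <- character(length(frags))
  energy <- numeric(length(frags))
  pt_list <- vector("list", length(frags))
  for (m in seq_along(frags)) {
    pt <- pt_from_pairs(frags[[m]], n)
    pt_list[[m]] <- pt
    db[m] <- db_from_pt(pt)
    energy[m] <- energy_pt(sq$chars, pt, params)
  }
  ord <- order(energy, db)
  db <- db[ord]; energy <- energy[ord]; pt_list <- pt_list[ord]
  if (!is.null(energy_band)) {
    keep <- energy <= energy[1] + energy_band
    db <- db[keep]; energy <- energy[keep]; pt_list <- pt_list[keep]
  }
  out <- data.frame(structure = db, energy = energy,
                    stringsAsFactors = FALSE)
  attr(out, "pt_list") <- pt_list
  attr(out, "n") <- n
  out
}

# all noLP pair sets over chars, as flat integer vectors c(i1,j1,i2,j2,...);
# unique by construction (first paired position, partner, maximal helix run)
enumerate_pairsets <- function(chars) {
  n <- length(chars)
  cp <- outer(chars, chars, FUN = function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  })
  memo <- new.env(parent = emptyenv())

  rec <- function(i, j) {
    if (j - i < 4) return(list(integer(0)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- rec(i + 1L, j)                    # position i unpaired
    for (k in seq.int(i + 4L, j)) {
      if (!cp[i, k]) next
      # grow a maximal helix (i,k), (i+1,k-1), ... of length l >= 2
      l <- 2L
      repeat {
        if (k - i < 2L * l + 2L) break       # innermost span too small
        if (!all(cp[cbind(seq.int(i, i + l - 1L), seq.int(k, k - l + 1L))])) break
        hx <- as.integer(rbind(seq.int(i, i + l - 1L),
                               seq.int(k, k - l + 1L)))
        ii <- i + l; jj <- k - l
        outers <- rec(k + 1L, j)
        for (inner in rec(ii, jj)) {
          if (length(inner)) {
            # maximality: the helix must not extend into the inner interval
            ip <- seq(1L, length(inner), by = 2L)
            if (any(inner[ip] == ii & inner[ip + 1L] == jj)) next
          }
          # empty interior: hairpin needs >= 3 unpaired (k-i >= 2l+2 holds)
          for (outer in outers) {
            res[[length(res) + 1L]] <- c(hx, inner, outer)
          }
        }
        l <- l + 1L
      }
    }
    memo[[key]] <- res
    res
  }

  rec(1L, n)
}
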