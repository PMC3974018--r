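#' RNA sequence
#'
#' Constructs an `rna_sequence`: an identifier plus residues over `{A,C,G,U}`
#' with 1-based positions. `T` is accepted on input and normalized to `U`;
#' lowercase is uppercased.
#'
#' @param residues Character scalar with the sequence.
#' @param id Identifier (default `"seq"`).
#' @return An object of class `rna_sequence` with fields `id`, `seq`
#'   (normalized string), `chars` (character vector) and `n` (length in nt).
#' @examples
#' rna_sequence("ggaaacc")
#' @export
rna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1)
  s <- chartr("tT", "uU", residues)
  s <- toupper(gsub("\\s", "", s))
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("illegal residue '", chars[bad[1]], "' at position ", bad[1])
  }
  structure(list(id = id, seq = s, chars = chars, n = length(chars)),
            class = "rna_sequence")
}

as_rna_sequence <- function(x) {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x)
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(">", x$id, " (", x$n, " nt)\n", x$seq, "\n", sep = "")
  invisible(x)
}

# canonical base-pair test, vector-safe on single bases
can_pair_bases <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Parse dot-bracket notation
#'
#' Converts a dot-bracket string into a `secondary_structure` (a pair table
#' over 1-based positions). Structures are required to be balanced; the
#' remaining invariants (pseudoknot-freedom is implied by the notation,
#' minimum hairpin size, absence of lonely pairs) can be checked with
#' [validate_structure()].
#'
#' @param text Dot-bracket string using `.`, `(` and `)`.
#' @return An object of class `secondary_structure` with fields `pt`
#'   (pair-table integer vector, 0 = unpaired) and `n`.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  pt <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    c <- chars[i]
    if (c == "(") {
      open <- c(open, i)
    } else if (c == ")") {
      if (length(open) == 0) {
        stop("unbalanced ')' at column ", i)
      }
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[j] <- i
      pt[i] <- j
    } else if (c != ".") {
      stop("illegal character '", c, "' at column ", i)
    }
  }
  if (length(open)) stop("unbalanced '(' at column ", open[1])
  new_structure(pt)
}

new_structure <- function(pt) {
  structure(list(pt = as.integer(pt), n = length(pt)),
            class = "secondary_structure")
}

as_structure <- function(x) {
  if (inherits(x, "secondary_structure")) x else parse_dotbracket(x)
}

#' Write dot-bracket notation
#'
#' Inverse of [parse_dotbracket()]: `parse_dotbracket(write_dotbracket(s))`
#' reproduces `s`.
#'
#' @param structure A `secondary_structure` (or dot-bracket string).
#' @return Dot-bracket character scalar.
#' @export
write_dotbracket <- function(structure) {
  s <- as_structure(structure)
  db_from_pt(s$pt)
}

db_from_pt <- function(pt) {
  out <- rep(".", length(pt))
  idx <- which(pt > seq_along(pt))
  out[idx] <- "("
  out[pt[idx]] <- ")"
  paste(out, collapse = "")
}

# 2-column matrix of pairs (i < j), ordered by i
pairs_from_pt <- function(pt) {
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
}

pt_from_pairs <- function(pairs, n) {
  pt <- integer(n)
  if (length(pairs)) {
    m <- matrix(pairs, ncol = 2, byrow = TRUE)  # flat (i1,j1,i2,j2,...)
    pt[m[, 1]] <- m[, 2]
    pt[m[, 2]] <- m[, 1]
  }
  pt
}

#' Structure pairs
#'
#' @param structure A `secondary_structure` or dot-bracket string.
#' @return Two-column integer matrix of base pairs `(i, j)` with `i < j`.
#' @export
structure_pairs <- function(structure) {
  pairs_from_pt(as_structure(structure)$pt)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(db_from_pt(x$pt), " (", nrow(pairs_from_pt(x$pt)), " pairs)\n", sep = "")
  invisible(x)
}

#' @export
format.secondary_structure <- function(x, ...) db_from_pt(x$pt)

# ---- invariants -----------------------------------------------------------

# TRUE iff every pair in pt has a stacking neighbor pair
pt_is_nolp <- function(pt) {
  idx <- which(pt > seq_along(pt))
  n <- length(pt)
  for (i in idx) {
    j <- pt[i]
    inner <- i + 1 <= n && pt[i + 1] == j - 1
    outer <- i - 1 >= 1 && j + 1 <= n && pt[i - 1] == j + 1
    if (!inner && !outer) return(FALSE)
  }
  TRUE
}

#' Validate a secondary structure
#'
#' Checks the structure invariants: each position in at most one pair and no
#' pseudoknots (both guaranteed by the pair-table representation), minimum
#' hairpin span (`j - i >= 4` for every pair), absence of lonely pairs
#' (every pair stacked on a neighbor), and -- when a sequence is supplied --
#' that all pairs are canonical (AU, GC, GU).
#'
#' @param structure A `secondary_structure` or dot-bracket string.
#' @param seq Optional `rna_sequence` (or string) for pair-compatibility.
#' @param nolp Require lonely-pair-freedom (default `TRUE`).
#' @return The validated structure, invisibly. Errors name the first
#'   offending position.
#' @export
validate_structure <- function(structure, seq = NULL, nolp = TRUE) {
  s <- as_structure(structure)
  pt <- s$pt
  prs <- pairs_from_pt(pt)
  if (nrow(prs)) {
    bad <- which(prs[, 2] - prs[, 1] < 4)
    if (length(bad)) {
      stop("pair (", prs[bad[1], 1], ",", prs[bad[1], 2],
           ") closes a hairpin loop with fewer than 3 unpaired bases")
    }
  }
  if (nolp && !pt_is_nolp(pt)) {
    idx <- which(pt > seq_along(pt))
    for (i in idx) {
      j <- pt[i]
      inner <- i + 1 <= s$n && pt[i + 1] == j - 1
      outer <- i - 1 >= 1 && j + 1 <= s$n && pt[i - 1] == j + 1
      if (!inner && !outer) {
        stop("lonely pair (", i, ",", j, ")")
      }
    }
  }
  if (!is.null(seq)) {
    sq <- as_rna_sequence(seq)
    if (sq$n != s$n) {
      stop("structure length ", s$n, " does not match sequence length ", sq$n)
    }
    if (nrow(prs)) {
      ok <- can_pair_bases(sq$chars[prs[, 1]], sq$chars[prs[, 2]])
      if (!all(ok)) {
        b <- which(!ok)[1]
        stop("non-canonical pair ", sq$chars[prs[b, 1]], "-",
             sq$chars[prs[b, 2]], " at positions (",
             prs[b, 1], ",", prs[b, 2], ")")
      }
    }
  }
  invisible(s)
}

#' Open-chain structure
#'
#' @param n Sequence length in nt.
#' @return The unpaired `secondary_structure` of length `n`.
#' @export
open_chain <- function(n) new_structure(integer(n))
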