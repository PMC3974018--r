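#' @name hishape
#' @title Helix index shapes
#'
#' @description
#' A hishape is the ordered list of decorated helix indices of a structure at
#' a chosen abstraction level. A helix is a maximal run of stacked pairs; its
#' innermost pair `(i, j)` closes the helix's terminating loop and the helix
#' index is the central position `(i + j) / 2` of that closing pair (possibly
#' half-integral). Indices are decorated `m`, `b` or `i` when the terminating
#' loop is a multiloop, bulge or internal loop; hairpin-terminated helices
#' carry no marker.
#'
#' The four abstraction levels form a refinement chain
#' `h` ⊑ `h+` ⊑ `m` ⊑ `a`:
#' * `"h"`  -- hairpin-loop helices only, flat list;
#' * `"h+"` -- additionally records multiloop nesting with parentheses;
#' * `"m"`  -- additionally keeps multiloop helices (marker `m`);
#' * `"a"`  -- additionally keeps bulge and internal helices (markers `b`, `i`).
#'
#' The canonical text form is a bracketed comma-separated list, e.g.
#' `"[4]"` or `"[12m(5,9),17.5]"`; the open chain is rendered `"[_]"`.
NULL

ABSTRACTION_LEVELS <- c("h", "h+", "m", "a")

normalize_level <- function(level) {
  lv <- as.character(level)
  alias <- c("1" = "h", "2" = "h+", "3" = "m", "4" = "a")
  if (lv %in% names(alias)) lv <- alias[[lv]]
  if (!lv %in% ABSTRACTION_LEVELS) {
    stop("unknown abstraction level '", level,
         "' (use h, h+, m, a or 1-4)")
  }
  lv
}

# maximal stacked runs: one row per helix with outer/inner pairs
pt_helices <- function(pt) {
  prs <- pairs_from_pt(pt)
  if (nrow(prs) == 0L) {
    return(matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("oi", "oj", "ii", "ij"))))
  }
  helices <- NULL
  r <- 1L
  while (r <= nrow(prs)) {
    oi <- prs[r, 1]; oj <- prs[r, 2]
    ii <- oi; ij <- oj
    while (ii + 1 <= length(pt) && pt[ii + 1] == ij - 1) {
      ii <- ii + 1L; ij <- ij - 1L
    }
    helices <- rbind(helices, c(oi, oj, ii, ij))
    # skip the consumed run (its pairs are consecutive rows of prs)
    r <- r + (ii - oi) + 1L
  }
  colnames(helices) <- c("oi", "oj", "ii", "ij")
  helices
}

# helix tree: parent of a helix is the helix whose terminating loop contains
# its outer pair; returns list(helices, parent, loop_kind per helix)
helix_tree <- function(pt) {
  hx <- pt_helices(pt)
  nh <- nrow(hx)
  kind <- character(nh)
  parent <- integer(nh)   # 0 = exterior
  if (nh == 0L) return(list(helices = hx, kind = kind, parent = parent))
  # loop kind terminated by each helix, from its innermost pair
  for (h in seq_len(nh)) {
    inn <- scan_interior(pt, hx[h, "ii"] + 1L, hx[h, "ij"] - 1L)
    nb <- if (is.null(inn$branches)) 0L else nrow(inn$branches)
    kind[h] <- if (nb == 0L) "hairpin"
               else if (nb >= 2L) "multiloop"
               else if (inn$gaps[1] == 0L || inn$gaps[2] == 0L) "bulge"
               else "internal"
  }
  # parent: helix whose inner interval most tightly encloses our outer pair
  for (h in seq_len(nh)) {
    best <- 0L; span <- Inf
    for (g in seq_len(nh)) {
      if (g == h) next
      if (hx[g, "ii"] < hx[h, "oi"] && hx[g, "ij"] > hx[h, "oj"]) {
        sp <- hx[g, "ij"] - hx[g, "ii"]
        if (sp < span) { span <- sp; best <- g }
      }
    }
    parent[h] <- best
  }
  list(helices = hx, kind = kind, parent = parent)
}

fmt_index <- function(x) {
  if (abs(x - round(x)) < 1e-9) sprintf("%d", as.integer(round(x)))
  else sprintf("%.1f", x)
}

#' Map a structure to its hishape
#'
#' @inheritParams structure_energy
#' @param structure A `secondary_structure` or dot-bracket string.
#' @param level Abstraction level: `"h"`, `"h+"`, `"m"` or `"a"` (numeric
#'   aliases `1`-`4` accepted).
#' @return Object of class `hishape`: list with `level`, canonical `text`,
#'   `indices` (data frame of `value`, `marker` in 5' order) and `phi` (the
#'   hairpin helix-index values, see [extract_hairpin_indices()]).
#' @examples
#' map_structure("GGAAACC", "((...))", level = "h")
#' @export
map_structure <- function(seq, structure, level = "h") {
  lv <- normalize_level(level)
  s <- validate_structure(structure, seq = seq)
  tree <- helix_tree(s$pt)
  parse_hishape(render_hishape(tree, lv)$text, lv)
}

#' Parse a canonical hishape text
#'
#' @param text Canonical hishape string, e.g. `"[12m(5,9),17.5]"` or `"[_]"`.
#' @param level Abstraction level the text belongs to.
#' @return A `hishape` object; `parse_hishape(h$text, h$level)` round-trips.
#' @export
parse_hishape <- function(text, level = "h") {
  lv <- normalize_level(level)
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl("^\\[.*\\]$", text)) stop("hishape text must be bracketed: ", text)
  inner <- substr(text, 2, nchar(text) - 1)
  value <- numeric(0); marker <- character(0)
  if (inner != "_" && nzchar(inner)) {
    body <- gsub("[()]", ",", inner)
    toks <- strsplit(body, ",", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    for (tk in toks) {
      m <- regmatches(tk, regexec("^([0-9]+(?:\\.[0-9]+)?)([mbi]?)$", tk))[[1]]
      if (length(m) == 0) stop("malformed hishape component '", tk, "'")
      value <- c(value, as.numeric(m[2]))
      marker <- c(marker, if (nzchar(m[3])) m[3] else "none")
    }
  }
  structure(list(level = lv, text = text,
                 indices = data.frame(value = value, marker = marker,
                                      stringsAsFactors = FALSE),
                 phi = value[marker == "none"]),
            class = "hishape")
}

#' @export
print.hishape <- function(x, ...) {
  cat(x$text, " (level ", x$level, ")\n", sep = "")
  invisible(x)
}

#' Extract hairpin helix indices
#'
#' The function phi: returns the values of the unmarked (hairpin-terminated)
#' helix indices of a hishape. The open chain yields an empty set.
#'
#' @param h A `hishape` (or hishape text, parsed at level `"h"`).
#' @return Numeric vector of unique hairpin helix-index values.
#' @examples
#' extract_hairpin_indices(parse_hishape("[4]"))
#' @export
extract_hairpin_indices <- function(h) {
  if (is.character(h)) h <- parse_hishape(h)
  stopifnot(inherits(h, "hishape"))
  unique(h$phi)
}

#' Strictly negative structures
#'
#' A structure is strictly negative (SN) when every closed substructure whose
#' parent loop is the exterior loop or a multiloop has non-positive free
#' energy (`<= 0` kcal/mol). Filtering the folding space to SN structures
#' removes helices whose formation costs energy, shrinking the space while
#' retaining the thermodynamically sensible conformations.
#'
#' @inheritParams structure_energy
#' @return Logical scalar; the open chain is vacuously strictly negative.
#' @examples
#' is_strictly_negative("GGAAACC", ".......")
#' @export
is_strictly_negative <- function(seq, structure, params = energy_parameters()) {
  sq <- as_rna_sequence(seq)
  s <- validate_structure(structure, seq = sq, nolp = FALSE)
  sn_pt(sq$chars, s$pt, params)
}

sn_pt <- function(chars, pt, params) {
  loops <- pt_loops(pt)
  for (lp in loops) {
    if (lp$kind %in% c("exterior", "multiloop") && !is.null(lp$branches)) {
      for (r in seq_len(nrow(lp$branches))) {
        e <- closed_energy_pt(chars, pt, loops,
                              lp$branches[r, 1], lp$branches[r, 2], params)
        if (e > 1e-12) return(FALSE)
      }
    }
  }
  TRUE
}
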