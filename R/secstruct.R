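#' @useDynLib rnamason, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif setNames uniroot sd
#' @importFrom utils read.table write.table head tail
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

## bracket families, in output precedence order
BRACKET_OPEN  <- c("(", "[", "{", "<", "A", "B", "C", "D")
BRACKET_CLOSE <- c(")", "]", "}", ">", "a", "b", "c", "d")

#' Parse a dot-bracket secondary structure
#'
#' Converts a sequence plus dot-bracket string into a secondary-structure
#' object holding the full base-pair pool. Bracket families `()`, `[]`,
#' `{}`, `<>` and `Aa`--`Dd` are supported, so pseudoknotted structures can
#' be written with multiple families. The returned structure is marked
#' unresolved: all pairs sit in a single pool until
#' [remove_pseudoknots()] classifies them into nested and pseudoknot sets.
#'
#' @param sequence RNA sequence (characters from `A`, `C`, `G`, `U`).
#' @param structure dot-bracket string of the same length.
#' @return an object of class `rna_secstruct` with elements `seq`
#'   (character vector), `pairs` (two-column integer matrix, `i < j`),
#'   `nested`, `pseudoknot` (classified pair matrices) and `resolved`
#'   (logical).
#' @examples
#' ss <- parse_dotbracket("GGAAUC", "((..))")
#' ss$pairs
#' @export
parse_dotbracket <- function(sequence, structure) {
  seq <- toupper(strsplit(gsub("\\s", "", sequence), "")[[1]])
  db <- strsplit(gsub("\\s", "", structure), "")[[1]]
  if (length(seq) < 1L) stop("empty sequence")
  if (length(seq) != length(db)) {
    stop(sprintf("sequence length (%d) does not match structure length (%d)",
                 length(seq), length(db)))
  }
  bad <- which(!seq %in% RNA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("invalid nucleotide code '%s' at position %d", seq[bad[1]], bad[1]))
  }
  pairs <- matrix(integer(0), ncol = 2)
  for (f in seq_along(BRACKET_OPEN)) {
    op <- BRACKET_OPEN[f]; cl <- BRACKET_CLOSE[f]
    stack <- integer(0)
    for (pos in seq_along(db)) {
      ch <- db[pos]
      if (ch == op) {
        stack <- c(stack, pos)
      } else if (ch == cl) {
        if (!length(stack)) {
          stop(sprintf("unbalanced bracket '%s' at position %d", ch, pos))
        }
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (pos - i < 3L) {
          stop(sprintf("pair (%d,%d) violates the minimum hairpin size of 2 unpaired nucleotides", i, pos))
        }
        pairs <- rbind(pairs, c(i, pos))
      }
    }
    if (length(stack)) {
      stop(sprintf("unbalanced bracket '%s' at position %d", op, stack[1]))
    }
  }
  unknown <- setdiff(unique(db), c(".", "-", BRACKET_OPEN, BRACKET_CLOSE))
  if (length(unknown)) {
    stop(sprintf("unknown structure character '%s'", unknown[1]))
  }
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  new_secstruct(seq, pairs, resolved = FALSE)
}

new_secstruct <- function(seq, pairs, nested = NULL, pseudoknot = NULL,
                          resolved = FALSE) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs)) {
    if (anyDuplicated(c(pairs))) stop("a residue appears in more than one base pair")
    if (any(pairs[, 1] >= pairs[, 2])) stop("base pairs must have i < j")
    if (any(pairs < 1L) || any(pairs > length(seq))) stop("base pair index out of range")
  }
  structure(list(
    seq = seq,
    pairs = pairs,
    nested = if (is.null(nested)) as_pair_matrix(NULL) else as_pair_matrix(nested),
    pseudoknot = if (is.null(pseudoknot)) as_pair_matrix(NULL) else as_pair_matrix(pseudoknot),
    resolved = resolved
  ), class = "rna_secstruct")
}

as_pair_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || !length(x)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  m <- matrix(as.integer(x), ncol = 2)
  colnames(m) <- c("i", "j")
  m
}

pairs_cross <- function(p, q) {
  (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
  (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
}

#' Remove pseudoknots, maximizing the number of nested pairs
#'
#' Splits the base-pair pool into a maximum-cardinality crossing-free
#' (nested) subset and the remaining pseudoknot pairs. The optimum is found
#' by an exact interval dynamic program; among equally large solutions the
#' one whose lexicographically smallest removed pair is largest is chosen,
#' which makes the result deterministic. Every removed pair is returned as
#' a flat-bottom tertiary-contact restraint (glycosidic-nitrogen target
#' distance 9 A) so the pseudoknot is still enforced during refinement.
#'
#' @param ss an `rna_secstruct` (resolved or not); its full pair pool
#'   (`pairs`) is used.
#' @return list with `ss` (resolved `rna_secstruct`) and `restraints`
#'   (data frame `i, j, target, flat_width, weight`, one row per removed
#'   pair).
#' @export
remove_pseudoknots <- function(ss) {
  pool <- ss$pairs
  n <- length(ss$seq)
  m <- nrow(pool)
  if (m == 0L) {
    out <- new_secstruct(ss$seq, pool, nested = NULL, pseudoknot = NULL, resolved = TRUE)
    return(list(ss = out, restraints = empty_restraints()))
  }
  ## ranks: pool is sorted lexicographically; tie value prefers keeping
  ## small-rank pairs, which maximizes the smallest removed pair.
  tie_w <- 2^-(seq_len(m))
  ## interval DP over [i, j]: card[i,j] maximum nested pairs inside, tie[i,j]
  ## lexicographic tie value. Pairs indexed by their opening position.
  starts <- split(seq_len(m), pool[, 1])
  card <- matrix(0L, n + 1L, n + 1L)  # card[i, j+1] to allow j = i-1 empty
  tie <- matrix(0, n + 1L, n + 1L)
  for (len in 1:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      bc <- card[i + 1L, j + 1L]; bt <- tie[i + 1L, j + 1L]
      ps <- starts[[as.character(i)]]
      if (!is.null(ps)) {
        for (p in ps) {
          k <- pool[p, 2L]
          if (k <= j) {
            cc <- 1L + card[i + 1L, k] + card[k + 1L, j + 1L]
            tt <- tie_w[p] + tie[i + 1L, k] + tie[k + 1L, j + 1L]
            if (cc > bc || (cc == bc && tt > bt)) { bc <- cc; bt <- tt }
          }
        }
      }
      card[i, j + 1L] <- bc; tie[i, j + 1L] <- bt
    }
  }
  ## traceback
  kept <- logical(m)
  trace <- function(i, j) {
    while (i <= j) {
      bc <- card[i, j + 1L]; bt <- tie[i, j + 1L]
      if (bc == card[i + 1L, j + 1L] && bt == tie[i + 1L, j + 1L]) {
        i <- i + 1L
        next
      }
      ps <- starts[[as.character(i)]]
      done <- FALSE
      for (p in ps) {
        k <- pool[p, 2L]
        if (k <= j) {
          cc <- 1L + card[i + 1L, k] + card[k + 1L, j + 1L]
          tt <- tie_w[p] + tie[i + 1L, k] + tie[k + 1L, j + 1L]
          if (cc == bc && tt == bt) {
            kept[p] <<- TRUE
            trace(i + 1L, k - 1L)
            i <- k + 1L
            done <- TRUE
            break
          }
        }
      }
      if (!done) i <- i + 1L  # defensive; should not happen
    }
  }
  trace(1L, n)
  nested <- pool[kept, , drop = FALSE]
  removed <- pool[!kept, , drop = FALSE]
  out <- new_secstruct(ss$seq, pool, nested = nested, pseudoknot = removed, resolved = TRUE)
  list(ss = out, restraints = pseudoknot_restraints(removed))
}

empty_restraints <- function() {
  data.frame(i = integer(0), j = integer(0), target = numeric(0),
             flat_width = numeric(0), weight = numeric(0))
}

pseudoknot_restraints <- function(pairs) {
  pairs <- as_pair_matrix(pairs)
  data.frame(i = pairs[, 1], j = pairs[, 2],
             target = rep(9.0, nrow(pairs)),
             flat_width = rep(1.0, nrow(pairs)),
             weight = rep(1.0, nrow(pairs)))
}

#' Write a secondary structure back to dot-bracket notation
#'
#' Nested pairs use `()`; pseudoknot pairs are split into crossing-free
#' layers written with `[]`, `{}`, `<>`, `Aa`..`Dd` in order of descending
#' layer size.
#'
#' @param ss a resolved `rna_secstruct`.
#' @return dot-bracket string.
#' @export
write_dotbracket <- function(ss) {
  if (!ss$resolved) stop("secondary structure is unresolved; run remove_pseudoknots() first")
  n <- length(ss$seq)
  db <- rep(".", n)
  put <- function(pairs, fam) {
    db[pairs[, 1]] <<- BRACKET_OPEN[fam]
    db[pairs[, 2]] <<- BRACKET_CLOSE[fam]
  }
  if (nrow(ss$nested)) put(ss$nested, 1L)
  pk <- ss$pseudoknot
  fam <- 2L
  while (nrow(pk)) {
    ## peel off crossing-free layers, largest first
    keep <- logical(nrow(pk))
    layer <- integer(0)
    for (r in seq_len(nrow(pk))) {
      ok <- TRUE
      for (s in layer) if (pairs_cross(pk[r, ], pk[s, ])) { ok <- FALSE; break }
      if (ok) { layer <- c(layer, r); keep[r] <- TRUE }
    }
    if (fam > length(BRACKET_OPEN)) stop("too many pseudoknot layers to encode")
    put(pk[keep, , drop = FALSE], fam)
    pk <- pk[!keep, , drop = FALSE]
    fam <- fam + 1L
  }
  paste(db, collapse = "")
}

#' Write a secondary-structure report
#'
#' Writes the dot-bracket lines plus a TSV of pairs
#' (`i`, `j`, `family`, `class`).
#'
#' @param ss resolved `rna_secstruct`.
#' @param path output file prefix; `<path>.dbn` and `<path>.tsv` are written.
#' @return invisibly, the paths written.
#' @export
write_secstruct_report <- function(ss, path) {
  db <- write_dotbracket(ss)
  dbn <- paste0(path, ".dbn")
  writeLines(c(paste(ss$seq, collapse = ""), db), dbn)
  fam <- strsplit(db, "")[[1]]
  rows <- rbind(
    if (nrow(ss$nested)) data.frame(i = ss$nested[, 1], j = ss$nested[, 2],
                                    family = fam[ss$nested[, 1]], class = "nested"),
    if (nrow(ss$pseudoknot)) data.frame(i = ss$pseudoknot[, 1], j = ss$pseudoknot[, 2],
                                        family = fam[ss$pseudoknot[, 1]], class = "pseudoknot")
  )
  if (is.null(rows)) rows <- data.frame(i = integer(0), j = integer(0),
                                        family = character(0), class = character(0))
  tsv <- paste0(path, ".tsv")
  write.table(rows[order(rows$i), ], tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dbn, tsv))
}
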