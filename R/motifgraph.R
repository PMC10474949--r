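## Motif-graph compilation: stems, loops and single strands as tree nodes,
## edges on shared closing pairs.

#' Decompose a secondary structure into a motif graph
#'
#' Compiles a pseudoknot-free secondary structure into a tree of structural
#' motifs: maximal helices become `stem` nodes; the regions they close
#' become `hairpin_loop`, `internal_loop` or `junction` nodes (which
#' include their closing-pair nucleotides); unpaired 5'/3' tails become
#' `single_strand` nodes. Adjacent motifs share the nucleotides of one
#' closing pair, which defines the graph edges. With no pseudoknots in the
#' nested set the result is always a tree.
#'
#' @param ss a resolved `rna_secstruct` (see [remove_pseudoknots()]); its
#'   `nested` pairs define the topology.
#' @return object of class `rna_motifgraph`: list with `nodes` (list of
#'   motif nodes carrying `kind`, `pairs`, `spacers`, `layout`,
#'   `signature`), `edges` (data frame `a`, `b`, `i`, `j`) and `seq`.
#' @examples
#' ss <- remove_pseudoknots(parse_dotbracket("GGGGAAAACCCC", "((((....))))"))$ss
#' g <- decompose_motifs(ss)
#' vapply(g$nodes, `[[`, "", "signature")
#' @export
decompose_motifs <- function(ss) {
  if (!ss$resolved) stop("secondary structure must be resolved (run remove_pseudoknots)")
  n <- length(ss$seq)
  pairs <- ss$nested
  pt <- integer(n)
  if (nrow(pairs)) {
    pt[pairs[, 1]] <- pairs[, 2]
    pt[pairs[, 2]] <- pairs[, 1]
  }
  nodes <- list()
  add_node <- function(node) {
    node$id <- length(nodes) + 1L
    nodes[[node$id]] <<- node
    node$id
  }
  ## ---- stems: maximal helices
  stems <- list()
  i <- 1L
  while (i <= n) {
    j <- pt[i]
    if (j > i) {
      L <- 1L
      while (pt[i + L] == j - L && (i + L) < (j - L)) L <- L + 1L
      stems[[length(stems) + 1L]] <- list(i = i, j = j, L = L)
      i <- i + L
      ## skip to just past the 5' strand of this helix; inner content handled
      ## when we reach it
    } else {
      i <- i + 1L
    }
  }
  for (s in stems) {
    L <- s$L
    layout <- c(s$i:(s$i + L - 1L), (s$j - L + 1L):s$j)
    prs <- rbind(c(s$i, s$j))
    if (L > 1L) prs <- rbind(prs, c(s$i + L - 1L, s$j - L + 1L))
    add_node(list(kind = "stem", L = L,
                  pairs = as_pair_matrix(prs),
                  spacers = integer(0),
                  strands = list(s$i:(s$i + L - 1L), (s$j - L + 1L):s$j),
                  layout = layout,
                  signature = paste0("stem:", L),
                  open = FALSE))
  }
  ## helper: top-level child outer pairs in (from, to)
  top_children <- function(from, to) {
    kids <- list()
    t <- from
    while (t <= to) {
      if (pt[t] > t) {
        kids[[length(kids) + 1L]] <- c(t, pt[t])
        t <- pt[t] + 1L
      } else t <- t + 1L
    }
    kids
  }
  ## ---- loops closed by each stem's inner pair
  for (s in stems) {
    a <- s$i + s$L - 1L; b <- s$j - s$L + 1L
    kids <- top_children(a + 1L, b - 1L)
    nodes_pairs <- rbind(c(a, b), do.call(rbind, kids))
    k <- nrow(nodes_pairs)
    bounds <- rbind(nodes_pairs, c(b, a))  # cycle: after last child comes entry.j
    spacers <- integer(k)
    layout <- a
    strands <- list()
    cursor <- a
    for (t in seq_len(k)) {
      nxt <- if (t < k) nodes_pairs[t + 1L, 1L] else b
      seg <- if (nxt - cursor > 1L) (cursor + 1L):(nxt - 1L) else integer(0)
      spacers[t] <- length(seg)
      strands[[t]] <- seg
      layout <- c(layout, seg, if (t < k) nodes_pairs[t + 1L, ] else b)
      cursor <- if (t < k) nodes_pairs[t + 1L, 2L] else b
    }
    kind <- if (k == 1L) "hairpin_loop" else if (k == 2L) "internal_loop" else "junction"
    add_node(list(kind = kind,
                  pairs = as_pair_matrix(nodes_pairs),
                  spacers = spacers,
                  strands = strands,
                  layout = layout,
                  signature = loop_signature(kind, spacers),
                  open = FALSE))
  }
  ## ---- exterior region
  kids <- top_children(1L, n)
  nk <- length(kids)
  if (nk == 0L) {
    add_node(list(kind = "single_strand",
                  pairs = as_pair_matrix(NULL),
                  spacers = n,
                  strands = list(1:n),
                  layout = 1:n,
                  signature = paste0("ss:", n),
                  open = FALSE, attach = "none"))
  } else if (nk == 1L) {
    kid <- kids[[1L]]
    if (kid[1] > 1L) {
      strand <- 1:(kid[1] - 1L)
      add_node(list(kind = "single_strand",
                    pairs = as_pair_matrix(rbind(kid)),
                    spacers = length(strand),
                    strands = list(strand),
                    layout = c(strand, kid),
                    signature = paste0("ss:", length(strand)),
                    open = FALSE, attach = "5p"))
    }
    if (kid[2] < n) {
      strand <- (kid[2] + 1L):n
      add_node(list(kind = "single_strand",
                    pairs = as_pair_matrix(rbind(kid)),
                    spacers = length(strand),
                    strands = list(strand),
                    layout = c(kid, strand),
                    signature = paste0("ss:", length(strand)),
                    open = FALSE, attach = "3p"))
    }
  } else {
    ## open exterior junction joining >= 2 top-level helices (tails folded in)
    prs <- do.call(rbind, kids)
    bnd <- c(0L, as.vector(t(prs)), n + 1L)
    spacers <- integer(nk + 1L)
    layout <- integer(0)
    strands <- list()
    cursor <- 0L
    for (t in seq_len(nk)) {
      seg <- if (prs[t, 1] - cursor > 1L) (cursor + 1L):(prs[t, 1] - 1L) else integer(0)
      spacers[t] <- length(seg)
      strands[[t]] <- seg
      layout <- c(layout, seg, prs[t, ])
      cursor <- prs[t, 2]
    }
    seg <- if (n - cursor >= 1L) (cursor + 1L):n else integer(0)
    spacers[nk + 1L] <- length(seg)
    strands[[nk + 1L]] <- seg
    layout <- c(layout, seg)
    add_node(list(kind = "junction",
                  pairs = as_pair_matrix(prs),
                  spacers = spacers,
                  strands = strands,
                  layout = layout,
                  signature = paste0("xjunction:", nk, ":", paste(spacers, collapse = "-")),
                  open = TRUE))
  }
  ## ---- edges on shared closing pairs
  edges <- data.frame(a = integer(0), b = integer(0), i = integer(0), j = integer(0))
  key <- function(p) paste(p[1], p[2])
  stem_ids <- which(vapply(nodes, function(nd) nd$kind == "stem", TRUE))
  stem_pairs <- list()
  for (sid in stem_ids) {
    for (r in seq_len(nrow(nodes[[sid]]$pairs))) {
      stem_pairs[[key(nodes[[sid]]$pairs[r, ])]] <- sid
    }
  }
  for (nid in seq_along(nodes)) {
    nd <- nodes[[nid]]
    if (nd$kind == "stem") next
    if (nrow(nd$pairs)) {
      for (r in seq_len(nrow(nd$pairs))) {
        sid <- stem_pairs[[key(nd$pairs[r, ])]]
        if (!is.null(sid)) {
          edges <- rbind(edges, data.frame(a = sid, b = nid,
                                           i = nd$pairs[r, 1], j = nd$pairs[r, 2]))
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, seq = ss$seq, ss = ss),
            class = "rna_motifgraph")
}

loop_signature <- function(kind, spacers) {
  switch(kind,
    hairpin_loop = paste0("hairpin:", spacers[1]),
    internal_loop = paste0("internal:", spacers[1], "-", spacers[2]),
    junction = paste0("junction:", length(spacers), ":",
                      paste(min_rotation(spacers), collapse = "-")),
    stop("not a loop kind: ", kind))
}

## lexicographically minimal rotation of an integer vector
min_rotation <- function(x) {
  k <- length(x)
  best <- x
  for (r in seq_len(k - 1L)) {
    rot <- c(x[(r + 1L):k], x[1:r])
    for (t in seq_len(k)) {
      if (rot[t] < best[t]) { best <- rot; break }
      if (rot[t] > best[t]) break
    }
  }
  best
}

#' @export
print.rna_motifgraph <- function(x, ...) {
  cat(sprintf("RNA motif graph: %d nt, %d nodes, %d edges\n",
              length(x$seq), length(x$nodes), nrow(x$edges)))
  for (nd in x$nodes) {
    cat(sprintf("  [%d] %-14s %s\n", nd$id, nd$kind, nd$signature))
  }
  invisible(x)
}

## residues covered by the graph (sanity checks / tests)
graph_residues <- function(graph) sort(unique(unlist(lapply(graph$nodes, `[[`, "layout"))))

## connectivity check used by tests and assembly
graph_is_tree <- function(graph) {
  nn <- length(graph$nodes)
  if (nn == 1L) return(nrow(graph$edges) == 0L)
  if (nrow(graph$edges) != nn - 1L) return(FALSE)
  adj <- lapply(seq_len(nn), function(i) integer(0))
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[r]; b <- graph$edges$b[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(nn); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}
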