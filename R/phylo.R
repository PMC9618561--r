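# Jukes-Cantor distances over protein (or nucleotide) strings and
# neighbor-joining tree construction. Trees are ape "phylo" objects;
# to_newick() writes a canonical Newick string (children ordered by their
# smallest contained leaf label) so serialized output is permutation
# invariant.

#' Observed proportion of differing positions (p-distance)
#'
#' Positions where either string carries the missing symbol are deleted
#' pairwise before comparison.
#'
#' @param a,b equal-length character strings.
#' @param missing the gap/missing symbol (default `"-"`).
#' @return proportion of differing comparable positions.
#' @export
#' @examples
#' p_distance("AAAA", "AAAT")  # 0.25
p_distance <- function(a, b, missing = "-") {
  if (nchar(a) != nchar(b))
    bcr_error("p_distance requires equal-length strings", "argument_error")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca != missing & cb != missing
  if (!any(ok))
    bcr_error("no comparable positions after pairwise deletion",
              "argument_error")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Jukes-Cantor distance for alphabet size 4 (nt) or 20 (protein)
#'
#' `d = -((a-1)/a) * log(1 - a*p/(a-1))`. The distance diverges as `p`
#' approaches the saturation bound `(a-1)/a`; saturated pairs raise an
#' error rather than being capped, since a silent cap distorts tree
#' topology.
#'
#' @param p observed difference proportion(s), from [p_distance()].
#' @param alphabet_size 4 (nucleotide) or 20 (protein, the default used for
#'   six-CDR trees).
#' @return Jukes-Cantor corrected distance(s).
#' @export
jc_distance <- function(p, alphabet_size = 20) {
  if (!alphabet_size %in% c(4, 20))
    bcr_error("alphabet_size must be 4 or 20", "argument_error")
  a <- alphabet_size
  if (any(p < 0) || any(p >= (a - 1) / a))
    bcr_error(sprintf("saturated: p must lie in [0, %g)", (a - 1) / a),
              "saturated")
  -((a - 1) / a) * log(1 - a * p / (a - 1))
}

# closed-form inverse of jc_distance (used for round-trip checks)
jc_inverse <- function(d, alphabet_size = 20) {
  a <- alphabet_size
  ((a - 1) / a) * (1 - exp(-a * d / (a - 1)))
}

.quote_label <- function(x) {
  needs <- grepl("[](),:;'[ \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

.fmt_len <- function(x) sprintf("%.12g", max(x, 0) + 0)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined (ties
#' broken by the smallest index pair), branch lengths follow the standard
#' formulas with negative lengths clamped to zero, and joined nodes are
#' replaced by their internal node. The result is an unrooted tree; it
#' reconstructs any additive (tree-metric) matrix exactly.
#'
#' @param D symmetric numeric matrix with zero diagonal; `rownames(D)` are
#'   used as leaf labels (defaults `t1..tn`).
#' @return an [ape] `phylo` tree (unrooted; stored with a trifurcating
#'   root node for n >= 3).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L)
    bcr_error("neighbor joining needs at least 2 taxa", "argument_error")
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0) || any(!is.finite(D)))
    bcr_error("D must be symmetric, finite, with zero diagonal",
              "argument_error")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  # assemble with placeholder leaf names, restore real labels on the phylo
  # (keeps Newick metacharacters in labels out of the parser)
  frags <- sprintf("leaf%06d", seq_len(n))
  restore <- function(tr) {
    tr$tip.label <- labels[match(tr$tip.label, sprintf("leaf%06d", seq_len(n)))]
    tr
  }
  if (n == 2L) {
    h <- D[1, 2] / 2
    txt <- sprintf("(%s:%s,%s:%s);", frags[1], .fmt_len(h),
                   frags[2], .fmt_len(h))
    return(restore(ape::read.tree(text = txt)))
  }
  act <- seq_len(n)
  while (length(act) > 3L) {
    m <- length(act)
    d <- D[act, act]
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- d[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[act[i]], .fmt_len(bi),
                        frags[act[j]], .fmt_len(bj))
    # distances from the new node u to every remaining k
    du <- (d[i, ] + d[j, ] - dij) / 2
    u <- act[i]
    D[u, act] <- du; D[act, u] <- du; D[u, u] <- 0
    frags[u] <- new_frag
    act <- act[-j]
  }
  d <- D[act, act]
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frags[act[1]], .fmt_len(b1),
                 frags[act[2]], .fmt_len(b2),
                 frags[act[3]], .fmt_len(b3))
  restore(ape::read.tree(text = txt))
}

#' Serialize a tree as canonical Newick
#'
#' Standard Newick with branch lengths. The serialization is canonical for
#' the *unrooted* tree: output is anchored at the internal node adjacent to
#' the lexicographically smallest leaf label, and the children of every
#' node are emitted in order of their smallest contained leaf label, so
#' isomorphic trees (e.g. built from a permuted distance matrix) serialize
#' identically regardless of how ape happens to store them. Labels
#' containing Newick metacharacters are single-quoted.
#'
#' @param t an ape `phylo` tree with edge lengths.
#' @return a single Newick string (terminated by `;`).
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "phylo"))
  n_tip <- length(t$tip.label)
  lens <- t$edge.length %||% rep(0, nrow(t$edge))
  # undirected adjacency: node -> (neighbor, edge index)
  n_nodes <- max(t$edge)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(t$edge))) {
    a <- t$edge[e, 1]; b <- t$edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  emit <- function(node, parent) {
    if (node <= n_tip)
      return(list(txt = .quote_label(t$tip.label[node]),
                  min_leaf = t$tip.label[node]))
    nb <- adj[[node]]
    sub <- list()
    for (r in seq_len(nrow(nb))) {
      if (nb[r, 1] == parent) next
      res <- emit(nb[r, 1], node)
      res$txt <- paste0(res$txt, ":",
                        sprintf("%.10g", max(lens[nb[r, 2]], 0) + 0))
      sub[[length(sub) + 1L]] <- res
    }
    ord <- order(vapply(sub, `[[`, character(1), "min_leaf"))
    sub <- sub[ord]
    list(txt = paste0("(", paste(vapply(sub, `[[`, character(1), "txt"),
                                 collapse = ","), ")"),
         min_leaf = sub[[1]]$min_leaf)
  }
  if (n_tip == 1L) return(paste0(.quote_label(t$tip.label[1]), ";"))
  min_tip <- order(t$tip.label)[1L]
  anchor <- adj[[min_tip]][1, 1]
  if (anchor <= n_tip) {  # two-leaf tree: single edge
    l <- sum(lens)
    labs <- .quote_label(t$tip.label)
    ord <- order(t$tip.label)
    return(sprintf("(%s:%s,%s:%s);", labs[ord[1]],
                   sprintf("%.10g", l / 2), labs[ord[2]],
                   sprintf("%.10g", l / 2)))
  }
  paste0(emit(anchor, 0L)$txt, ";")
}

# splits (bipartitions) of an unrooted phylo, each canonicalized as a
# sorted leaf-label string of the side not containing the first label
tree_splits <- function(t) {
  n_tip <- length(t$tip.label)
  desc <- function(node, acc) {
    if (node <= n_tip) return(node)
    kids <- t$edge[t$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  out <- character(0)
  for (e in seq_len(nrow(t$edge))) {
    child <- t$edge[e, 2]
    if (child <= n_tip) next  # trivial split
    side <- sort(t$tip.label[desc(child)])
    if (t$tip.label[1] %in% side)
      side <- sort(setdiff(t$tip.label, side))
    if (length(side) < 2 || length(side) > n_tip - 2) next
    out <- c(out, paste(side, collapse = "|"))
  }
  sort(unique(out))
}

# pad region strings to a common width with the missing symbol and
# concatenate the six CDRs per record
.concat_padded_cdrs <- function(ann) {
  cols <- c(paste0("vh_", c("cdr1", "cdr2", "cdr3")),
            paste0("vk_", c("cdr1", "cdr2", "cdr3")))
  pieces <- lapply(cols, function(cl) {
    x <- ann[[cl]]
    w <- max(nchar(x))
    paste0(x, strrep("-", w - nchar(x)))
  })
  do.call(paste0, pieces)
}

#' Six-CDR Jukes-Cantor neighbor-joining tree of a repertoire
#'
#' Concatenates heavy CDR1-3 and kappa CDR1-3 amino-acid strings of every
#' annotated record (each region right-padded with `-` to its repertoire-
#' wide maximum length, so unequal CDR3 lengths align without a full MSA),
#' computes p-distances with pairwise deletion, applies the protein
#' (alphabet 20) Jukes-Cantor correction and builds a neighbor-joining
#' tree. Saturated pairs abort with an error.
#'
#' @param rep an annotated repertoire with >= 2 annotated records.
#' @return an ape `phylo` tree with cell ids as leaf labels.
#' @export
cdr_tree <- function(rep) {
  ann <- .annotated(rep)
  if (nrow(ann) < 2L)
    bcr_error("cdr_tree needs >= 2 annotated records", "argument_error")
  seqs <- .concat_padded_cdrs(ann)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ann$cell_id, ann$cell_id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- jc_distance(p_distance(seqs[i], seqs[j]), 20)
    D[i, j] <- d; D[j, i] <- d
  }
  neighbor_joining(D)
}

#' Write a distance matrix as square PHYLIP-style text
#'
#' @param D labelled square matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(D, path) {
  con <- textConnection(NULL, "w", local = TRUE)
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(format(rownames(D)[i], width = 10),
                       sprintf("%.8f", D[i, ])), collapse = "  "), con)
  txt <- textConnectionValue(con)
  close(con)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(txt, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    bcr_error(sprintf("could not write '%s'", path), "io_error")
  }
  invisible(path)
}
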