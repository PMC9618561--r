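# Shared fixtures and independent oracles, all built in code.

# one cached small reference reused across tests (generation is seeded)
ref9x8 <- generate_germline_reference(9, 8, seed = 101)

# a minimal hand-built annotated repertoire: one row per record with the
# region strings given; everything else is filled with plausible defaults
fake_repertoire <- function(vh_regions, vk_regions = NULL, label = "fake",
                            vh_family = NULL, vk_family = NULL) {
  n <- nrow(vh_regions)
  if (is.null(vk_regions))
    vk_regions <- data.frame(fr1 = "M", cdr1 = "K", fr2 = "L", cdr2 = "Q",
                             fr3 = "V", cdr3 = "W",
                             stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  ids <- sprintf("F%03d", seq_len(n))
  ann <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
  for (r in names(vh_regions)) ann[[paste0("vh_", r)]] <- vh_regions[[r]]
  for (r in names(vk_regions)) ann[[paste0("vk_", r)]] <- vk_regions[[r]]
  ann$vh_call <- rep("HV1-1", n); ann$vk_call <- rep("KV1-1", n)
  ann$vh_family <- rep(if (is.null(vh_family)) "HV1" else vh_family,
                       length.out = n)
  ann$vk_family <- rep(if (is.null(vk_family)) "KV1" else vk_family,
                       length.out = n)
  ann$vh_identity <- rep(1, n); ann$vk_identity <- rep(1, n)
  ann$productive <- rep(TRUE, n); ann$annotated <- rep(TRUE, n)
  ann$failure_reason <- rep(NA_character_, n)
  structure(list(
    records = data.frame(cell_id = ids, compartment = rep("input", n),
                         pairing_origin = rep("cognate", n),
                         stringsAsFactors = FALSE),
    annotation = ann, label = label,
    provenance = list(n_failed = 0L, reference_genes = NA_integer_)
  ), class = "repertoire")
}

# a fully synthetic annotated repertoire (specific cells only)
synthetic_annotated <- function(n = 30, n_lineages = 3, seed = 1,
                                shm_cdr = 0.01, shm_fr = 0.002,
                                ref = ref9x8) {
  cfg <- sim_config(n_cells = n, antigen_specific_fraction = 1,
                    n_founder_lineages = n_lineages,
                    shm_rate_cdr = shm_cdr, shm_rate_fr = shm_fr,
                    seed = seed)
  pool <- simulate_immune_response(ref, cfg)
  suppressMessages(annotate_repertoire(pool, ref, label = paste0("syn", seed)))
}

# quick hand-made B-cell record table (no sequences needed)
fake_records <- function(n, n_specific, igg = TRUE) {
  data.frame(
    cell_id = sprintf("R%04d", seq_len(n)),
    vh_nt = "A", vk_nt = "A",
    lineage_id = c(rep("L01", n_specific), rep(NA, n - n_specific)),
    is_antigen_specific = c(rep(TRUE, n_specific), rep(FALSE, n - n_specific)),
    vh_specific = c(rep(TRUE, n_specific), rep(FALSE, n - n_specific)),
    vk_specific = c(rep(TRUE, n_specific), rep(FALSE, n - n_specific)),
    vh_gene = "HV1-1", vk_gene = "KV1-1",
    isotype = if (igg) "IgG" else "IgM/IgD",
    compartment = "input", pairing_origin = "cognate",
    stringsAsFactors = FALSE
  )
}

# ---- brute-force tree oracles -------------------------------------------

# enumerate all unrooted binary topologies on leaves 1..n as edge matrices
# (leaf ids 1..n, internal ids n+1, n+2, ...)
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                 ncol = 2, byrow = TRUE)
  tops <- list(list(edges = base, next_id = n + 2L))
  if (n > 3) for (leaf in 4:n) {
    nxt <- list()
    for (tp in tops) {
      for (e in seq_len(nrow(tp$edges))) {
        ed <- tp$edges
        a <- ed[e, 1]; b <- ed[e, 2]
        m <- tp$next_id
        ed <- rbind(ed[-e, , drop = FALSE],
                    c(a, m), c(m, b), c(m, leaf))
        nxt[[length(nxt) + 1L]] <- list(edges = ed, next_id = m + 1L)
      }
    }
    tops <- nxt
  }
  lapply(tops, `[[`, "edges")
}

# indicator matrix: rows = leaf pairs (i<j), cols = edges; 1 if edge on path
path_design_matrix <- function(edges, n) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
    adj[[a]] <- c(adj[[a]], e); adj[[b]] <- c(adj[[b]], e)
  }
  # for each edge, leaves on the child side (component of edges[e,2] when
  # edge e is removed)
  side <- matrix(FALSE, nrow = nrow(edges), ncol = n)
  for (e in seq_len(nrow(edges))) {
    seen <- c()
    stack <- edges[e, 2]
    blocked <- e
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      seen <- c(seen, v)
      for (e2 in adj[[as.character(v)]]) {
        if (e2 %in% blocked) next
        w <- setdiff(edges[e2, ], v)
        if (!(w %in% seen)) { stack <- c(stack, w); blocked <- c(blocked, e2) }
      }
    }
    side[e, ] <- seq_len(n) %in% seen
  }
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow = nrow(pairs), ncol = nrow(edges))
  for (r in seq_len(nrow(pairs)))
    A[r, ] <- as.numeric(xor(side[, pairs[r, 1]], side[, pairs[r, 2]]))
  A
}

# distances vector aligned with path_design_matrix pair order (combn order)
pair_dist_vector <- function(D) {
  n <- nrow(D)
  pairs <- t(utils::combn(n, 2))
  D[cbind(pairs[, 1], pairs[, 2])]
}

topology_residual <- function(edges, D) {
  A <- path_design_matrix(edges, nrow(D))
  d <- pair_dist_vector(D)
  b <- qr.coef(qr(A), d)
  b[is.na(b)] <- 0
  sqrt(sum((A %*% b - d)^2))
}

# edge matrix -> ape phylo (topology only), labels t1..tn
edges_to_phylo <- function(edges, n) {
  labs <- paste0("t", seq_len(n))
  frag <- as.list(labs)
  # iteratively collapse: root at internal node with smallest id
  # build children map from edges, rooted at n+1
  build <- function(node, parent) {
    kids <- c(edges[edges[, 1] == node & edges[, 2] != parent, 2],
              edges[edges[, 2] == node & edges[, 1] != parent, 1])
    if (node <= n) return(labs[node])
    paste0("(", paste(vapply(kids, build, character(1), parent = node),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(n + 1L, -1L), ";"))
}

# random additive (tree-metric) distance matrix with its generating tree
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tops <- NULL
  # grow one random topology by random edge insertion
  edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE)
  next_id <- n + 2L
  if (n > 3) for (leaf in 4:n) {
    e <- sample(nrow(edges), 1)
    a <- edges[e, 1]; b <- edges[e, 2]
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(a, next_id), c(next_id, b), c(next_id, leaf))
    next_id <- next_id + 1L
  }
  lens <- stats::runif(nrow(edges), 0.1, 1)
  A <- path_design_matrix(edges, n)
  dv <- as.vector(A %*% lens)
  D <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  pairs <- t(utils::combn(n, 2))
  D[cbind(pairs[, 1], pairs[, 2])] <- dv
  D[cbind(pairs[, 2], pairs[, 1])] <- dv
  list(D = D, edges = edges, lengths = lens)
}

# brute-force Mann-Whitney two-sided exact p by enumerating all
# assignments of the pooled sample to group labels
mw_exact_p_bruteforce <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  min(1, p)
}
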