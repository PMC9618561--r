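# Germline V-gene assignment, FR/CDR delineation and AIRR-style export.
#
# Assignment aligns every reference gene of the requested chain against the
# query (germline global, query end gaps free) and keeps the best-scoring
# gene; region boundaries are then projected from the assigned gene through
# the alignment, and CDR3 runs from the end of FR3 to the first occurrence
# of the gene's anchor motif in the translated query.

.ALN_SCORING <- list(match = 1, mismatch = -1, gap_open = 4, gap_ext = 1)

.aln_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(
    match = .ALN_SCORING$match, mismatch = .ALN_SCORING$mismatch,
    baseOnly = FALSE)
}

# Align many queries against every gene of one chain with a single
# vectorized alignment call per gene (queries local, gene global: the
# germline spans end-to-end, query end gaps are free). Returns one
# `germline_assignment` per query, or NULL where no gene clears identity
# 0.5 / the query is shorter than 60 nt.
.batch_assign <- function(seqs, ref, chain) {
  g <- ref$genes[ref$genes$chain == chain, , drop = FALSE]
  g <- g[order(g$name), , drop = FALSE]  # ties -> smallest name wins below
  mat <- .aln_submat()
  qset <- Biostrings::DNAStringSet(seqs)
  nq <- length(seqs)
  alns <- vector("list", nrow(g))
  scores <- matrix(-Inf, nrow = nrow(g), ncol = nq)
  for (gi in seq_len(nrow(g))) {
    alns[[gi]] <- Biostrings::pairwiseAlignment(
      pattern = qset, subject = Biostrings::DNAString(g$nt_sequence[gi]),
      type = "local-global", substitutionMatrix = mat,
      gapOpening = .ALN_SCORING$gap_open, gapExtension = .ALN_SCORING$gap_ext)
    scores[gi, ] <- Biostrings::score(alns[[gi]])
  }
  # first max = lexicographically smallest gene name (genes are sorted)
  best <- apply(scores, 2L, which.max)
  pids <- numeric(nq)
  ref_gapped <- query_gapped <- rep(NA_character_, nq)
  qstart <- integer(nq)
  for (gi in unique(best)) {
    idx <- which(best == gi)
    sub <- alns[[gi]][idx]
    pids[idx] <- Biostrings::pid(sub, type = "PID1")
    qstart[idx] <- Biostrings::start(Biostrings::pattern(sub))
    # gapped strings are only needed when the alignment has indels; the
    # ungapped case maps reference to query by a plain offset
    ind <- Biostrings::nindel(sub)
    gapped <- which(Biostrings::insertion(ind)[, "Length"] +
                    Biostrings::deletion(ind)[, "Length"] > 0L)
    for (w in gapped) {
      one <- sub[w]
      ref_gapped[idx[w]] <- as.character(Biostrings::alignedSubject(one))
      query_gapped[idx[w]] <- as.character(Biostrings::alignedPattern(one))
    }
  }
  lapply(seq_len(nq), function(q) {
    identity <- pids[q] / 100
    if (nchar(seqs[q]) < 60L || identity <= 0.5) return(NULL)
    structure(list(
      gene_name = g$name[best[q]], family = g$family[best[q]], chain = chain,
      score = scores[best[q], q], identity = identity,
      alignment = list(
        ref_gapped = ref_gapped[q],
        query_gapped = query_gapped[q],
        query_start = qstart[q],
        ref_length = nchar(g$nt_sequence[best[q]])
      )
    ), class = "germline_assignment")
  })
}

#' Assign the best-matching germline V gene to a nucleotide sequence
#'
#' Performs a Needleman-Wunsch-style alignment of every reference gene of
#' the given chain against `seq` (the germline aligned end-to-end, query end
#' gaps free; match +1, mismatch -1, gap open -4, gap extend -1) and returns
#' the gene with the maximal score. Ties are broken by the lexicographically
#' smallest gene name. Identity is the fraction of identical positions over
#' the aligned germline span.
#'
#' @param seq query nucleotide string (>= 60 nt).
#' @param ref a `germline_reference`.
#' @param chain `"heavy"` or `"kappa"`.
#' @return an object of class `germline_assignment`: list with `gene_name`,
#'   `family`, `score`, `identity`, `chain` and the pairwise `alignment`
#'   (gapped germline/query strings plus query start offset).
#' @export
assign_germline <- function(seq, ref, chain = c("heavy", "kappa")) {
  chain <- match.arg(chain)
  stopifnot(inherits(ref, "germline_reference"))
  if (nchar(seq) < 60L)
    bcr_error("query shorter than 60 nt", "argument_error")
  asg <- .batch_assign(seq, ref, chain)[[1L]]
  if (is.null(asg))
    bcr_error(sprintf("no germline %s gene exceeds identity 0.5", chain),
              "unassignable")
  asg
}

#' @export
print.germline_assignment <- function(x, ...) {
  cat(sprintf("V-gene assignment: %s (%s, %s chain), score %d, identity %.3f\n",
              x$gene_name, x$family, x$chain, x$score, x$identity))
  invisible(x)
}

# map reference positions (1-based) to query positions through the gapped
# alignment; returns NA where the reference position aligns to a gap
.ref_to_query_map <- function(aln) {
  if (is.na(aln$ref_gapped))  # ungapped alignment: plain offset
    return(seq_len(aln$ref_length) + aln$query_start - 1L)
  rg <- strsplit(aln$ref_gapped, "")[[1]]
  qg <- strsplit(aln$query_gapped, "")[[1]]
  rpos <- cumsum(rg != "-")
  qpos <- cumsum(qg != "-") + aln$query_start - 1L
  map <- rep(NA_integer_, max(rpos))
  ok <- rg != "-" & qg != "-"
  map[rpos[ok]] <- qpos[ok]
  map
}

#' Delineate FR1-FR3, CDR1-CDR2 and CDR3 on a query sequence
#'
#' FR and CDR boundaries of the assigned germline gene are projected onto
#' the query through the alignment; each projected interval is translated in
#' the frame fixed by the alignment start. CDR3 is the translated segment
#' from the end of FR3 up to (excluding) the first occurrence of the gene's
#' anchor motif.
#'
#' @param seq query nucleotide string.
#' @param asg a [assign_germline()] result for `seq`.
#' @param ref the `germline_reference` used for assignment.
#' @return an object of class `region_set`: list with amino-acid strings
#'   `fr1`, `cdr1`, `fr2`, `cdr2`, `fr3`, `cdr3` and `intervals`, the
#'   corresponding 0-based half-open nt intervals on the query.
#' @export
delineate_regions <- function(seq, asg, ref) {
  stopifnot(inherits(asg, "germline_assignment"))
  bnd <- gene_boundaries(ref, asg$gene_name)
  map <- .ref_to_query_map(asg$alignment)
  regions <- rownames(bnd)
  aa <- stats::setNames(vector("list", length(regions) + 1L),
                        c(regions, "cdr3"))
  iv <- matrix(NA_integer_, nrow = length(regions) + 1L, ncol = 2L,
               dimnames = list(c(regions, "cdr3"), c("start", "end")))
  for (r in regions) {
    # reference interval [start, end) in 0-based -> 1-based positions
    rs <- bnd[r, "start"] + 1L; re <- bnd[r, "end"]
    qs <- map[rs]; qe <- map[re]
    if (is.na(qs) || is.na(qe))
      bcr_error(sprintf("region %s boundary falls in an alignment gap", r),
                "frameshift")
    if ((qe - qs + 1L) %% 3L != 0L)
      bcr_error(sprintf("frameshift in projected region %s", r), "frameshift")
    aa[[r]] <- translate_nt(substr(seq, qs, qe))
    iv[r, ] <- c(qs - 1L, qe)
  }
  # CDR3: translate the tail after FR3, cut at the anchor motif
  gene <- ref$genes[ref$genes$name == asg$gene_name, ]
  tail_start <- iv["fr3", "end"] + 1L
  tail_nt <- substr(seq, tail_start, nchar(seq))
  tail_aa <- translate_nt(tail_nt)
  hit <- regexpr(gene$anchor_motif, tail_aa, fixed = TRUE)
  if (hit < 1L)
    bcr_error(sprintf("anchor motif %s not found after FR3", gene$anchor_motif),
              "cdr3_undefined")
  if (hit == 1L)
    bcr_error("empty CDR3 (anchor motif abuts FR3)", "cdr3_undefined")
  aa$cdr3 <- substr(tail_aa, 1L, hit - 1L)
  iv["cdr3", ] <- c(tail_start - 1L, tail_start - 1L + 3L * (hit - 1L))
  structure(c(aa, list(intervals = iv)), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  for (r in c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3"))
    cat(sprintf("%5s [%4d,%4d) %s\n", r,
                x$intervals[r, 1], x$intervals[r, 2], x[[r]]))
  invisible(x)
}


#' Annotate a set of B-cell records against a germline reference
#'
#' Assigns heavy and kappa V genes and region sets for every record.
#' Records failing annotation (unassignable gene, missing anchor motif,
#' frameshift) are retained with `annotated = FALSE` and a failure reason,
#' and are excluded from downstream diversity analyses; the failure count
#' is reported via `message()`.
#'
#' @param records B-cell records (needs `cell_id`, `vh_nt`, `vk_nt`).
#' @param ref a `germline_reference`.
#' @param label repertoire label carried into outputs.
#' @return an object of class `repertoire`: list with `records`, the
#'   per-cell `annotation` data.frame (wide: `vh_call`, `vh_family`,
#'   `vh_identity`, `vh_fr1` ... `vh_cdr3`, same for `vk_*`, `productive`,
#'   `annotated`, `failure_reason`), `label`, and `provenance`.
#' @export
annotate_repertoire <- function(records, ref, label = "repertoire") {
  stopifnot(inherits(ref, "germline_reference"))
  n <- nrow(records)
  regs <- c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3")
  cols <- c("cell_id",
            paste0("vh_", c("call", "family", "identity", regs)),
            paste0("vk_", c("call", "family", "identity", regs)),
            "productive", "annotated", "failure_reason")
  ann <- as.data.frame(matrix(NA, nrow = n, ncol = length(cols)),
                       stringsAsFactors = FALSE)
  names(ann) <- cols
  ann$cell_id <- records$cell_id
  ann$annotated <- FALSE
  asg_h <- .batch_assign(records$vh_nt, ref, "heavy")
  asg_k <- .batch_assign(records$vk_nt, ref, "kappa")
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (is.null(asg_h[[i]]))
        bcr_error("heavy chain unassignable", "unassignable")
      if (is.null(asg_k[[i]]))
        bcr_error("kappa chain unassignable", "unassignable")
      h <- list(asg = asg_h[[i]],
                rs = delineate_regions(records$vh_nt[i], asg_h[[i]], ref))
      k <- list(asg = asg_k[[i]],
                rs = delineate_regions(records$vk_nt[i], asg_k[[i]], ref))
      list(h = h, k = k, err = NULL)
    }, bcr_error = function(e) list(err = conditionMessage(e)))
    if (is.null(res$err)) {
      for (ch in c("h", "k")) {
        p <- paste0("v", ch, "_")
        ann[i, paste0(p, "call")] <- res[[ch]]$asg$gene_name
        ann[i, paste0(p, "family")] <- res[[ch]]$asg$family
        ann[i, paste0(p, "identity")] <- res[[ch]]$asg$identity
        for (r in regs) ann[i, paste0(p, r)] <- res[[ch]]$rs[[r]]
      }
      full_aa <- c(unlist(ann[i, paste0("vh_", regs)]),
                   unlist(ann[i, paste0("vk_", regs)]))
      ann$productive[i] <- !any(grepl("*", full_aa, fixed = TRUE))
      ann$annotated[i] <- TRUE
    } else {
      ann$failure_reason[i] <- res$err
    }
  }
  n_fail <- sum(!ann$annotated)
  if (n_fail > 0)
    message(sprintf("annotate_repertoire: %d of %d records failed annotation",
                    n_fail, n))
  structure(list(
    records = records, annotation = ann, label = label,
    provenance = list(n_failed = n_fail,
                      reference_genes = nrow(ref$genes))
  ), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("Repertoire '%s': %d records, %d annotated (%d failed)\n",
              x$label, nrow(x$records), sum(x$annotation$annotated),
              x$provenance$n_failed))
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) {
  ann <- object$annotation[object$annotation$annotated, , drop = FALSE]
  out <- list(
    label = object$label,
    n_records = nrow(object$records),
    n_annotated = nrow(ann),
    n_failed = object$provenance$n_failed,
    vh_family_usage = if (nrow(ann)) table(ann$vh_family) else table(character()),
    vk_family_usage = if (nrow(ann)) table(ann$vk_family) else table(character())
  )
  class(out) <- "summary.repertoire"
  out
}

#' @export
print.summary.repertoire <- function(x, ...) {
  cat(sprintf("Repertoire '%s': %d records, %d annotated, %d failed\n",
              x$label, x$n_records, x$n_annotated, x$n_failed))
  cat("VH family usage:\n"); print(x$vh_family_usage)
  cat("VK family usage:\n"); print(x$vk_family_usage)
  invisible(x)
}

#' Export a repertoire as an AIRR-style rearrangement table
#'
#' One row per chain per annotated cell, with `sequence_id`, `chain`
#' (`heavy`/`kappa`), `v_call`, `v_family`, `v_identity`, amino-acid
#' `fr1`...`fr3` and `cdr1`...`cdr3`, a `productive` flag, and source
#' labels (`compartment`, `pairing_origin`). Records that failed annotation
#' are omitted (their count is in the repertoire's provenance).
#'
#' @param rep a [annotate_repertoire()] result.
#' @return a data.frame in long AIRR-style layout.
#' @export
as_airr <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  ann <- rep$annotation[rep$annotation$annotated, , drop = FALSE]
  rec <- rep$records[match(ann$cell_id, rep$records$cell_id), , drop = FALSE]
  regs <- c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3")
  one_chain <- function(p, chain) {
    df <- data.frame(
      sequence_id = paste0(ann$cell_id, "_", chain),
      cell_id = ann$cell_id, chain = chain,
      v_call = ann[[paste0(p, "call")]],
      v_family = ann[[paste0(p, "family")]],
      v_identity = ann[[paste0(p, "identity")]],
      stringsAsFactors = FALSE
    )
    for (r in regs) df[[r]] <- ann[[paste0(p, r)]]
    df$productive <- ann$productive
    df$compartment <- rec$compartment
    df$pairing_origin <- rec$pairing_origin
    df
  }
  out <- rbind(one_chain("vh_", "heavy"), one_chain("vk_", "kappa"))
  out[order(out$cell_id, out$chain), , drop = FALSE]
}
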