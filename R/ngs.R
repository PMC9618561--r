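# NGS VH-repertoire analysis: exact-match read collapsing with a
# minimum-observation filter, unique-sequence counting, and gene-family
# frequency comparison between pools.

#' Collapse reads by exact match and filter by minimum observation count
#'
#' Reads shorter than 60 nt are dropped before collapsing (too short to be
#' a V amplicon) and their count is logged. Distinct sequences observed
#' fewer than `min_count` times are removed: a plain count filter is the
#' whole denoising step (no clustering, no UMIs), so singleton sequencing
#' errors disappear at the default `min_count = 2`.
#'
#' @param reads character vector of nucleotide reads.
#' @param min_count minimum observations for a sequence to be retained
#'   (>= 1).
#' @param pool_label label carried into outputs.
#' @return an object of class `collapsed_set`: list with `entries` (named
#'   integer vector: sequence -> count), `pool_label`, and a `removed`
#'   accounting list (`short_reads`, `low_count_sequences`,
#'   `low_count_reads`, `total_input_reads`).
#' @export
collapse_reads <- function(reads, min_count = 2L, pool_label = "pool") {
  if (min_count < 1L)
    bcr_error("min_count must be >= 1", "argument_error")
  total <- length(reads)
  short <- nchar(reads) < 60L
  if (any(short))
    message(sprintf("collapse_reads: dropped %d reads shorter than 60 nt",
                    sum(short)))
  reads <- reads[!short]
  tab <- table(reads)
  keep <- tab >= min_count
  entries <- stats::setNames(as.integer(tab[keep]), names(tab[keep]))
  structure(list(
    entries = entries, pool_label = pool_label, min_count = as.integer(min_count),
    removed = list(short_reads = sum(short),
                   low_count_sequences = sum(!keep),
                   low_count_reads = sum(tab[!keep]),
                   total_input_reads = total)
  ), class = "collapsed_set")
}

#' @export
print.collapsed_set <- function(x, ...) {
  cat(sprintf("Collapsed set '%s': %d unique sequences (>=%dx), %d/%d reads retained\n",
              x$pool_label, length(x$entries), x$min_count,
              sum(x$entries), x$removed$total_input_reads))
  invisible(x)
}

#' Number of unique sequences retained after collapsing
#'
#' @param cs a [collapse_reads()] result.
#' @return integer count of retained unique sequences.
#' @export
unique_vh_count <- function(cs) {
  stopifnot(inherits(cs, "collapsed_set"))
  length(cs$entries)
}

#' Gene-family frequency table of a collapsed read set
#'
#' Assigns every retained unique sequence to a germline V gene with
#' [assign_germline()] and tabulates unique-sequence counts per family.
#' Unassignable sequences are tallied separately, never silently dropped.
#'
#' @param cs a [collapse_reads()] result.
#' @param ref a `germline_reference`.
#' @param chain chain of the pool (default heavy).
#' @return data.frame with columns `family` and `n_unique`; attribute
#'   `unassignable` holds the count of sequences no gene matched.
#' @export
family_frequency_table <- function(cs, ref, chain = "heavy") {
  seqs <- names(cs$entries)
  asg <- if (length(seqs)) .batch_assign(seqs, ref, chain) else list()
  fam <- vapply(asg, function(a) if (is.null(a)) NA_character_ else a$family,
                character(1))
  n_un <- sum(is.na(fam))
  tab <- table(fam[!is.na(fam)])
  out <- data.frame(family = names(tab), n_unique = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassignable") <- n_un
  attr(out, "pool_label") <- cs$pool_label
  out
}

#' Join two family tables and flag exclusive families
#'
#' Full outer join on `family`, with per-pool unique-sequence counts and a
#' presence flag (`A_only`, `B_only`, `both`).
#'
#' @param tA,tB [family_frequency_table()] results.
#' @return data.frame with columns `family`, `n_unique_A`, `n_unique_B`,
#'   `presence`.
#' @export
compare_family_tables <- function(tA, tB) {
  m <- merge(tA, tB, by = "family", all = TRUE,
             suffixes = c("_A", "_B"))
  m$n_unique_A[is.na(m$n_unique_A)] <- 0L
  m$n_unique_B[is.na(m$n_unique_B)] <- 0L
  m$presence <- ifelse(m$n_unique_A > 0 & m$n_unique_B > 0, "both",
                       ifelse(m$n_unique_A > 0, "A_only", "B_only"))
  m[order(m$family), , drop = FALSE]
}

#' Simulate an NGS read pool from a set of template sequences
#'
#' Emits every template `depth` times plus `n_noise` singleton error reads,
#' each a one-substitution copy of a random template, guaranteed distinct
#' from all templates and from the other noise reads. With `depth >= 2`,
#' collapsing at `min_count = 2` recovers exactly the template set.
#'
#' @param templates character vector of template nt sequences.
#' @param depth reads per template (>= 1).
#' @param n_noise number of singleton error reads.
#' @param seed integer seed.
#' @return character vector of reads, shuffled.
#' @export
simulate_ngs_reads <- function(templates, depth = 3L, n_noise = 0L, seed = 1L) {
  stopifnot(depth >= 1L, n_noise >= 0L, length(templates) >= 1L)
  with_seed(seed, {
    reads <- rep(templates, each = depth)
    noise <- character(0)
    bases <- c("A", "C", "G", "T")
    guard <- 0L
    while (length(noise) < n_noise && guard < 50L * n_noise + 100L) {
      guard <- guard + 1L
      s <- sample(templates, 1L)
      p <- sample(nchar(s), 1L)
      substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1L)
      if (!(s %in% templates) && !(s %in% noise)) noise <- c(noise, s)
    }
    sample(c(reads, noise))
  })
}
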