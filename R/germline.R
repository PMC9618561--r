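# Synthetic germline V-gene references.
#
# Genes are generated by divergence from a per-chain ancestral scaffold:
# families diverge from the ancestor, genes diverge from their family
# consensus. All substitutions swap whole codons among the 61 sense codons,
# so every gene translates without stops and region boundaries (codon
# multiples) are preserved. Heavy and kappa chains carry a J-segment
# surrogate: a fixed amino-acid anchor motif that terminates CDR3 during
# annotation.

# region lengths in codons: FR1, CDR1, FR2, CDR2, FR3
.REGION_CODONS <- c(fr1 = 25L, cdr1 = 8L, fr2 = 17L, cdr2 = 8L, fr3 = 38L)
.REGIONS_V <- names(.REGION_CODONS)

.ANCHORS <- list(
  heavy = list(aa = "WGQG", nt = "TGGGGTCAAGGT"),
  kappa = list(aa = "FGQG", nt = "TTTGGTCAAGGT")
)

.FAMILY_POOL <- list(heavy = paste0("HV", 1:4), kappa = paste0("KV", 1:3))

# substitute a fraction of codons with random sense codons
.diverge <- function(codons, frac, sense) {
  k <- max(1L, round(frac * length(codons)))
  pos <- sample(length(codons), k)
  codons[pos] <- sample(sense, k, replace = TRUE)
  codons
}

#' Generate a synthetic annotated germline V-gene reference
#'
#' Builds `n_vh` heavy and `n_vk` kappa germline V genes with known
#' FR1/CDR1/FR2/CDR2/FR3 boundaries (0-based, half-open, in nucleotides) and
#' a CDR3-terminating anchor motif per gene. Genes within a chain are
#' homologous: they descend from a shared ancestral scaffold with family-
#' and gene-level codon divergence, mimicking the similarity structure of
#' real V-gene loci. Families are assigned round-robin (e.g. `HV1`, `HV2`,
#' ...). Each kappa gene additionally carries a canonical germline-encoded
#' CDR3 junction, reflecting the low junctional diversity of light chains.
#'
#' @param n_vh,n_vk number of heavy / kappa V genes (>= 1).
#' @param seed integer seed; the reference is a pure function of
#'   `(n_vh, n_vk, seed)`.
#' @return An object of class `germline_reference`: a list with element
#'   `genes`, a data.frame with one row per gene (`name`, `chain`, `family`,
#'   `nt_sequence`, `anchor_motif`, `anchor_nt`, `cdr3_nt`, and
#'   `<region>_start` / `<region>_end` interval columns).
#' @export
#' @examples
#' ref <- generate_germline_reference(9, 8, seed = 1)
#' table(ref$genes$chain)
generate_germline_reference <- function(n_vh, n_vk, seed) {
  if (!is.numeric(n_vh) || !is.numeric(n_vk) || n_vh < 1 || n_vk < 1)
    bcr_error("n_vh and n_vk must be positive counts", "argument_error")
  n_vh <- as.integer(n_vh); n_vk <- as.integer(n_vk)
  with_seed(seed, {
    sense <- sense_codons()
    rows <- list()
    for (chain in c("heavy", "kappa")) {
      n <- if (chain == "heavy") n_vh else n_vk
      fam_pool <- .FAMILY_POOL[[chain]]
      fams <- rep(fam_pool, length.out = n)
      ancestor <- sample(sense, sum(.REGION_CODONS), replace = TRUE)
      fam_cons <- lapply(unique(fams), function(f)
        .diverge(ancestor, 0.25, sense))
      names(fam_cons) <- unique(fams)
      idx_in_fam <- stats::ave(seq_len(n), fams, FUN = seq_along)
      for (i in seq_len(n)) {
        codons <- .diverge(fam_cons[[fams[i]]], 0.12, sense)
        nt <- paste(codons, collapse = "")
        ends <- cumsum(.REGION_CODONS) * 3L
        starts <- c(0L, ends[-length(ends)])
        anc <- .ANCHORS[[chain]]
        cdr3_nt <- if (chain == "kappa")
          random_inframe_segments(1L, 9L, motif = anc$aa) else NA_character_
        row <- data.frame(
          name = sprintf("%s-%d", fams[i], idx_in_fam[i]),
          chain = chain, family = fams[i], nt_sequence = nt,
          anchor_motif = anc$aa, anchor_nt = anc$nt, cdr3_nt = cdr3_nt,
          stringsAsFactors = FALSE
        )
        for (r in seq_along(.REGIONS_V)) {
          row[[paste0(.REGIONS_V[r], "_start")]] <- starts[r]
          row[[paste0(.REGIONS_V[r], "_end")]] <- ends[r]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    ref <- structure(
      list(genes = do.call(rbind, rows), seed = as.integer(seed)),
      class = "germline_reference"
    )
    validate_germline_reference(ref)
    ref
  })
}

#' Validate a germline reference against its structural invariants
#'
#' Checks unique gene names, at least one gene per chain, and per-gene region
#' intervals that are contiguous, non-overlapping, cover the sequence prefix
#' and have codon-multiple lengths.
#'
#' @param ref a `germline_reference`.
#' @return `ref`, invisibly; errors if any invariant fails.
#' @export
validate_germline_reference <- function(ref) {
  g <- ref$genes
  if (anyDuplicated(g$name))
    bcr_error("germline gene names must be unique", "reference_error")
  if (!all(c("heavy", "kappa") %in% g$chain))
    bcr_error("reference needs at least one gene per chain", "reference_error")
  for (i in seq_len(nrow(g))) {
    starts <- unlist(g[i, paste0(.REGIONS_V, "_start")])
    ends <- unlist(g[i, paste0(.REGIONS_V, "_end")])
    if (starts[1] != 0L || any(starts[-1] != ends[-length(ends)]))
      bcr_error(sprintf("gene %s: region intervals not contiguous from 0", g$name[i]),
                "reference_error")
    if (any((ends - starts) %% 3L != 0L) || any(ends <= starts))
      bcr_error(sprintf("gene %s: region lengths must be positive codon multiples",
                        g$name[i]), "reference_error")
    if (ends[length(ends)] > nchar(g$nt_sequence[i]))
      bcr_error(sprintf("gene %s: intervals exceed sequence", g$name[i]),
                "reference_error")
  }
  invisible(ref)
}

#' @export
print.germline_reference <- function(x, ...) {
  g <- x$genes
  cat(sprintf("Synthetic germline V reference: %d heavy, %d kappa genes\n",
              sum(g$chain == "heavy"), sum(g$chain == "kappa")))
  cat("Families:", paste(sort(unique(g$family)), collapse = ", "), "\n")
  invisible(x)
}

# region intervals (0-based half-open) for one gene, as a 2-column matrix
gene_boundaries <- function(ref, gene_name) {
  g <- ref$genes[ref$genes$name == gene_name, , drop = FALSE]
  if (nrow(g) != 1L)
    bcr_error(sprintf("gene '%s' not in reference", gene_name), "argument_error")
  m <- cbind(
    start = unlist(g[paste0(.REGIONS_V, "_start")]),
    end = unlist(g[paste0(.REGIONS_V, "_end")])
  )
  rownames(m) <- .REGIONS_V
  m
}

#' Write a germline reference as FASTA plus annotation sidecar
#'
#' The FASTA holds one record per gene; the sidecar TSV holds chain, family,
#' the five region intervals (0-based half-open nt coordinates), the anchor
#' motif and, for kappa genes, the canonical CDR3 junction.
#'
#' @param ref a `germline_reference`.
#' @param fasta_path,annotation_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_germline_reference <- function(ref, fasta_path, annotation_path) {
  g <- ref$genes
  seqs <- Biostrings::DNAStringSet(g$nt_sequence)
  names(seqs) <- g$name
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  write_tsv_atomic(g[, setdiff(names(g), "nt_sequence")], annotation_path)
  invisible(c(fasta_path, annotation_path))
}

#' Read a germline reference written by [write_germline_reference()]
#'
#' @param fasta_path,annotation_path the FASTA and sidecar TSV paths.
#' @return a validated `germline_reference`.
#' @export
read_germline_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- read_tsv(annotation_path)
  if (!all(ann$name %in% names(seqs)))
    bcr_error("annotation names missing from FASTA", "io_error")
  ann$nt_sequence <- as.character(seqs[ann$name])
  ann$cdr3_nt <- as.character(ann$cdr3_nt)
  ref <- structure(list(genes = ann, seed = NA_integer_),
                   class = "germline_reference")
  validate_germline_reference(ref)
  ref
}
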