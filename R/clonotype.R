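# Clonotype uniqueness, sharing, paratope grouping and VH/VK family
# pairing. All keys are amino-acid region strings by default: FR1 and FR4
# never enter any key (degenerate-primer regions), so two clones differing
# only there collapse to the same clonotype.

.REGION_ORDER <- c("cdr1", "fr2", "cdr2", "fr3", "cdr3")  # genomic order
.CHAIN_TAG <- c(heavy = "H", kappa = "K")

.annotated <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  rep$annotation[rep$annotation$annotated, , drop = FALSE]
}

#' Clonotype keys for the annotated records of a repertoire
#'
#' The key of a record is the `'|'`-joined, chain-tagged concatenation of
#' the requested amino-acid regions in fixed genomic order
#' (cdr1, fr2, cdr2, fr3, cdr3 per chain). The default -- all CDRs plus
#' frameworks 2 and 3 of the heavy chain -- is the VH-uniqueness key;
#' frameworks 1 and 4 are never part of a key.
#'
#' @param rep a [annotate_repertoire()] result.
#' @param regions subset of `c("cdr1","cdr2","cdr3","fr2","fr3")`.
#' @param chains `"heavy"`, `"kappa"`, or both.
#' @return named character vector of keys (names are cell ids), one per
#'   annotated record.
#' @export
clone_keys <- function(rep, regions = c("cdr1", "cdr2", "cdr3", "fr2", "fr3"),
                       chains = "heavy") {
  bad <- setdiff(regions, .REGION_ORDER)
  if (length(bad))
    bcr_error(paste0("unknown/unsupported region(s): ",
                     paste(bad, collapse = ", ")), "argument_error")
  bad <- setdiff(chains, names(.CHAIN_TAG))
  if (length(bad))
    bcr_error(paste0("unknown chain(s): ", paste(bad, collapse = ", ")),
              "argument_error")
  regions <- .REGION_ORDER[.REGION_ORDER %in% regions]
  ann <- .annotated(rep)
  if (nrow(ann) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- list()
  for (ch in c("heavy", "kappa")[c("heavy", "kappa") %in% chains]) {
    p <- if (ch == "heavy") "vh_" else "vk_"
    for (r in regions)
      parts[[paste0(ch, r)]] <-
        paste0(.CHAIN_TAG[ch], ":", r, "=", ann[[paste0(p, r)]])
  }
  keys <- do.call(paste, c(parts, sep = "|"))
  stats::setNames(keys, ann$cell_id)
}

#' Partition a repertoire into unique clonotypes
#'
#' Groups annotated records by their clonotype key and reports the number
#' of unique clones (partition blocks).
#'
#' @inheritParams clone_keys
#' @return an object of class `clone_partition`: list with `n_clones`,
#'   `partition` (named list: key -> member cell ids), `regions`, `chains`.
#' @export
unique_clones <- function(rep, regions = c("cdr1", "cdr2", "cdr3", "fr2", "fr3"),
                          chains = "heavy") {
  keys <- clone_keys(rep, regions, chains)
  part <- split(names(keys), keys)
  structure(list(n_clones = length(part), partition = part,
                 regions = regions, chains = chains),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat(sprintf("Clone partition: %d unique clones over %d records (%s: %s)\n",
              x$n_clones, sum(lengths(x$partition)),
              paste(x$chains, collapse = "+"),
              paste(x$regions, collapse = ",")))
  invisible(x)
}

#' Unique and shared clonotypes between two repertoires
#'
#' Computed on the key *sets* of the two repertoires: keys only in A, keys
#' in both, keys only in B.
#'
#' @param repA,repB annotated repertoires.
#' @inheritParams clone_keys
#' @return named integer vector `c(unique_A, shared, unique_B)`.
#' @export
shared_unique <- function(repA, repB,
                          regions = c("cdr1", "cdr2", "cdr3", "fr2", "fr3"),
                          chains = "heavy") {
  ka <- unique(clone_keys(repA, regions, chains))
  kb <- unique(clone_keys(repB, regions, chains))
  c(unique_A = length(setdiff(ka, kb)),
    shared = length(intersect(ka, kb)),
    unique_B = length(setdiff(kb, ka)))
}

#' Unique/shared counts for a single CDR
#'
#' As [shared_unique()] with the key reduced to one CDR's amino-acid string
#' on one chain.
#'
#' @param repA,repB annotated repertoires.
#' @param cdr one of `"cdr1"`, `"cdr2"`, `"cdr3"`.
#' @param chain `"heavy"` or `"kappa"`.
#' @return named integer vector `c(unique_A, shared, unique_B)`.
#' @export
per_cdr_unique_shared <- function(repA, repB, cdr = c("cdr1", "cdr2", "cdr3"),
                                  chain = "heavy") {
  cdr <- match.arg(cdr)
  shared_unique(repA, repB, regions = cdr, chains = chain)
}

#' Group clones by paratope (all six CDRs)
#'
#' The paratope key concatenates heavy CDR1-3 and kappa CDR1-3 amino-acid
#' strings (chain-tagged); identical concatenations form one paratope
#' group. Records without a kappa annotation are excluded (they never reach
#' this point, since annotation requires both chains) and failures are
#' logged by [annotate_repertoire()].
#'
#' @param rep an annotated repertoire.
#' @return list with `n_groups` and the `clone_partition`.
#' @export
paratope_groups <- function(rep) {
  part <- unique_clones(rep, regions = c("cdr1", "cdr2", "cdr3"),
                        chains = c("heavy", "kappa"))
  list(n_groups = part$n_clones, partition = part)
}

#' VH/VK family pairing matrix
#'
#' Counts annotated records per (heavy family, kappa family) combination.
#'
#' @param rep an annotated repertoire.
#' @return an object of class `pairing_matrix`: integer matrix with heavy
#'   families as rows and kappa families as columns.
#' @export
pairing_matrix <- function(rep) {
  ann <- .annotated(rep)
  m <- table(heavy_family = ann$vh_family, kappa_family = ann$vk_family)
  m <- unclass(as.matrix(m))
  class(m) <- c("pairing_matrix", class(m))
  m
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat("VH/VK family pairing counts:\n")
  print(unclass(x))
  invisible(x)
}

# long-format view of a pairing matrix, nonzero cells only
pairing_long <- function(m) {
  df <- as.data.frame(as.table(unclass(m)), stringsAsFactors = FALSE)
  names(df) <- c("heavy_family", "kappa_family", "n")
  df[df$n > 0, , drop = FALSE]
}

#' Family pairs exclusive to each of two pairing matrices
#'
#' Compares the sets of nonzero (heavy family, kappa family) cells.
#'
#' @param mA,mB [pairing_matrix()] results.
#' @return list of data.frames `pairs_only_A`, `pairs_only_B`, `pairs_both`
#'   (columns `heavy_family`, `kappa_family`).
#' @export
exclusive_pairs <- function(mA, mB) {
  la <- pairing_long(mA); lb <- pairing_long(mB)
  ka <- paste(la$heavy_family, la$kappa_family, sep = "\r")
  kb <- paste(lb$heavy_family, lb$kappa_family, sep = "\r")
  pick <- function(l, keep) l[keep, c("heavy_family", "kappa_family"), drop = FALSE]
  list(pairs_only_A = pick(la, !(ka %in% kb)),
       pairs_only_B = pick(lb, !(kb %in% ka)),
       pairs_both = pick(la, ka %in% kb))
}

#' Gene-usage table for a repertoire
#'
#' Counts annotated records per V gene (or family) for one chain, the
#' substrate of gene-usage bar charts.
#'
#' @param rep an annotated repertoire.
#' @param chain `"heavy"` or `"kappa"`.
#' @param by `"gene"` or `"family"`.
#' @return data.frame with columns `label` and `n`.
#' @export
gene_usage <- function(rep, chain = c("heavy", "kappa"),
                       by = c("gene", "family")) {
  chain <- match.arg(chain); by <- match.arg(by)
  ann <- .annotated(rep)
  col <- paste0(if (chain == "heavy") "vh_" else "vk_",
                if (by == "gene") "call" else "family")
  tab <- sort(table(ann[[col]]), decreasing = TRUE)
  data.frame(label = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
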