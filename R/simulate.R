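# Stochastic model of the selection workflow: immune response ->
# IgM/IgD depletion -> magnetic bulk selection -> library construction.
#
# Cells are rows of a data.frame ("B-cell records"); sequences carry full
# ground truth so downstream annotation and diversity analyses can be
# checked against the generator.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic immune response and bulk
#' selection. Defaults encode the study conditions this package emulates:
#' antigen-specific cells are rare (5e-4 of B cells, within the 1e-4..1e-3
#' range typical of a robust immune response), ~10% of B cells are
#' class-switched IgG, magnetic capture keeps 98% of specific cells (~2%
#' loss), and nonspecific carryover is small enough that the selected pool's
#' binder rate falls in the 51-88% band observed for bulk-selected wells.
#'
#' @param n_cells number of B cells to simulate.
#' @param antigen_specific_fraction proportion of cells that are
#'   antigen-specific (truth label).
#' @param n_founder_lineages number of founder clonal lineages among
#'   specific cells.
#' @param shm_rate_cdr,shm_rate_fr per-site somatic-hypermutation
#'   substitution probabilities in CDR and framework intervals;
#'   `shm_rate_cdr >= shm_rate_fr` (CDR bias).
#' @param igg_fraction proportion of cells that are IgG (others IgM/IgD).
#' @param capture_efficiency probability a specific cell is captured into
#'   the selected fraction.
#' @param nonspecific_capture_rate probability a non-specific cell is
#'   carried into the selected fraction.
#' @param pairing_mode default library pairing mode, `"cognate"` or
#'   `"combinatorial"`.
#' @param binding_model a [binding_model()].
#' @param seed integer seed recorded in all outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1e5,
                       antigen_specific_fraction = 5e-4,
                       n_founder_lineages = 8,
                       shm_rate_cdr = 0.01,
                       shm_rate_fr = 0.002,
                       igg_fraction = 0.1,
                       capture_efficiency = 0.98,
                       nonspecific_capture_rate = 2e-4,
                       pairing_mode = c("cognate", "combinatorial"),
                       binding_model = bcrselect::binding_model(),
                       seed = 1L) {
  pairing_mode <- match.arg(pairing_mode)
  props <- c(antigen_specific_fraction = antigen_specific_fraction,
             shm_rate_cdr = shm_rate_cdr, shm_rate_fr = shm_rate_fr,
             igg_fraction = igg_fraction,
             capture_efficiency = capture_efficiency,
             nonspecific_capture_rate = nonspecific_capture_rate)
  if (any(props < 0 | props > 1))
    bcr_error("all proportions must lie in [0, 1]", "config_error")
  if (shm_rate_cdr < shm_rate_fr)
    bcr_error("shm_rate_cdr must be >= shm_rate_fr (CDR bias)", "config_error")
  if (n_cells < 1 || n_founder_lineages < 1)
    bcr_error("n_cells and n_founder_lineages must be positive", "config_error")
  structure(list(
    n_cells = as.integer(n_cells),
    antigen_specific_fraction = antigen_specific_fraction,
    n_founder_lineages = as.integer(n_founder_lineages),
    shm_rate_cdr = shm_rate_cdr, shm_rate_fr = shm_rate_fr,
    igg_fraction = igg_fraction,
    capture_efficiency = capture_efficiency,
    nonspecific_capture_rate = nonspecific_capture_rate,
    pairing_mode = pairing_mode, binding_model = binding_model,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:\n")
  cat(sprintf("  n_cells=%d, specific fraction=%g, %d founder lineages\n",
              x$n_cells, x$antigen_specific_fraction, x$n_founder_lineages))
  cat(sprintf("  SHM per-site: CDR %g, FR %g; IgG fraction %g\n",
              x$shm_rate_cdr, x$shm_rate_fr, x$igg_fraction))
  cat(sprintf("  capture %g, nonspecific carryover %g, seed %d\n",
              x$capture_efficiency, x$nonspecific_capture_rate, x$seed))
  invisible(x)
}

#' Antigen-binding model for paired heavy/kappa clones
#'
#' Probabilities that a clone binds antigen depending on how its chains were
#' paired, and that a binder is functional. The monotone invariant
#' `p_bind_cognate >= p_bind_both_specific >= p_bind_mixed` encodes the
#' mechanism that cognate pairing preserves function best, shuffled pairing
#' of two antigen-experienced chains less, and a specific chain paired with
#' a bystander chain least.
#'
#' @param p_bind_cognate P(binds) for a cognate pair from a specific cell.
#' @param p_bind_both_specific P(binds) for a shuffled pair whose chains
#'   both come from specific lineages.
#' @param p_bind_mixed P(binds) for a shuffled pair with exactly one
#'   specific chain.
#' @param p_functional_given_bind_cognate,p_functional_given_bind_shuffled
#'   conditional probabilities that a binder is functional, by pairing
#'   origin.
#' @return an object of class `binding_model`.
#' @export
binding_model <- function(p_bind_cognate = 0.9,
                          p_bind_both_specific = 0.6,
                          p_bind_mixed = 0.3,
                          p_functional_given_bind_cognate = 0.8,
                          p_functional_given_bind_shuffled = 0.5) {
  p <- c(p_bind_cognate, p_bind_both_specific, p_bind_mixed,
         p_functional_given_bind_cognate, p_functional_given_bind_shuffled)
  if (any(p < 0 | p > 1))
    bcr_error("binding probabilities must lie in [0, 1]", "config_error")
  if (!(p_bind_cognate >= p_bind_both_specific &&
        p_bind_both_specific >= p_bind_mixed))
    bcr_error("need p_bind_cognate >= p_bind_both_specific >= p_bind_mixed",
              "config_error")
  structure(list(
    p_bind_cognate = p_bind_cognate,
    p_bind_both_specific = p_bind_both_specific,
    p_bind_mixed = p_bind_mixed,
    p_functional_given_bind_cognate = p_functional_given_bind_cognate,
    p_functional_given_bind_shuffled = p_functional_given_bind_shuffled
  ), class = "binding_model")
}

# CDR/FR nt intervals (1-based inclusive) of a full chain sequence built as
# V(FR1..FR3) + CDR3 + anchor
.chain_intervals <- function(bnd, cdr3_len_nt) {
  v_end <- bnd["fr3", "end"]
  list(
    cdr = rbind(bnd["cdr1", ] + c(1L, 0L), bnd["cdr2", ] + c(1L, 0L),
                c(v_end + 1L, v_end + cdr3_len_nt)),
    fr = rbind(bnd["fr1", ] + c(1L, 0L), bnd["fr2", ] + c(1L, 0L),
               bnd["fr3", ] + c(1L, 0L))
  )
}

# apply per-site substitutions at the given rates; substitutions creating a
# stop codon are redrawn up to 10 times, then the site is skipped
.mutate_chain <- function(seq, ivs, rate_cdr, rate_fr) {
  bases <- c("A", "C", "G", "T")
  pick_sites <- function(m, rate) {
    if (rate <= 0) return(integer(0))
    sites <- unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2]))
    sites[stats::runif(length(sites)) < rate]
  }
  pos <- c(pick_sites(ivs$cdr, rate_cdr), pick_sites(ivs$fr, rate_fr))
  for (p in pos) {
    old <- substr(seq, p, p)
    frame0 <- (p - 1L) %/% 3L * 3L + 1L
    for (try in 1:10) {
      new <- sample(setdiff(bases, old), 1L)
      cand <- seq
      substr(cand, p, p) <- new
      if (!(substr(cand, frame0, frame0 + 2L) %in% STOP_CODONS)) {
        seq <- cand
        break
      }
    }
  }
  seq
}

#' Simulate an immune response with rare antigen-specific lineages
#'
#' Generates `cfg$n_cells` B-cell records. Each cell is antigen-specific
#' with probability `antigen_specific_fraction`; specific cells are assigned
#' uniformly to `n_founder_lineages` clonal lineages. A lineage has a founder
#' heavy and kappa V gene and a lineage-defining junctional heavy CDR3;
#' kappa CDR3 is the germline-encoded canonical junction of the founder
#' kappa gene. Lineage members accumulate somatic hypermutation: per-site
#' substitutions at `shm_rate_cdr` in CDR1/CDR2/CDR3 and `shm_rate_fr` in
#' FR1-FR3 of both chains (stop-creating substitutions redrawn). The
#' J-surrogate anchor is never mutated (it is the primer-annealed segment
#' excluded from all analyses). Non-specific cells carry unmutated germline
#' V genes with a cell-private junctional heavy CDR3. Isotype is IgG with
#' probability `igg_fraction`, else IgM/IgD.
#'
#' @param ref a [generate_germline_reference()] result.
#' @param cfg a [sim_config()]; `cfg$seed` fixes all randomness.
#' @return a data.frame of B-cell records with columns `cell_id`, `vh_nt`,
#'   `vk_nt`, `lineage_id` (NA for non-specific), `is_antigen_specific`,
#'   `vh_specific`, `vk_specific`, `vh_gene`, `vk_gene`, `isotype`,
#'   `compartment` (`"input"`), `pairing_origin` (`"cognate"`).
#' @export
simulate_immune_response <- function(ref, cfg) {
  stopifnot(inherits(ref, "germline_reference"), inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    g <- ref$genes
    hv <- g[g$chain == "heavy", , drop = FALSE]
    kv <- g[g$chain == "kappa", , drop = FALSE]
    n <- cfg$n_cells
    is_spec <- stats::runif(n) < cfg$antigen_specific_fraction
    n_spec <- sum(is_spec)

    # founder lineages: genes + junctional heavy CDR3, shared by members.
    # The kappa junction is the founder gene's canonical CDR3 with a couple
    # of lineage-private junctional substitutions: light-chain junctions are
    # germline-proximal but still clonally distinct.
    nl <- cfg$n_founder_lineages
    fl <- data.frame(
      lineage = sprintf("L%02d", seq_len(nl)),
      hv_idx = sample(nrow(hv), nl, replace = TRUE),
      kv_idx = sample(nrow(kv), nl, replace = TRUE),
      cdr3h = random_inframe_segments(nl, 8:16, motif = .ANCHORS$heavy$aa),
      stringsAsFactors = FALSE
    )
    sense <- sense_codons()
    fl$cdr3k <- vapply(seq_len(nl), function(i) {
      nt <- kv$cdr3_nt[fl$kv_idx[i]]
      n_cod <- nchar(nt) %/% 3L
      for (try in 1:25) {
        cand <- nt
        for (p in sample(n_cod, 2L)) {
          substr(cand, 3L * p - 2L, 3L * p) <- sample(sense, 1L)
        }
        aa <- translate_nt(cand)
        if (!grepl(.ANCHORS$kappa$aa, aa, fixed = TRUE)) return(cand)
      }
      nt
    }, character(1))

    # non-specific cells: germline V, private heavy CDR3, canonical kappa CDR3
    hv_idx <- sample(nrow(hv), n, replace = TRUE)
    kv_idx <- sample(nrow(kv), n, replace = TRUE)
    cdr3h <- random_inframe_segments(n, 8:16, motif = .ANCHORS$heavy$aa)
    cdr3k <- kv$cdr3_nt[kv_idx]
    lineage <- rep(NA_character_, n)
    if (n_spec > 0) {
      li <- sample(nl, n_spec, replace = TRUE)
      w <- which(is_spec)
      lineage[w] <- fl$lineage[li]
      hv_idx[w] <- fl$hv_idx[li]
      kv_idx[w] <- fl$kv_idx[li]
      cdr3h[w] <- fl$cdr3h[li]
      cdr3k[w] <- fl$cdr3k[li]
    }

    vh <- paste0(substr(hv$nt_sequence[hv_idx], 1L, hv$fr3_end[1]),
                 cdr3h, hv$anchor_nt[1])
    vk <- paste0(substr(kv$nt_sequence[kv_idx], 1L, kv$fr3_end[1]),
                 cdr3k, kv$anchor_nt[1])

    # SHM: antigen-experienced (specific) cells only
    if (n_spec > 0 && (cfg$shm_rate_cdr > 0 || cfg$shm_rate_fr > 0)) {
      bnd_h <- gene_boundaries(ref, hv$name[1])
      bnd_k <- gene_boundaries(ref, kv$name[1])
      for (i in which(is_spec)) {
        ivh <- .chain_intervals(bnd_h, nchar(cdr3h[i]))
        vh[i] <- .mutate_chain(vh[i], ivh, cfg$shm_rate_cdr, cfg$shm_rate_fr)
        ivk <- .chain_intervals(bnd_k, nchar(cdr3k[i]))
        vk[i] <- .mutate_chain(vk[i], ivk, cfg$shm_rate_cdr, cfg$shm_rate_fr)
      }
    }

    data.frame(
      cell_id = sprintf("C%06d", seq_len(n)),
      vh_nt = vh, vk_nt = vk,
      lineage_id = lineage,
      is_antigen_specific = is_spec,
      vh_specific = is_spec, vk_specific = is_spec,
      vh_gene = hv$name[hv_idx], vk_gene = kv$name[kv_idx],
      isotype = ifelse(stats::runif(n) < cfg$igg_fraction, "IgG", "IgM/IgD"),
      compartment = "input", pairing_origin = "cognate",
      stringsAsFactors = FALSE
    )
  })
}

#' Deplete IgM/IgD cells, keeping IgG records in order
#'
#' Mirrors the IgM+/IgD+ depletion step performed before antigen selection.
#'
#' @param pool a B-cell record data.frame.
#' @return the IgG-only subset, original order preserved.
#' @export
deplete_igm_igd <- function(pool) {
  pool[pool$isotype == "IgG", , drop = FALSE]
}

#' Simulate magnetic bulk selection of antigen-specific cells
#'
#' Every specific cell enters the selected fraction with probability
#' `capture_efficiency`, every non-specific cell with probability
#' `nonspecific_capture_rate`; all remaining cells form the flow-through.
#' No cells are created or destroyed.
#'
#' @param pool IgG+ B-cell records (deplete IgM/IgD first).
#' @param cfg a [sim_config()].
#' @param seed seed for the capture draws (default derived from `cfg$seed`).
#' @return `list(selected = ..., flow_through = ...)` with `compartment`
#'   labels set.
#' @export
simulate_selection <- function(pool, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(pool) == 0L)
    return(list(selected = pool, flow_through = pool))
  with_seed(seed, {
    p <- ifelse(pool$is_antigen_specific,
                cfg$capture_efficiency, cfg$nonspecific_capture_rate)
    captured <- stats::runif(nrow(pool)) < p
    sel <- pool[captured, , drop = FALSE]
    ft <- pool[!captured, , drop = FALSE]
    if (nrow(sel)) sel$compartment <- "selected"
    if (nrow(ft)) ft$compartment <- "flow_through"
    list(selected = sel, flow_through = ft)
  })
}

#' Construct a display library with cognate or combinatorial chain pairing
#'
#' Cognate mode keeps each cell's natural heavy/kappa pair. Combinatorial
#' mode permutes the kappa chains uniformly at random across records
#' (heavy fixed), the in-distribution equivalent of shuffling both chains
#' during bulk library cloning; the heavy and kappa chain multisets are both
#' preserved.
#'
#' @param pool non-empty B-cell records.
#' @param mode `"cognate"` or `"combinatorial"`.
#' @param seed seed for the permutation.
#' @return records with `pairing_origin` set to `"cognate"` or `"shuffled"`;
#'   in combinatorial mode the `vk_*` truth columns follow the kappa chain.
#' @export
build_library <- function(pool, mode = c("cognate", "combinatorial"), seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(pool) == 0L)
    bcr_error("cannot build a library from an empty pool", "argument_error")
  if (mode == "cognate") {
    pool$pairing_origin <- "cognate"
    return(pool)
  }
  with_seed(seed, {
    perm <- sample(nrow(pool))
    for (col in c("vk_nt", "vk_specific", "vk_gene"))
      pool[[col]] <- pool[[col]][perm]
    pool$pairing_origin <- "shuffled"
    pool
  })
}

#' Draw antigen binding and functionality for paired records
#'
#' The binding probability of each record is chosen by case: cognate pair
#' from a specific cell (`p_bind_cognate`); shuffled pair with both chains
#' specific (`p_bind_both_specific`); shuffled mixed pair whose *heavy*
#' chain is specific (`p_bind_mixed` -- antigen recognition is treated as
#' heavy-chain driven, so a specific kappa on a bystander heavy does not
#' bind); no specific heavy chain (never binds). Functionality is drawn
#' only for binders, using the conditional matched to the record's pairing
#' origin.
#'
#' @param records B-cell records with `pairing_origin`, `vh_specific`,
#'   `vk_specific` columns.
#' @param model a [binding_model()].
#' @param seed seed for the Bernoulli draws.
#' @return `records` with logical columns `binds` and `functional` added.
#' @export
assign_binding <- function(records, model = binding_model(), seed = 1L) {
  stopifnot(inherits(model, "binding_model"))
  if (is.null(records$pairing_origin))
    bcr_error("records must have pairing_origin set", "argument_error")
  with_seed(seed, {
    n <- nrow(records)
    cognate <- records$pairing_origin == "cognate"
    p_bind <- numeric(n)
    p_bind[cognate & records$is_antigen_specific] <- model$p_bind_cognate
    p_bind[!cognate & records$vh_specific & records$vk_specific] <-
      model$p_bind_both_specific
    p_bind[!cognate & records$vh_specific & !records$vk_specific] <-
      model$p_bind_mixed
    binds <- stats::runif(n) < p_bind
    p_fun <- ifelse(cognate, model$p_functional_given_bind_cognate,
                    model$p_functional_given_bind_shuffled)
    functional <- binds & (stats::runif(n) < p_fun)
    records$binds <- binds
    records$functional <- functional
    records
  })
}

#' Write a simulated repertoire as paired FASTA plus a truth-label table
#'
#' @param records B-cell records (optionally with `binds`/`functional`).
#' @param prefix output path prefix; writes `<prefix>_heavy.fasta`,
#'   `<prefix>_kappa.fasta` and `<prefix>_truth.tsv`.
#' @return invisibly, the three paths.
#' @export
write_repertoire_fasta <- function(records, prefix) {
  h <- Biostrings::DNAStringSet(records$vh_nt); names(h) <- records$cell_id
  k <- Biostrings::DNAStringSet(records$vk_nt); names(k) <- records$cell_id
  ph <- paste0(prefix, "_heavy.fasta"); pk <- paste0(prefix, "_kappa.fasta")
  pt <- paste0(prefix, "_truth.tsv")
  Biostrings::writeXStringSet(h, ph, width = 80L)
  Biostrings::writeXStringSet(k, pk, width = 80L)
  keep <- intersect(c("cell_id", "lineage_id", "is_antigen_specific",
                      "isotype", "compartment", "pairing_origin",
                      "binds", "functional"), names(records))
  write_tsv_atomic(records[, keep], pt)
  invisible(c(ph, pk, pt))
}
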