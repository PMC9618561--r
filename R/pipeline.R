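# End-to-end orchestration: simulate -> select -> build libraries ->
# annotate -> diversity/trees -> NGS -> screening summaries, from a single
# seeded config. Every stochastic stage draws its seed deterministically
# from the run seed; all tables are written atomically (write-then-rename)
# so a failed run leaves no truncated files.

#' Pipeline run configuration
#'
#' @param output_dir directory for report files (created if missing).
#' @param seed master run seed; every stage seed is derived from it.
#' @param sim a [sim_config()] for synthetic runs, or `NULL` to analyze
#'   provided inputs only.
#' @param n_vh,n_vk germline reference size for synthetic runs.
#' @param reference_fasta,reference_annotation paths to a stored reference
#'   (overrides synthetic reference generation).
#' @param heavy_fasta,kappa_fasta optional paired repertoire FASTA inputs
#'   (matched ids) to annotate instead of simulating.
#' @param plate_file optional long-format plate TSV for hit calling / QC.
#' @param regions clonotype region set for VH uniqueness.
#' @param min_count NGS collapse threshold.
#' @param fold_threshold hit-calling fold over negative controls.
#' @param max_screen number of binder clones screened (annotated) per
#'   library, mirroring a Sanger screening depth of a few hundred clones.
#' @param ngs_depth,ngs_noise read depth per template and singleton noise
#'   reads for the synthetic NGS stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       seed = 1L,
                       sim = sim_config(seed = seed),
                       n_vh = 9L, n_vk = 8L,
                       reference_fasta = NULL, reference_annotation = NULL,
                       heavy_fasta = NULL, kappa_fasta = NULL,
                       plate_file = NULL,
                       regions = c("cdr1", "cdr2", "cdr3", "fr2", "fr3"),
                       min_count = 2L,
                       fold_threshold = 10,
                       max_screen = 150L,
                       ngs_depth = 3L, ngs_noise = 25L) {
  structure(list(
    output_dir = output_dir, seed = as.integer(seed), sim = sim,
    n_vh = n_vh, n_vk = n_vk,
    reference_fasta = reference_fasta,
    reference_annotation = reference_annotation,
    heavy_fasta = heavy_fasta, kappa_fasta = kappa_fasta,
    plate_file = plate_file,
    regions = regions, min_count = min_count,
    fold_threshold = fold_threshold, max_screen = max_screen,
    ngs_depth = ngs_depth, ngs_noise = ngs_noise
  ), class = "run_config")
}

#' Validate pipeline inputs without running anything
#'
#' Checks file existence, reference invariants, paired FASTA id matching
#' and plate-table roles. Returns structured diagnostics and never mutates
#' inputs.
#'
#' @param cfg a [run_config()].
#' @return data.frame with columns `check` and `message`; zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  diag <- list()
  note <- function(check, msg)
    diag[[length(diag) + 1L]] <<- data.frame(check = check, message = msg,
                                             stringsAsFactors = FALSE)
  for (f in c("reference_fasta", "reference_annotation",
              "heavy_fasta", "kappa_fasta", "plate_file")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      note(f, sprintf("file not found: %s", p))
  }
  if (!is.null(cfg$reference_fasta) && !is.null(cfg$reference_annotation) &&
      file.exists(cfg$reference_fasta) && file.exists(cfg$reference_annotation)) {
    tryCatch(read_germline_reference(cfg$reference_fasta, cfg$reference_annotation),
             error = function(e) note("reference", conditionMessage(e)))
  }
  if (!is.null(cfg$heavy_fasta) && !is.null(cfg$kappa_fasta) &&
      file.exists(cfg$heavy_fasta) && file.exists(cfg$kappa_fasta)) {
    h <- Biostrings::readDNAStringSet(cfg$heavy_fasta)
    k <- Biostrings::readDNAStringSet(cfg$kappa_fasta)
    if (!setequal(names(h), names(k)))
      note("paired_fasta", "heavy and kappa FASTA ids do not match")
  }
  if (!is.null(cfg$plate_file) && file.exists(cfg$plate_file)) {
    plates <- tryCatch(read_plate_table(cfg$plate_file),
                       error = function(e) {
                         note("plate_file", conditionMessage(e)); NULL
                       })
    if (!is.null(plates)) {
      for (pl in plates)
        if (!any(pl$roles == "negative_control"))
          note("plate_controls",
               sprintf("plate %s has no negative-control wells", pl$plate_id))
    }
  }
  if (is.null(cfg$sim) && (is.null(cfg$heavy_fasta) || is.null(cfg$kappa_fasta)))
    note("inputs", "no simulation config and no paired repertoire inputs")
  if (length(diag)) do.call(rbind, diag)
  else data.frame(check = character(0), message = character(0))
}

# fixed offsets for the per-stage substreams of a run seed
.stage_seed <- function(seed, stage) {
  offs <- c(reference = 11L, response = 23L, selection = 37L,
            lib_cognate = 41L, lib_agsc = 43L, lib_tbc = 47L,
            bind_input = 53L, bind_selected = 59L, bind_flow = 61L,
            bind_cognate = 67L, bind_agsc = 71L, bind_tbc = 73L,
            screen = 79L, ngs = 83L)
  (as.integer(seed) * 101L + offs[[stage]]) %% .Machine$integer.max
}

.binder_pct <- function(records, model, seed) {
  if (nrow(records) == 0L) return(NA_real_)
  b <- assign_binding(records, model, seed = seed)
  100 * mean(b$binds)
}

#' Run the full pipeline from one configuration
#'
#' In synthetic mode (the default): generates the germline reference,
#' simulates the immune response, depletes IgM/IgD cells, performs bulk
#' selection, builds the three libraries (cognate from selected cells,
#' combinatorial within selected cells, combinatorial within the total IgG
#' pool), draws binding/functionality, screens up to `max_screen` binder
#' clones per library through annotation, and writes AIRR tables,
#' gene-usage/pairing/unique-shared/paratope tables, Newick six-CDR trees,
#' NGS comparison tables, screening summaries and a machine-readable run
#' manifest into `output_dir`. With paired FASTA inputs it annotates and
#' analyzes those instead of simulating.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory results (`reference`,
#'   `repertoires`, `tables`, `manifest`, `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  diag <- validate_inputs(cfg)
  if (nrow(diag))
    bcr_error(paste0("invalid inputs:\n",
                     paste(sprintf("- [%s] %s", diag$check, diag$message),
                           collapse = "\n")), "config_error")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$output_dir, name)
  files <- character(0)
  tables <- list()

  # --- reference ---
  ref <- if (!is.null(cfg$reference_fasta))
    read_germline_reference(cfg$reference_fasta, cfg$reference_annotation)
  else
    generate_germline_reference(cfg$n_vh, cfg$n_vk,
                                seed = .stage_seed(cfg$seed, "reference"))
  write_germline_reference(ref, out("germline_reference.fasta"),
                           out("germline_reference.tsv"))
  files <- c(files, out("germline_reference.fasta"), out("germline_reference.tsv"))

  reps <- list()
  screened <- list()

  if (!is.null(cfg$heavy_fasta)) {
    # --- file mode: annotate provided paired sequences ---
    h <- Biostrings::readDNAStringSet(cfg$heavy_fasta)
    k <- Biostrings::readDNAStringSet(cfg$kappa_fasta)
    k <- k[names(h)]
    records <- data.frame(cell_id = names(h),
                          vh_nt = as.character(h), vk_nt = as.character(k),
                          compartment = "input", pairing_origin = "cognate",
                          stringsAsFactors = FALSE)
    reps$input <- suppressMessages(annotate_repertoire(records, ref, "input"))
    screened$input <- reps$input
  } else {
    # --- synthetic mode ---
    sim <- cfg$sim
    sim$seed <- .stage_seed(cfg$seed, "response")
    pool <- simulate_immune_response(ref, sim)
    igg <- deplete_igm_igd(pool)
    sf <- simulate_selection(igg, sim, seed = .stage_seed(cfg$seed, "selection"))
    model <- sim$binding_model

    libs <- list(
      cognate = build_library(sf$selected, "cognate",
                              seed = .stage_seed(cfg$seed, "lib_cognate")),
      agsc_lib = build_library(sf$selected, "combinatorial",
                               seed = .stage_seed(cfg$seed, "lib_agsc")),
      tbc_lib = build_library(igg, "combinatorial",
                              seed = .stage_seed(cfg$seed, "lib_tbc"))
    )
    libs <- lapply(names(libs), function(nm)
      assign_binding(libs[[nm]], model,
                     seed = .stage_seed(cfg$seed, paste0("bind_", sub("_lib", "", nm)))))
    names(libs) <- c("cognate", "agsc_lib", "tbc_lib")

    # Fig3-style enrichment summary: binder percent by compartment
    tables$enrichment <- data.frame(
      compartment = c("input", "selected", "flow_through"),
      n_cells = c(nrow(igg), nrow(sf$selected), nrow(sf$flow_through)),
      binder_pct = c(
        .binder_pct(igg, model, .stage_seed(cfg$seed, "bind_input")),
        .binder_pct(sf$selected, model, .stage_seed(cfg$seed, "bind_selected")),
        .binder_pct(sf$flow_through, model, .stage_seed(cfg$seed, "bind_flow"))
      ),
      stringsAsFactors = FALSE
    )
    write_tsv_atomic(tables$enrichment, out("enrichment_summary.tsv"))
    files <- c(files, out("enrichment_summary.tsv"))

    # Fig5-style functional summary over whole libraries
    tables$functional <- data.frame(
      library = names(libs),
      n_clones = vapply(libs, nrow, integer(1)),
      functional_pct = vapply(libs, function(l) 100 * mean(l$functional),
                              numeric(1)),
      stringsAsFactors = FALSE
    )
    write_tsv_atomic(tables$functional, out("functional_summary.tsv"))
    files <- c(files, out("functional_summary.tsv"))

    # screened clones: up to max_screen binders per library, annotated
    sseed <- .stage_seed(cfg$seed, "screen")
    for (nm in names(libs)) {
      binders <- libs[[nm]][libs[[nm]]$binds, , drop = FALSE]
      if (nrow(binders) > cfg$max_screen)
        binders <- with_seed(sseed + match(nm, names(libs)),
                             binders[sample(nrow(binders), cfg$max_screen), ,
                                     drop = FALSE])
      if (nrow(binders) > 0)
        screened[[nm]] <- suppressMessages(
          annotate_repertoire(binders, ref, label = nm))
    }
    reps <- screened

    # NGS stage: collapse read pools from the two phage libraries
    nseed <- .stage_seed(cfg$seed, "ngs")
    ngs_tabs <- list()
    for (nm in c("agsc_lib", "tbc_lib")) {
      templ <- unique(libs[[nm]]$vh_nt)
      if (length(templ) > 200L)
        templ <- with_seed(nseed, sample(templ, 200L))
      reads <- simulate_ngs_reads(templ, depth = cfg$ngs_depth,
                                  n_noise = cfg$ngs_noise,
                                  seed = nseed + match(nm, c("agsc_lib", "tbc_lib")))
      cs <- collapse_reads(reads, min_count = cfg$min_count, pool_label = nm)
      ngs_tabs[[nm]] <- family_frequency_table(cs, ref)
      df <- data.frame(sequence = names(cs$entries),
                       count = unname(cs$entries), stringsAsFactors = FALSE)
      write_tsv_atomic(df, out(paste0("ngs_collapsed_", nm, ".tsv")))
      files <- c(files, out(paste0("ngs_collapsed_", nm, ".tsv")))
    }
    tables$ngs_comparison <- compare_family_tables(ngs_tabs$agsc_lib,
                                                   ngs_tabs$tbc_lib)
    write_tsv_atomic(tables$ngs_comparison, out("ngs_family_comparison.tsv"))
    files <- c(files, out("ngs_family_comparison.tsv"))
  }

  # --- per-repertoire reports ---
  for (nm in names(screened)) {
    rp <- screened[[nm]]
    write_tsv_atomic(as_airr(rp), out(paste0("airr_", nm, ".tsv")))
    write_tsv_atomic(gene_usage(rp, "heavy"), out(paste0("gene_usage_", nm, ".tsv")))
    write_tsv_atomic(pairing_long(pairing_matrix(rp)),
                     out(paste0("pairing_", nm, ".tsv")))
    files <- c(files, out(paste0("airr_", nm, ".tsv")),
               out(paste0("gene_usage_", nm, ".tsv")),
               out(paste0("pairing_", nm, ".tsv")))
    if (sum(rp$annotation$annotated) >= 2L) {
      nwk <- to_newick(cdr_tree(rp))
      tmp <- paste0(out(paste0("tree_", nm, ".nwk")), ".tmp")
      writeLines(nwk, tmp)
      file.rename(tmp, out(paste0("tree_", nm, ".nwk")))
      files <- c(files, out(paste0("tree_", nm, ".nwk")))
    }
  }

  # --- comparative diversity (first two screened repertoires) ---
  if (length(screened) >= 2L) {
    a <- screened[[length(screened) - 1L]]; b <- screened[[length(screened)]]
    if (!is.null(screened$agsc_lib) && !is.null(screened$tbc_lib)) {
      a <- screened$agsc_lib; b <- screened$tbc_lib
    }
    su <- shared_unique(a, b, regions = cfg$regions)
    per_cdr <- do.call(rbind, lapply(c("cdr1", "cdr2", "cdr3"), function(cd) {
      v <- per_cdr_unique_shared(a, b, cd)
      data.frame(cdr = cd, unique_A = v[1], shared = v[2], unique_B = v[3],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    tables$unique_shared <- data.frame(
      comparison = paste(a$label, "vs", b$label),
      unique_A = su[1], shared = su[2], unique_B = su[3],
      paratope_groups_A = paratope_groups(a)$n_groups,
      paratope_groups_B = paratope_groups(b)$n_groups,
      row.names = NULL, stringsAsFactors = FALSE
    )
    tables$per_cdr <- per_cdr
    write_tsv_atomic(tables$unique_shared, out("unique_shared.tsv"))
    write_tsv_atomic(per_cdr, out("per_cdr_unique_shared.tsv"))
    files <- c(files, out("unique_shared.tsv"), out("per_cdr_unique_shared.tsv"))
  }

  # --- plate screening (if provided) ---
  if (!is.null(cfg$plate_file)) {
    plates <- read_plate_table(cfg$plate_file)
    qc <- do.call(rbind, lapply(plates, function(pl) {
      hits <- call_hits(pl, cfg$fold_threshold)
      pos <- pl$signals[pl$roles == "positive_control"]
      neg <- pl$signals[pl$roles == "negative_control"]
      rz <- if (length(pos) >= 2L && length(neg) >= 2L)
        robust_zprime(pos, neg) else list(z_prime = NA_real_, masked = NA)
      data.frame(plate_id = pl$plate_id,
                 n_samples = sum(pl$roles == "sample"),
                 n_hits = hits$n_hits, threshold = hits$threshold,
                 z_prime = rz$z_prime, masked = rz$masked,
                 stringsAsFactors = FALSE)
    }))
    tables$plate_qc <- qc
    write_tsv_atomic(qc, out("plate_qc.tsv"))
    files <- c(files, out("plate_qc.tsv"))
  }

  # --- manifest ---
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "sim")],
                               auto_unbox = TRUE, null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "bcrselect",
    version = as.character(utils::packageVersion("bcrselect")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "sim")],
    sim = if (!is.null(cfg$sim)) unclass(cfg$sim[setdiff(names(cfg$sim), "binding_model")]),
    binding_model = if (!is.null(cfg$sim)) unclass(cfg$sim$binding_model),
    config_hash = unname(tools::md5sum(tmp)),
    n_annotation_failures = vapply(screened, function(r) r$provenance$n_failed,
                                   integer(1)),
    files = basename(files)
  )
  unlink(tmp)
  mtmp <- paste0(out("manifest.json"), ".tmp")
  jsonlite::write_json(manifest, mtmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  file.rename(mtmp, out("manifest.json"))
  files <- c(files, out("manifest.json"))

  invisible(list(reference = ref, repertoires = screened, tables = tables,
                 manifest = manifest, files = files))
}
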