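make_vh <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  stopifnot(all(c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3") %in% names(df)))
  df
}

base_row <- function(cdr3 = "ARDY", fr1 = "EVQL") {
  make_vh(fr1 = fr1, cdr1 = "GFTF", fr2 = "WVRQ", cdr2 = "ISGG",
          fr3 = "RFTI", cdr3 = cdr3)
}

test_that("FR1-only differences collapse to one clonotype key", {
  rp <- fake_repertoire(rbind(base_row(fr1 = "EVQL"), base_row(fr1 = "QVQL")))
  k <- clone_keys(rp)
  expect_equal(k[[1]], k[[2]])
  # identical records give identical keys; one CDR3 aa apart separates them
  rp2 <- fake_repertoire(rbind(base_row("ARDY"), base_row("ARDY"),
                               base_row("ARDF")))
  k2 <- clone_keys(rp2)
  expect_equal(k2[[1]], k2[[2]])
  expect_false(k2[[1]] == k2[[3]])
})

test_that("unknown regions and chains are rejected", {
  rp <- fake_repertoire(base_row())
  expect_error(clone_keys(rp, regions = "fr4"), class = "argument_error")
  expect_error(clone_keys(rp, regions = "fr1"), class = "argument_error")
  expect_error(clone_keys(rp, chains = "lambda"), class = "argument_error")
})

test_that("unique_clones partitions correctly, including duplication", {
  rows <- rbind(base_row("AAAA"), base_row("BBBB"), base_row("CCCC"))
  rp <- fake_repertoire(rows)
  uc <- unique_clones(rp)
  expect_equal(uc$n_clones, 3)
  expect_true(all(lengths(uc$partition) == 1))
  # duplicated repertoire: same block count, doubled block sizes
  rp2 <- fake_repertoire(rbind(rows, rows))
  uc2 <- unique_clones(rp2)
  expect_equal(uc2$n_clones, 3)
  expect_true(all(lengths(uc2$partition) == 2))
})

test_that("partitions are disjoint and exhaustive on synthetic repertoires", {
  for (s in 1:3) {
    rp <- synthetic_annotated(n = 20, n_lineages = 3, seed = 600 + s)
    for (ch in list("heavy", c("heavy", "kappa"))) {
      uc <- unique_clones(rp, chains = ch)
      ids <- unlist(uc$partition, use.names = FALSE)
      expect_equal(sort(ids),
                   sort(rp$annotation$cell_id[rp$annotation$annotated]))
      expect_equal(anyDuplicated(ids), 0)
      # block count equals an independent set construction over keys
      expect_equal(uc$n_clones,
                   length(unique(clone_keys(rp, chains = ch))))
    }
  }
})

test_that("shared/unique counts equal set-theoretic oracles", {
  ra <- fake_repertoire(rbind(base_row("AAAA"), base_row("BBBB"),
                              base_row("CCCC")))
  rb <- fake_repertoire(rbind(base_row("BBBB"), base_row("DDDD")))
  expect_equal(unname(shared_unique(ra, rb)), c(2, 1, 1))
  # disjoint and identical key sets
  rc <- fake_repertoire(rbind(base_row("XXXX"), base_row("YYYY")))
  expect_equal(unname(shared_unique(ra, rc))[2], 0)
  expect_equal(unname(shared_unique(ra, ra)), c(0, 3, 0))
  # sharing identity on random synthetic repertoires
  r1 <- synthetic_annotated(n = 15, seed = 71)
  r2 <- synthetic_annotated(n = 15, seed = 72)
  for (regs in list("cdr3", c("cdr1", "cdr2", "cdr3", "fr2", "fr3"))) {
    su <- shared_unique(r1, r2, regions = regs)
    expect_equal(su[["unique_A"]] + su[["shared"]],
                 length(unique(clone_keys(r1, regs))))
    expect_equal(su[["unique_B"]] + su[["shared"]],
                 length(unique(clone_keys(r2, regs))))
  }
})

test_that("per-CDR sharing handles toy and empty repertoires", {
  ra <- fake_repertoire(rbind(base_row("AA"), base_row("BB")))
  rb <- fake_repertoire(rbind(base_row("BB"), base_row("CC")))
  expect_equal(unname(per_cdr_unique_shared(ra, rb, "cdr3")), c(1, 1, 1))
  expect_equal(unname(per_cdr_unique_shared(ra, ra, "cdr3")), c(0, 2, 0))
  empty <- fake_repertoire(base_row()[0, ])
  expect_equal(unname(per_cdr_unique_shared(ra, empty, "cdr3")), c(2, 0, 0))
})

test_that("paratope grouping counts planted paratopes", {
  rows <- NULL; krows <- NULL
  for (i in 1:5) for (rep in 1:3) {
    rows <- rbind(rows, base_row(cdr3 = strrep(LETTERS[i], 4)))
    krows <- rbind(krows, data.frame(fr1 = "M", cdr1 = paste0("Q", LETTERS[i]),
                                     fr2 = "L", cdr2 = "SS", fr3 = "V",
                                     cdr3 = "WQ", stringsAsFactors = FALSE))
  }
  rp <- fake_repertoire(rows, krows)
  pg <- paratope_groups(rp)
  expect_equal(pg$n_groups, 5)
  expect_true(all(lengths(pg$partition$partition) == 3))
  # all-identical and all-distinct edge cases
  same <- fake_repertoire(rbind(base_row(), base_row(), base_row()))
  expect_equal(paratope_groups(same)$n_groups, 1)
  dist <- fake_repertoire(rbind(base_row("AA"), base_row("BB"), base_row("CC")))
  expect_equal(paratope_groups(dist)$n_groups, 3)
})

test_that("pairing matrix tallies families and conserves totals", {
  rp <- fake_repertoire(rbind(base_row(), base_row(), base_row(), base_row()),
                        vh_family = c("HV1", "HV1", "HV2", "HV3"),
                        vk_family = c("KV1", "KV2", "KV1", "KV1"))
  m <- pairing_matrix(rp)
  expect_equal(sum(m), 4)
  expect_equal(m["HV1", "KV1"], 1)
  expect_equal(m["HV1", "KV2"], 1)
  expect_equal(m["HV2", "KV1"], 1)
  expect_equal(m["HV3", "KV1"], 1)
  single <- fake_repertoire(base_row(), vh_family = "HV4", vk_family = "KV3")
  ms <- pairing_matrix(single)
  expect_equal(sum(ms), 1)
  expect_equal(ms["HV4", "KV3"], 1)
})

test_that("exclusive pairs match a brute-force cell scan", {
  set.seed(9)
  fams_h <- paste0("HV", 1:4); fams_k <- paste0("KV", 1:3)
  rnd_rep <- function(n) {
    fake_repertoire(do.call(rbind, replicate(n, base_row(), simplify = FALSE)),
                    vh_family = sample(fams_h, n, replace = TRUE),
                    vk_family = sample(fams_k, n, replace = TRUE))
  }
  ra <- rnd_rep(12); rb <- rnd_rep(12)
  ma <- pairing_matrix(ra); mb <- pairing_matrix(rb)
  ex <- exclusive_pairs(ma, mb)
  # oracle: scan the full family grid
  oracle_a <- oracle_b <- oracle_both <- character(0)
  for (h in fams_h) for (k in fams_k) {
    ina <- h %in% rownames(ma) && k %in% colnames(ma) && ma[h, k] > 0
    inb <- h %in% rownames(mb) && k %in% colnames(mb) && mb[h, k] > 0
    key <- paste(h, k)
    if (ina && !inb) oracle_a <- c(oracle_a, key)
    if (inb && !ina) oracle_b <- c(oracle_b, key)
    if (ina && inb) oracle_both <- c(oracle_both, key)
  }
  expect_setequal(paste(ex$pairs_only_A$heavy_family, ex$pairs_only_A$kappa_family),
                  oracle_a)
  expect_setequal(paste(ex$pairs_only_B$heavy_family, ex$pairs_only_B$kappa_family),
                  oracle_b)
  expect_setequal(paste(ex$pairs_both$heavy_family, ex$pairs_both$kappa_family),
                  oracle_both)
  # identical matrices: no exclusives
  ex2 <- exclusive_pairs(ma, ma)
  expect_equal(nrow(ex2$pairs_only_A), 0)
  expect_equal(nrow(ex2$pairs_only_B), 0)
})

test_that("simulated libraries mirror the qualitative diversity patterns", {
  # (a) shuffling within the selected pool never loses family-pair variety;
  # (b) at matched sample size, the antigen-binding subset of the total-IgG
  #     combinatorial library spans fewer paratope groups than the AgSC one
  fam_of <- function(genes) sub("-.*$", "", genes)
  pairs_a_wins <- 0; paratope_wins <- 0; n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_cells = 4000, antigen_specific_fraction = 0.05,
                      n_founder_lineages = 8, igg_fraction = 0.5,
                      nonspecific_capture_rate = 1e-3, seed = 1200 + s)
    pool <- simulate_immune_response(ref9x8, cfg)
    igg <- deplete_igm_igd(pool)
    sf <- simulate_selection(igg, cfg, seed = cfg$seed + 1L)
    agsc <- build_library(sf$selected, "combinatorial", seed = cfg$seed + 2L)
    tbc <- build_library(igg, "combinatorial", seed = cfg$seed + 3L)
    # family pairs from ground-truth gene labels
    n_pairs <- function(recs)
      length(unique(paste(fam_of(recs$vh_gene), fam_of(recs$vk_gene))))
    if (n_pairs(agsc) >= n_pairs(sf$selected)) pairs_a_wins <- pairs_a_wins + 1
    m <- cfg$binding_model
    agsc_b <- assign_binding(agsc, m, seed = cfg$seed + 4L)
    tbc_b <- assign_binding(tbc, m, seed = cfg$seed + 5L)
    agsc_bind <- agsc_b[agsc_b$binds, , drop = FALSE]
    tbc_bind <- tbc_b[tbc_b$binds, , drop = FALSE]
    k <- min(nrow(agsc_bind), nrow(tbc_bind), 60L)
    if (k < 5) next
    ra <- suppressMessages(
      annotate_repertoire(agsc_bind[seq_len(k), , drop = FALSE], ref9x8, "agsc"))
    rt <- suppressMessages(
      annotate_repertoire(tbc_bind[seq_len(k), , drop = FALSE], ref9x8, "tbc"))
    if (paratope_groups(rt)$n_groups < paratope_groups(ra)$n_groups)
      paratope_wins <- paratope_wins + 1
  }
  expect_gte(pairs_a_wins, ceiling(n_seeds / 2))
  expect_gte(paratope_wins, ceiling(n_seeds / 2))
})
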