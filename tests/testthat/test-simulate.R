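test_that("config validation enforces proportions and CDR mutation bias", {
  expect_error(sim_config(antigen_specific_fraction = 1.2), "proportions")
  expect_error(sim_config(shm_rate_cdr = 0.001, shm_rate_fr = 0.01), "CDR bias")
  expect_error(binding_model(p_bind_cognate = 0.2, p_bind_both_specific = 0.5),
               "p_bind_cognate")
})

test_that("specific fraction is binomial around its target", {
  cfg <- sim_config(n_cells = 1e5, antigen_specific_fraction = 5e-4, seed = 21)
  pool <- simulate_immune_response(ref9x8, cfg)
  n_spec <- sum(pool$is_antigen_specific)
  mu <- 1e5 * 5e-4
  sdv <- sqrt(mu * (1 - 5e-4))
  expect_lt(abs(n_spec - mu), 3 * sdv)
  # zero fraction -> no specific records, no lineages
  cfg0 <- sim_config(n_cells = 500, antigen_specific_fraction = 0, seed = 3)
  p0 <- simulate_immune_response(ref9x8, cfg0)
  expect_equal(sum(p0$is_antigen_specific), 0)
  expect_true(all(is.na(p0$lineage_id)))
})

test_that("lineage labels exist iff a record is antigen-specific", {
  cfg <- sim_config(n_cells = 2000, antigen_specific_fraction = 0.05,
                    n_founder_lineages = 4, seed = 8)
  pool <- simulate_immune_response(ref9x8, cfg)
  expect_true(all(!is.na(pool$lineage_id[pool$is_antigen_specific])))
  expect_true(all(is.na(pool$lineage_id[!pool$is_antigen_specific])))
  expect_lte(length(unique(stats::na.omit(pool$lineage_id))), 4)
})

test_that("zero framework SHM leaves FR segments at germline", {
  cfg <- sim_config(n_cells = 40, antigen_specific_fraction = 1,
                    n_founder_lineages = 3, shm_rate_cdr = 0.05,
                    shm_rate_fr = 0, seed = 13)
  pool <- simulate_immune_response(ref9x8, cfg)
  g <- ref9x8$genes
  for (i in seq_len(nrow(pool))) {
    gh <- g[g$name == pool$vh_gene[i], ]
    for (r in c("fr1", "fr2", "fr3")) {
      s <- gh[[paste0(r, "_start")]] + 1L; e <- gh[[paste0(r, "_end")]]
      expect_identical(substr(pool$vh_nt[i], s, e), substr(gh$nt_sequence, s, e))
    }
  }
})

test_that("records always translate without internal stop codons", {
  cfg <- sim_config(n_cells = 60, antigen_specific_fraction = 1,
                    n_founder_lineages = 5, shm_rate_cdr = 0.08,
                    shm_rate_fr = 0.03, seed = 17)
  pool <- simulate_immune_response(ref9x8, cfg)
  aa <- bcrselect:::translate_nt(c(pool$vh_nt, pool$vk_nt))
  expect_false(any(grepl("*", aa, fixed = TRUE)))
})

test_that("IgM/IgD depletion keeps IgG records in original order", {
  pool <- fake_records(10, 2)
  pool$isotype <- c("IgG", "IgM/IgD", "IgM/IgD", "IgG", "IgM/IgD",
                    "IgG", "IgM/IgD", "IgG", "IgM/IgD", "IgM/IgD")
  kept <- deplete_igm_igd(pool)
  expect_equal(kept$cell_id, pool$cell_id[c(1, 4, 6, 8)])
  # all-IgG pool is the identity; empty pool stays empty
  expect_identical(deplete_igm_igd(fake_records(5, 1)), fake_records(5, 1))
  expect_equal(nrow(deplete_igm_igd(fake_records(5, 1)[0, ])), 0)
})

test_that("selection is exhaustive, exclusive and respects capture limits", {
  pool <- fake_records(500, 40)
  cfg <- sim_config(capture_efficiency = 1, nonspecific_capture_rate = 0)
  sf <- simulate_selection(pool, cfg, seed = 4)
  expect_setequal(sf$selected$cell_id, pool$cell_id[pool$is_antigen_specific])
  expect_equal(nrow(sf$selected) + nrow(sf$flow_through), nrow(pool))
  expect_true(all(sf$selected$compartment == "selected"))
  expect_true(all(sf$flow_through$compartment == "flow_through"))
  # conservation across arbitrary seeds and rates
  cfg2 <- sim_config(capture_efficiency = 0.7, nonspecific_capture_rate = 0.1)
  for (s in 1:5) {
    sf2 <- simulate_selection(pool, cfg2, seed = s)
    expect_setequal(c(sf2$selected$cell_id, sf2$flow_through$cell_id),
                    pool$cell_id)
  }
  # empty pool: empty outputs, no error
  sf0 <- simulate_selection(pool[0, ], cfg)
  expect_equal(nrow(sf0$selected), 0)
  expect_equal(nrow(sf0$flow_through), 0)
})

test_that("specific-cell loss matches 1 - capture_efficiency", {
  pool <- fake_records(4000, 2000)
  cfg <- sim_config(capture_efficiency = 0.98, nonspecific_capture_rate = 0)
  lost <- 0; tot <- 0
  for (s in 1:10) {
    sf <- simulate_selection(pool, cfg, seed = 100 + s)
    lost <- lost + sum(sf$flow_through$is_antigen_specific)
    tot <- tot + sum(pool$is_antigen_specific)
  }
  # pooled loss within 3 binomial SE of 2%
  expect_lt(abs(lost / tot - 0.02), 3 * sqrt(0.02 * 0.98 / tot))
})

test_that("enrichment ordering holds in at least 95% of 100 seeded runs", {
  pool <- fake_records(1000, 50)
  cfg <- sim_config(capture_efficiency = 0.98, nonspecific_capture_rate = 1e-3)
  ok <- 0
  input_frac <- mean(pool$is_antigen_specific)
  for (s in 1:100) {
    sf <- simulate_selection(pool, cfg, seed = s)
    sel_frac <- mean(sf$selected$is_antigen_specific)
    ft_frac <- mean(sf$flow_through$is_antigen_specific)
    if (isTRUE(sel_frac > input_frac && input_frac > ft_frac)) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("cognate libraries are untouched; combinatorial permutes kappa only", {
  cfg <- sim_config(n_cells = 50, antigen_specific_fraction = 1,
                    n_founder_lineages = 5, seed = 31)
  pool <- simulate_immune_response(ref9x8, cfg)
  cog <- build_library(pool, "cognate", seed = 1)
  expect_identical(cog$vk_nt, pool$vk_nt)
  expect_true(all(cog$pairing_origin == "cognate"))
  comb <- build_library(pool, "combinatorial", seed = 1)
  expect_identical(comb$vh_nt, pool$vh_nt)              # heavy fixed
  expect_identical(sort(comb$vk_nt), sort(pool$vk_nt))  # kappa multiset kept
  expect_true(all(comb$pairing_origin == "shuffled"))
  # 1-cell pool: only permutation is the identity
  one <- build_library(pool[1, ], "combinatorial", seed = 5)
  expect_identical(one$vk_nt, pool$vk_nt[1])
  expect_error(build_library(pool[0, ], "cognate"), "empty")
})

test_that("combinatorial both-specific fraction approaches f squared", {
  n <- 4000; f <- 0.3
  pool <- fake_records(n, round(n * f))
  both <- numeric(20)
  for (s in 1:20) {
    lib <- build_library(pool, "combinatorial", seed = s)
    both[s] <- mean(lib$vh_specific & lib$vk_specific)
  }
  se <- sqrt(f^2 * (1 - f^2) / n / 20)
  expect_lt(abs(mean(both) - f^2), 4 * se)
})

test_that("binding cases follow the model, including impossible binders", {
  pool <- fake_records(200, 0)
  pool$pairing_origin <- "shuffled"
  b <- assign_binding(pool, binding_model(), seed = 2)
  expect_false(any(b$binds))          # neither chain specific
  expect_false(any(b$functional))
  sure <- fake_records(50, 50)
  m1 <- binding_model(p_bind_cognate = 1, p_functional_given_bind_cognate = 1)
  b1 <- assign_binding(sure, m1, seed = 3)
  expect_true(all(b1$binds) && all(b1$functional))
})

test_that("mixed-pair binder rate matches its Bernoulli probability", {
  n <- 1e4
  pool <- fake_records(n, n)          # heavy specific everywhere
  pool$vk_specific <- FALSE           # kappa never specific -> mixed case
  pool$pairing_origin <- "shuffled"
  m <- binding_model(p_bind_mixed = 0.3)
  b <- assign_binding(pool, m, seed = 11)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(b$binds) - 0.3), 3 * se)
})

test_that("identical config and seed reproduce outputs byte-for-byte", {
  cfg <- sim_config(n_cells = 800, antigen_specific_fraction = 0.02, seed = 77)
  p1 <- simulate_immune_response(ref9x8, cfg)
  p2 <- simulate_immune_response(ref9x8, cfg)
  expect_identical(p1, p2)
  d <- withr::local_tempdir()
  write_repertoire_fasta(p1, file.path(d, "r1"))
  write_repertoire_fasta(p2, file.path(d, "r2"))
  expect_identical(readLines(file.path(d, "r1_heavy.fasta")),
                   readLines(file.path(d, "r2_heavy.fasta")))
  expect_identical(readLines(file.path(d, "r1_truth.tsv")),
                   readLines(file.path(d, "r2_truth.tsv")))
})
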