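test_that("simulated trees are binary, labelled and deterministic", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)
  t5 <- simulate_tree(5, seed = 2)
  expect_equal(t5$Nnode, 4L)              # internal = tips - 1 (binary)
  expect_true(all(t5$edge.length > 0))
  expect_identical(write_newick(simulate_tree(9, seed = 7)),
                   write_newick(simulate_tree(9, seed = 7)))
  expect_false(identical(write_newick(simulate_tree(9, seed = 7)),
                         write_newick(simulate_tree(9, seed = 8))))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("repertoire without events keeps exactly the ancestral families", {
  cfg <- simulation_config(n_genomes = 6, ancestral_family_count = 12,
                           gain_rate = 0, loss_rate = 0, seed = 3)
  tree <- simulate_tree(6, seed = 3)
  pm <- simulate_repertoire(tree, cfg)
  expect_equal(dim(pm), c(12L, 6L))
  expect_true(all(pm))
  ## gains without losses: core stays at the ancestral count
  cfg2 <- simulation_config(n_genomes = 6, ancestral_family_count = 12,
                            gain_rate = 8, loss_rate = 0, seed = 3)
  pm2 <- simulate_repertoire(tree, cfg2)
  expect_gte(nrow(pm2), 12L)
  expect_equal(length(core_families(pm2)), 12L)
})

test_that("new-families-per-genome matches a replicate-simulation oracle", {
  ## single-run estimate under the stated config ...
  cfg <- simulation_config(n_genomes = 10, ancestral_family_count = 50,
                           gain_rate = 2, loss_rate = 0.5, seed = 41)
  tree <- simulate_tree(10, seed = 41)
  est <- accumulation_curves(simulate_repertoire(tree, cfg), 50,
                             seed = 1)$new_per_genome_mean
  ## ... against the mean of independent re-simulations (fresh trees and
  ## repertoires per replicate seed)
  reps <- vapply(1:300, function(s) {
    cfg_s <- simulation_config(n_genomes = 10, ancestral_family_count = 50,
                               gain_rate = 2, loss_rate = 0.5, seed = 1000 + s)
    tr <- simulate_tree(10, seed = 1000 + s)
    pm <- simulate_repertoire(tr, cfg_s)
    accumulation_curves(pm, 10, seed = s)$new_per_genome_mean
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  ## the single run is one draw from the replicate distribution
  expect_lt(abs(est - mean(reps)), 3 * sd(reps))
  expect_gt(se, 0)
})

test_that("sequence simulation respects presence and zero-rate identity", {
  cfg <- simulation_config(n_genomes = 4, ancestral_family_count = 10,
                           gain_rate = 3, loss_rate = 0.2,
                           substitution_rate = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  ## truth consistency: every gene maps to exactly one family and matches
  ## the presence matrix
  expect_equal(anyDuplicated(sim$genes$gene_id), 0L)
  for (g in colnames(sim$presence)) {
    fams <- sim$genes$family_id[sim$genes$genome_id == g]
    expect_setequal(fams, rownames(sim$presence)[sim$presence[, g]])
  }
  ## no substitutions: all copies identical, expected identity 100
  for (f in rownames(sim$presence)) {
    copies <- sim$genes$nucleotide[sim$genes$family_id == f]
    expect_equal(length(unique(copies)), 1L)
  }
  ids <- sim$truth$expected_pairwise_identity
  expect_true(all(ids[!is.na(ids)] == 100))
})

test_that("realized identity tracks a direct Hamming comparison", {
  cfg <- simulation_config(n_genomes = 2, ancestral_family_count = 30,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.03, seed = 9)
  sim <- simulate_dataset(cfg)
  a <- sim$assemblies$g01[[1]]; b <- sim$assemblies$g02[[1]]
  expect_equal(nchar(a), nchar(b))
  ham <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  expect_equal(sim$truth$genome_identity["g01", "g02"], 100 * ham,
               tolerance = 1e-12)
  ## identity symmetric with unit diagonal
  ids <- sim$truth$expected_pairwise_identity
  expect_equal(ids, t(ids))
  expect_equal(unname(diag(ids)), rep(100, 2))
})

test_that("translated proteins are stop-free and codon-consistent", {
  cfg <- simulation_config(n_genomes = 3, ancestral_family_count = 15,
                           gain_rate = 2, loss_rate = 0.1,
                           substitution_rate = 0.08, seed = 21)
  sim <- simulate_dataset(cfg)
  expect_true(all(nchar(sim$genes$nucleotide) %% 3 == 0))
  expect_false(any(grepl("\\*", sim$genes$protein)))
  expect_equal(nchar(sim$genes$protein) * 3, nchar(sim$genes$nucleotide))
  expect_true(all(nchar(sim$genes$protein) >= 30))
})

test_that("host labels cover all tips and split at the root by default", {
  cfg <- simulation_config(n_genomes = 8, seed = 11)
  tree <- simulate_tree(8, seed = 11)
  hosts <- corepan:::.assign_hosts(tree, cfg)
  expect_setequal(names(hosts), tree$tip.label)
  expect_setequal(unique(unname(hosts)), c("bee", "human"))
  ## each host group is a clade below the root
  root_kids <- tree$edge[tree$edge[, 1] == 9L, 2]
  clade1 <- if (root_kids[1] <= 8) tree$tip.label[root_kids[1]] else
    ape::extract.clade(tree, root_kids[1])$tip.label
  expect_equal(length(unique(hosts[clade1])), 1L)
})

test_that("simulation output is deterministic and round-trips via files", {
  cfg <- simulation_config(n_genomes = 4, ancestral_family_count = 8,
                           gain_rate = 1, loss_rate = 0.1,
                           substitution_rate = 0.02, seed = 31)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$assemblies, s2$assemblies)

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_simulation(s1, d1); write_simulation(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("hosts.tsv", "tree.nwk", "truth.json") %in% f1))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  ## byte-faithful sequence round-trip through the readers
  asm <- read_genome_set(file.path(d1, "assemblies"))
  expect_equal(asm$g01[[1]], unname(s1$assemblies$g01[[1]]))
  gt <- read_gene_set(file.path(d1, "proteins"), "aa")
  expect_setequal(gt$gene_id, s1$genes$gene_id)
  expect_equal(gt$protein[match(s1$genes$gene_id, gt$gene_id)],
               s1$genes$protein)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_genomes = 1), ">= 2")
  expect_error(simulation_config(ancestral_family_count = 0), ">= 1")
  expect_error(simulation_config(gain_rate = -1), ">= 0")
  expect_error(simulation_config(substitution_rate = 1), "in \\[0, 1\\)")
  expect_error(simulation_config(mean_gene_length_aa = 10), ">= 30")
})

test_that("end-to-end family recovery meets the F1 target", {
  cfg <- simulation_config(n_genomes = 10, ancestral_family_count = 40,
                           gain_rate = 5, loss_rate = 0.05,
                           substitution_rate = 0.03, seed = 61)
  sim <- simulate_dataset(cfg)
  gt <- gene_table(sim$genes$gene_id, sim$genes$genome_id, sim$genes$protein)
  fams <- build_families(gt)
  pred <- as.integer(factor(fams$gene_index[gt$gene_id]))
  truth <- as.integer(factor(sim$truth$gene_family[gt$gene_id]))
  expect_gte(pair_f1(pred, truth), 0.95)
})
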