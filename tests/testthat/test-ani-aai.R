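test_that("genome fragmentation follows the window and remainder rules", {
  f1 <- fragment_genome(c(c1 = random_dna(3060)))
  expect_equal(nrow(f1), 3L)
  expect_equal(unique(nchar(f1$seq)), 1020L)
  expect_equal(f1$start, c(0L, 1020L, 2040L))

  set.seed(1)
  f2 <- fragment_genome(c(c1 = random_dna(1100)))   # 80-nt tail dropped
  expect_equal(nrow(f2), 1L)
  f3 <- fragment_genome(c(c1 = random_dna(1150)))   # 130-nt tail kept
  expect_equal(nrow(f3), 2L)
  expect_equal(nchar(f3$seq), c(1020L, 130L))
  ## multiple contigs fragment independently
  f4 <- fragment_genome(c(a = random_dna(1020), b = random_dna(2040)))
  expect_equal(table(f4$contig)[["b"]], 2L)
  expect_error(fragment_genome(character(0)), "empty assembly")
})

test_that("self-ANI is 100 with all fragments retained", {
  set.seed(3)
  g <- c(c1 = random_dna(8000))
  r <- ani(g, g)
  expect_equal(r$ani, 100)
  expect_equal(unname(r$fragments_retained), unname(r$fragments_total))
})

test_that("ANI recovers the realized divergence on synthetic pairs", {
  cfg <- simulation_config(n_genomes = 2, ancestral_family_count = 60,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.02, seed = 19)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth$genome_identity["g01", "g02"]
  r <- ani(sim$assemblies$g01, sim$assemblies$g02)
  expect_lt(abs(r$ani - truth), 0.3)
  ## symmetry under the reciprocal-mean definition
  r2 <- ani(sim$assemblies$g02, sim$assemblies$g01)
  expect_equal(r$ani, r2$ani, tolerance = 1e-12)
})

test_that("ANI degrades monotonically with the substitution rate", {
  vals <- vapply(c(0, 0.01, 0.02, 0.05), function(rate) {
    cfg <- simulation_config(n_genomes = 2, ancestral_family_count = 25,
                             gain_rate = 0, loss_rate = 0,
                             substitution_rate = rate, seed = 50)
    sim <- simulate_dataset(cfg)
    ani(sim$assemblies$g01, sim$assemblies$g02)$ani
  }, numeric(1))
  expect_equal(vals[1], 100)
  expect_true(all(diff(vals) < 0))
})

test_that("pairs below 5% divergence sit above the 95% species cutoff", {
  cfg <- simulation_config(n_genomes = 2, ancestral_family_count = 25,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.01, seed = 77)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth$genome_identity["g01", "g02"]
  expect_gt(truth, 95)           # the stated world: < 5% divergence
  expect_gt(ani(sim$assemblies$g01, sim$assemblies$g02)$ani, 95)
})

test_that("ANI is undefined (classed error) when nothing aligns", {
  set.seed(4)
  a <- c(c1 = random_dna(1500))
  b <- c(c1 = strrep("T", 200))
  expect_error(ani(a, b), class = "corepan_undefined_distance")
})

test_that("identical proteomes give AAI 100", {
  set.seed(6)
  p <- setNames(vapply(1:8, function(i) random_protein(sample(60:150, 1)),
                       character(1)), paste0("p", 1:8))
  r <- aai(p, p)
  expect_equal(r$aai, 100)
  expect_equal(unname(r$hits_retained["forward"]), 8L)
})

test_that("directional mean averages constructed best-hit identities", {
  ## two query proteins whose best hits are ~80% and ~90% identical
  set.seed(13)
  q1 <- random_protein(100); q2 <- random_protein(100)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- setdiff(c("A","G","L","V","K","R"), ch[i])[1]
    paste(ch, collapse = "")
  }
  s1 <- mut(q1, 20); s2 <- mut(q2, 10)
  prot <- scoring_scheme("protein")
  id1 <- local_align(q1, s1, prot)$identity_pct
  id2 <- local_align(q2, s2, prot)$identity_pct
  r <- aai(c(q1 = q1, q2 = q2), c(s1 = s1, s2 = s2), reciprocal = FALSE)
  expect_equal(r$aai, mean(c(id1, id2)), tolerance = 1e-9)
})

test_that("AAI filters remove weak, short and low-coverage hits", {
  prot <- scoring_scheme("protein")
  set.seed(17)
  anchor_q <- random_protein(100)
  anchor_s <- anchor_q
  ## (i) identity < 30: a ~25%-identity pair must not contribute
  weak_q <- random_protein(100)
  weak_s <- random_protein(100)
  r1 <- aai(c(a = anchor_q, w = weak_q), c(a = anchor_s, w2 = weak_s),
            reciprocal = FALSE, prefilter = FALSE)
  expect_equal(r1$aai, 100)          # only the anchor pair survives
  expect_equal(unname(r1$hits_retained["forward"]), 1L)
  ## (ii) alignment length < 30 aa
  short_q <- "MKLVWREPLYAGHITDNQSCFMKLVW"      # 26 aa, identical copy in subject
  r2 <- aai(c(a = anchor_q, s = short_q), c(a = anchor_s, s = short_q),
            reciprocal = FALSE, prefilter = FALSE)
  expect_equal(unname(r2$hits_retained["forward"]), 1L)
  ## (iii) < 70% of the query protein aligned
  half <- substr(anchor_q, 1, 40)              # 40% of the 100-aa query
  r3 <- aai(c(a = anchor_q), c(h = half), reciprocal = TRUE,
            prefilter = FALSE)
  ## forward direction fails coverage, reverse (40-aa query fully aligned)
  ## passes: reciprocal mean uses the defined direction only
  expect_equal(r3$forward_mean_identity, NA_real_)
  expect_equal(r3$reverse_mean_identity, 100)
  expect_equal(r3$aai, 100)
  ## both directions empty -> classed error
  expect_error(aai(c(a = random_protein(40)), c(b = strrep("W", 40)),
                   prefilter = FALSE),
               class = "corepan_undefined_distance")
})

test_that("AAI is symmetric and matches truth on simulated proteomes", {
  cfg <- simulation_config(n_genomes = 2, ancestral_family_count = 30,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.02, seed = 23)
  sim <- simulate_dataset(cfg)
  pr <- split_proteomes(gene_table(sim$genes$gene_id, sim$genes$genome_id,
                                   sim$genes$protein))
  r_ab <- aai(pr$g01, pr$g02)
  r_ba <- aai(pr$g02, pr$g01)
  expect_equal(r_ab$aai, r_ba$aai, tolerance = 1e-12)
  expect_gt(r_ab$aai, 90)   # 2% nt divergence -> high protein identity
  expect_equal(unname(r_ab$hits_retained["forward"]), 30L)
})

test_that("pairwise matrix is symmetric with unit diagonal", {
  cfg <- simulation_config(n_genomes = 3, ancestral_family_count = 20,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.02, seed = 29)
  sim <- simulate_dataset(cfg)
  pr <- split_proteomes(gene_table(sim$genes$gene_id, sim$genes$genome_id,
                                   sim$genes$protein))
  m <- pairwise_identity_matrix(pr, "aai")
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
})
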