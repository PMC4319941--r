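make_genes <- function(seqs, genome = "g1") {
  gene_table(names(seqs), rep(genome, length(seqs)), unname(seqs))
}

test_that("homology verdict applies the strict 50/50 rule", {
  prot <- scoring_scheme("protein")
  set.seed(5)
  p100 <- random_protein(100)
  v <- homology_pair_verdict(p100, p100, prot)
  expect_equal(v$identity_pct, 100)
  expect_equal(v$longer_gene_coverage, 1)
  expect_true(v$same_family)

  ## perfect 100-aa match inside a 300-aa protein: coverage 1/3 fails
  p300 <- paste0(random_protein(100), p100, random_protein(100))
  v2 <- homology_pair_verdict(p100, p300, prot)
  expect_equal(v2$identity_pct, 100)
  expect_equal(v2$longer_gene_coverage, 100 / 300, tolerance = 1e-9)
  expect_false(v2$same_family)

  expect_error(homology_pair_verdict("", p100), "missing protein")
})

test_that("identity exactly at the threshold is rejected (strict >)", {
  ## interior mismatches flanked by matches: identity exactly 50% over
  ## full coverage ("above 50%" must fail)
  nt <- scoring_scheme("nucleotide", match = 3, mismatch = -1,
                       gap_open = -50, gap_extend = -50)
  aln <- local_align("ACCA", "AGGA", nt)
  expect_equal(aln$identity_pct, 50)
  expect_equal(aln$query_coverage, 1)
  expect_false(aln$identity_pct > 50 && aln$query_coverage > 0.5)
})

test_that("families form single-linkage connected components", {
  prot <- scoring_scheme("protein")
  set.seed(9)
  base <- random_protein(120)
  seqs <- c(A = base, B = base, C = random_protein(120))
  fams <- build_families(make_genes(seqs), prot)
  expect_equal(length(unique(fams$members$family_id)), 2L)
  expect_equal(fams$gene_index[["A"]], fams$gene_index[["B"]])

  ## transitivity: A-B linked, B-C linked, A-C not => one family.
  ## Mutation chain: each step keeps ~60% identity, the composition drops
  ## below the 50% threshold.
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  mutate_aa <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < p)
    for (i in hit) ch[i] <- sample(setdiff(aa20, ch[i]), 1)
    paste(ch, collapse = "")
  }
  set.seed(101)
  A <- random_protein(150)
  B <- mutate_aa(A, 0.40)
  C <- mutate_aa(B, 0.40)
  vAB <- homology_pair_verdict(A, B, prot)$same_family
  vBC <- homology_pair_verdict(B, C, prot)$same_family
  vAC <- homology_pair_verdict(A, C, prot)$same_family
  expect_true(vAB && vBC && !vAC)
  vf <- build_families(make_genes(c(A = A, B = B, C = C)), prot)
  expect_equal(length(unique(vf$members$family_id)), 1L)
})

test_that("clustering equals the brute-force igraph oracle on random sets", {
  prot <- scoring_scheme("protein")
  set.seed(21)
  for (rep in 1:6) {
    n_fam <- sample(3:6, 1)
    ancestors <- replicate(n_fam, random_protein(sample(60:120, 1)))
    genes <- unlist(lapply(seq_len(n_fam), function(f) {
      n_mem <- sample(1:4, 1)
      setNames(
        vapply(seq_len(n_mem), function(i) {
          ch <- strsplit(ancestors[f], "")[[1]]
          mut <- which(runif(length(ch)) < 0.1)
          ch[mut] <- sample(c("A","C","D","E","F","G","H","I","K","L"),
                            length(mut), replace = TRUE)
          paste(ch, collapse = "")
        }, character(1)),
        sprintf("f%d_m%d", f, seq_len(n_mem)))
    }))
    gt <- make_genes(genes)
    got <- build_families(gt, prot)
    oracle <- ref_cluster(gt, prot)
    pred <- as.integer(factor(got$gene_index[gt$gene_id]))
    expect_true(same_partition(pred, oracle))
    ## prefilter losslessness: exact mode gives the identical partition
    exact <- build_families(gt, prot, prefilter = FALSE)
    expect_identical(got$members, exact$members)
  }
})

test_that("partition property holds and representatives are longest members", {
  prot <- scoring_scheme("protein")
  set.seed(2)
  base <- random_protein(100)
  seqs <- c(gX = paste0(base, random_protein(50)),  # 150 aa
            gB = base,                              # 100 aa
            gA = base)                              # 100 aa
  fams <- build_families(make_genes(seqs), prot)
  m <- fams$members
  expect_equal(nrow(m), 3L)                       # every gene exactly once
  expect_equal(anyDuplicated(m$gene_id), 0L)
  f <- unique(m$family_id)
  expect_length(f, 1L)
  expect_equal(select_representative(fams, f), "gX")   # longest wins
  ## tie on length -> lexicographically smallest id
  fams2 <- build_families(make_genes(c(gX = base, gA = base)), prot)
  expect_equal(select_representative(fams2, fams2$members$family_id[1]), "gA")
  expect_error(select_representative(fams, "FAMnope"), "unknown")
  expect_error(build_families(gene_table(c("a", "a"), c("g", "g"),
                                         c("MKL", "MKL"))), "duplicate")
})

test_that("simulated gene sets are recovered at low divergence", {
  cfg <- simulation_config(n_genomes = 5, ancestral_family_count = 10,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.01, seed = 33)
  sim <- simulate_dataset(cfg)
  gt <- gene_table(sim$genes$gene_id, sim$genes$genome_id, sim$genes$protein)
  fams <- build_families(gt)
  pred <- as.integer(factor(fams$gene_index[gt$gene_id]))
  truth <- as.integer(factor(sim$truth$gene_family[gt$gene_id]))
  expect_true(same_partition(pred, truth))
})

test_that("six-frame rescue flips only absences and finds deleted ORFs", {
  cfg <- simulation_config(n_genomes = 3, ancestral_family_count = 8,
                           gain_rate = 0, loss_rate = 0,
                           substitution_rate = 0.01, seed = 14)
  sim <- simulate_dataset(cfg)
  gt <- gene_table(sim$genes$gene_id, sim$genes$genome_id, sim$genes$protein)
  ## drop one annotated gene from genome g01
  victim <- gt$gene_id[gt$genome_id == "g01"][1]
  gt_cut <- gt[gt$gene_id != victim, ]
  fams <- build_families(gt_cut)
  pm <- presence_matrix(fams, genomes = colnames(sim$presence))
  missing_fam <- rownames(pm)[!pm[, "g01"]]
  expect_length(missing_fam, 1L)
  res <- rescue_missing_members(fams, sim$assemblies, presence = pm)
  expect_true(res$presence[missing_fam, "g01"])       # rescued
  expect_true(all(res$presence | !pm))                # presence-monotone
  ## idempotence on complete annotation
  fams_full <- build_families(gt)
  pm_full <- presence_matrix(fams_full)
  res2 <- rescue_missing_members(fams_full, sim$assemblies, presence = pm_full)
  expect_identical(res2$presence, pm_full)
  expect_equal(nrow(res2$rescued), 0L)
  ## unrelated genome stays absent
  alien <- list(zz = c(c1 = random_dna(3000)))
  pm3 <- cbind(pm_full, zz = FALSE)
  res3 <- rescue_missing_members(fams_full, c(sim$assemblies, alien),
                                 presence = pm3)
  expect_false(any(res3$presence[, "zz"]))
})
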