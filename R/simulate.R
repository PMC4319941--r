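## Genome-evolution simulator: a Yule birth tree, a gene repertoire
## evolving by gain/loss along its branches, and codon-structured gene
## sequences diverging by per-site substitution. Every downstream stage
## (families, pan/core, ANI/AAI, tree statistics, host cores) can be
## checked against the recorded ground truth.
##
## One global seed drives named sub-streams (tree, repertoire, sequences)
## so each stage is independently reproducible.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.NT <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe a desk-scale clade loosely emulating a bacterial
#' genus: 10 genomes, 300 ancestral gene families, ongoing gene gain
#' (events per unit branch length) with a small per-family loss rate, 5%
#' per-site substitution per unit branch length, and mean gene length 110
#' aa. Host labels are assigned to the two clades below the root (or at
#' random with `host_assignment = "random"`).
#'
#' @param n_genomes Number of tips (>= 2).
#' @param ancestral_family_count Families present at the root (>= 1).
#' @param gain_rate Gene-family gains per unit branch length (>= 0).
#' @param loss_rate Per-family loss rate per unit branch length (>= 0).
#' @param substitution_rate Per-site substitution rate per unit branch
#'   length, in [0, 1).
#' @param mean_gene_length_aa Mean gene length in amino acids (>= 30).
#' @param host_labels Labels for the host clades (default bee/human).
#' @param host_assignment `"deepest"` (the two clades below the root) or
#'   `"random"`.
#' @param spacer_range Intergenic spacer length range in nt.
#' @param seed Integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 10, ancestral_family_count = 300,
                              gain_rate = 25, loss_rate = 0.03,
                              substitution_rate = 0.05,
                              mean_gene_length_aa = 110,
                              host_labels = c("bee", "human"),
                              host_assignment = c("deepest", "random"),
                              spacer_range = c(50, 200), seed = 1) {
  host_assignment <- match.arg(host_assignment)
  if (n_genomes < 2) stop("n_genomes must be >= 2", call. = FALSE)
  if (ancestral_family_count < 1)
    stop("ancestral_family_count must be >= 1", call. = FALSE)
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0", call. = FALSE)
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must be in [0, 1)", call. = FALSE)
  if (mean_gene_length_aa < 30)
    stop("mean_gene_length_aa must be >= 30", call. = FALSE)
  if (abs(seed) > 2^31 - 10) stop("seed out of integer range", call. = FALSE)
  structure(list(n_genomes = as.integer(n_genomes),
                 ancestral_family_count = as.integer(ancestral_family_count),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 substitution_rate = substitution_rate,
                 mean_gene_length_aa = mean_gene_length_aa,
                 host_labels = host_labels,
                 host_assignment = host_assignment,
                 spacer_range = spacer_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starting from two lineages, a uniformly chosen tip is split until
#' `n_tips` is reached; every edge receives an independent Exp(1) branch
#' length. The result is a binary rooted `phylo` tree with `n_tips - 1`
#' internal nodes, deterministic for a fixed seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object with tip labels `g01`, `g02`, ...
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  with_seed(seed, {
    ## grow a nested-list topology by splitting random tips
    topo <- list(1L, 2L)
    ntip <- 2L
    while (ntip < n_tips) {
      ntip <- ntip + 1L
      target <- sample.int(ntip - 1L, 1L)
      cnt <- 0L
      split_tip <- function(node) {
        if (is.integer(node)) {
          cnt <<- cnt + 1L
          if (cnt == target) return(list(node, ntip))
          return(node)
        }
        list(split_tip(node[[1]]), split_tip(node[[2]]))
      }
      topo <- split_tip(topo)
    }
    fmt <- function(node) {
      if (is.integer(node))
        return(sprintf("g%02d:%.6f", node, stats::rexp(1)))
      sprintf("(%s,%s):%.6f", fmt(node[[1]]), fmt(node[[2]]), stats::rexp(1))
    }
    nwk <- sprintf("(%s,%s);", fmt(topo[[1]]), fmt(topo[[2]]))
    ape::read.tree(text = nwk)
  })
}

## preorder edge list (root first) with parent/child node ids
.preorder_edges <- function(tree) {
  root <- length(tree$tip.label) + 1L
  ord <- ape::reorder.phylo(tree, "cladewise")
  ord$edge
}

#' Simulate gene-family gain and loss along a tree
#'
#' Ancestral families are present at the root. Along each branch every
#' present family is lost with probability `1 - exp(-loss_rate * bl)` and
#' `Poisson(gain_rate * bl)` new families arise, each present in the
#' subtree below (until lost again). Families absent from every tip are
#' dropped.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param config A [simulation_config()].
#' @return Logical presence matrix (families x tips).
#' @export
simulate_repertoire <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    ntip <- length(tree$tip.label)
    edges <- .preorder_edges(tree)
    blen <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                   paste(tree$edge[, 1], tree$edge[, 2]))]
    anc <- sprintf("AF%04d", seq_len(config$ancestral_family_count))
    state <- list()
    state[[as.character(ntip + 1L)]] <- anc
    gained_total <- 0L
    tip_sets <- vector("list", ntip)
    for (e in seq_len(nrow(edges))) {
      par <- as.character(edges[e, 1]); chd <- edges[e, 2]
      present <- state[[par]]
      bl <- blen[e]
      p_loss <- 1 - exp(-config$loss_rate * bl)
      if (length(present) && p_loss > 0)
        present <- present[stats::runif(length(present)) >= p_loss]
      n_gain <- stats::rpois(1, config$gain_rate * bl)
      if (n_gain > 0) {
        new <- sprintf("GF%05d", gained_total + seq_len(n_gain))
        gained_total <- gained_total + n_gain
        present <- c(present, new)
      }
      if (chd <= ntip) tip_sets[[chd]] <- present
      else state[[as.character(chd)]] <- present
    }
    fams <- sort(unique(unlist(tip_sets)))
    m <- matrix(FALSE, length(fams), ntip,
                dimnames = list(fams, tree$tip.label))
    for (t in seq_len(ntip))
      m[match(tip_sets[[t]], fams), t] <- TRUE
    m
  })
}

.random_codons <- function(n_codons) {
  codons <- apply(expand.grid(.NT, .NT, .NT), 1, paste, collapse = "")
  codons <- setdiff(codons, .STOP_CODONS)
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

## mutate a sequence: each site substituted with prob p; in coding
## sequences a mutation creating an in-frame stop codon is redrawn.
.mutate_seq <- function(chars, p, coding) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (!length(hit)) return(chars)
  for (i in hit) {
    old <- chars[i]
    repeat {
      new <- sample(setdiff(.NT, chars[i]), 1)
      if (!coding) { chars[i] <- new; break }
      cs <- ((i - 1) %/% 3) * 3 + 1
      codon <- chars[cs:(cs + 2)]
      codon[i - cs + 1] <- new
      if (!paste(codon, collapse = "") %in% .STOP_CODONS) {
        chars[i] <- new
        break
      }
      ## stop codon: a different base always exists that avoids it
    }
  }
  chars
}

#' Simulate sequences for a gene repertoire
#'
#' Each family receives an ancestral codon-structured nucleotide sequence
#' (uniform over the 61 non-stop codons; length Poisson around
#' `mean_gene_length_aa`, minimum 30 aa). Sequences and intergenic spacers
#' mutate independently per site along each branch with probability
#' `1 - exp(-substitution_rate * bl)`; a mutation that would create an
#' in-frame stop codon is redrawn. Tip genomes are the concatenation of
#' their present genes, in family order, separated by the (evolved)
#' spacers, so an assembly is never identical to its concatenated CDS set.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param presence Logical presence matrix from [simulate_repertoire()].
#' @param config A [simulation_config()].
#' @return A `genome_simulation`: list with `tree`, `presence`, `genes`
#'   (data frame `genome_id`, `gene_id`, `family_id`, `nucleotide`,
#'   `protein`), `assemblies`, `host_labels`, `truth` (see
#'   [simulation_truth()]).
#' @export
simulate_sequences <- function(tree, presence, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!setequal(colnames(presence), tree$tip.label))
    stop("presence matrix columns must match tree tips", call. = FALSE)
  with_seed(config$seed + 2L, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    fams <- rownames(presence)
    nf <- length(fams)

    ## ancestral material: genes + one spacer per family slot + leading spacer
    gene_len <- pmax(30L, stats::rpois(nf, config$mean_gene_length_aa))
    anc_genes <- lapply(gene_len, function(L)
      strsplit(.random_codons(L), "", fixed = TRUE)[[1]])
    spacer_len <- sample(config$spacer_range[1]:config$spacer_range[2],
                         nf + 1L, replace = TRUE)
    anc_spacers <- lapply(spacer_len, function(L)
      strsplit(paste(sample(.NT, L, replace = TRUE), collapse = ""),
               "", fixed = TRUE)[[1]])

    edges <- .preorder_edges(tree)
    blen <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                   paste(tree$edge[, 1], tree$edge[, 2]))]
    node_genes <- list(); node_spacers <- list()
    node_genes[[as.character(root)]] <- anc_genes
    node_spacers[[as.character(root)]] <- anc_spacers
    tip_genes <- vector("list", ntip)
    tip_spacers <- vector("list", ntip)
    for (e in seq_len(nrow(edges))) {
      par <- as.character(edges[e, 1]); chd <- edges[e, 2]
      p <- 1 - exp(-config$substitution_rate * blen[e])
      g <- lapply(node_genes[[par]], .mutate_seq, p = p, coding = TRUE)
      s <- lapply(node_spacers[[par]], .mutate_seq, p = p, coding = FALSE)
      if (chd <= ntip) {
        tip_genes[[chd]] <- g
        tip_spacers[[chd]] <- s
      } else {
        node_genes[[as.character(chd)]] <- g
        node_spacers[[as.character(chd)]] <- s
      }
    }

    tips <- tree$tip.label
    genes <- list(); assemblies <- list()
    for (t in seq_len(ntip)) {
      present <- which(presence[, tips[t]])
      nt_seqs <- vapply(tip_genes[[t]][present], paste, character(1),
                        collapse = "")
      gid <- paste0(tips[t], "|", fams[present])
      prot <- vapply(nt_seqs, function(s)
        as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE)),
        character(1), USE.NAMES = FALSE)
      genes[[t]] <- data.frame(genome_id = tips[t], gene_id = gid,
                               family_id = fams[present],
                               nucleotide = unname(nt_seqs), protein = prot,
                               stringsAsFactors = FALSE)
      parts <- character(2 * length(present) + 1L)
      parts[1] <- paste(tip_spacers[[t]][[1]], collapse = "")
      for (k in seq_along(present)) {
        parts[2 * k] <- nt_seqs[k]
        parts[2 * k + 1] <- paste(tip_spacers[[t]][[present[k] + 1L]],
                                  collapse = "")
      }
      assemblies[[tips[t]]] <- stats::setNames(paste(parts, collapse = ""),
                                               paste0(tips[t], "_c1"))
    }
    genes <- do.call(rbind, genes)

    hosts <- .assign_hosts(tree, config)
    sim <- structure(
      list(config = config, tree = tree, presence = presence, genes = genes,
           assemblies = assemblies, host_labels = hosts),
      class = "genome_simulation")
    sim$truth <- simulation_truth(sim)
    sim
  })
}

.assign_hosts <- function(tree, config) {
  tips <- tree$tip.label
  if (config$host_assignment == "random") {
    labs <- sample(config$host_labels, length(tips), replace = TRUE)
    return(stats::setNames(labs, tips))
  }
  ## deepest: the clades below the root, labels recycled across them
  root <- length(tips) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  out <- stats::setNames(rep(config$host_labels[1], length(tips)), tips)
  for (i in seq_along(kids)) {
    lab <- config$host_labels[((i - 1) %% length(config$host_labels)) + 1]
    if (kids[i] <= length(tips)) out[tips[kids[i]]] <- lab
    else out[ape::extract.clade(tree, kids[i])$tip.label] <- lab
  }
  out
}

#' Ground truth of a simulation
#'
#' Recomputes the truth bundle from the realized sequences: the true
#' family partition, per-pair expected nucleotide identity over shared
#' genes (Hamming, since gene alignments are gap-free by construction),
#' and the realized whole-genome identity for pairs with identical family
#' content.
#'
#' @param sim A `genome_simulation`.
#' @return List with `tree_newick`, `presence`, `host_labels`,
#'   `gene_family` (gene id -> true family), `expected_pairwise_identity`
#'   and `genome_identity` (percent matrices; `genome_identity` is NA for
#'   pairs with unequal gene content).
#' @export
simulation_truth <- function(sim) {
  tips <- colnames(sim$presence)
  n <- length(tips)
  cds_id <- gen_id <- matrix(100, n, n, dimnames = list(tips, tips))
  split_genes <- split(sim$genes, sim$genes$genome_id)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    gi <- split_genes[[tips[i]]]; gj <- split_genes[[tips[j]]]
    shared <- intersect(gi$family_id, gj$family_id)
    if (length(shared)) {
      a <- paste(gi$nucleotide[match(shared, gi$family_id)], collapse = "")
      b <- paste(gj$nucleotide[match(shared, gj$family_id)], collapse = "")
      cds_id[i, j] <- cds_id[j, i] <- 100 * .hamming_identity(a, b)
    } else cds_id[i, j] <- cds_id[j, i] <- NA_real_
    ga <- sim$assemblies[[tips[i]]]; gb <- sim$assemblies[[tips[j]]]
    if (identical(sim$presence[, i], sim$presence[, j]) &&
        nchar(ga) == nchar(gb)) {
      gen_id[i, j] <- gen_id[j, i] <- 100 * .hamming_identity(ga, gb)
    } else gen_id[i, j] <- gen_id[j, i] <- NA_real_
  }
  list(tree_newick = ape::write.tree(sim$tree),
       presence = sim$presence,
       host_labels = sim$host_labels,
       gene_family = stats::setNames(sim$genes$family_id, sim$genes$gene_id),
       expected_pairwise_identity = cds_id,
       genome_identity = gen_id)
}

.hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  mean(va == vb)
}

#' Run a full simulation
#'
#' Convenience wrapper: tree, repertoire and sequences from one
#' [simulation_config()].
#'
#' @param config A [simulation_config()].
#' @return A `genome_simulation`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  tree <- simulate_tree(config$n_genomes, seed = config$seed)
  presence <- simulate_repertoire(tree, config)
  simulate_sequences(tree, presence, config)
}

#' @export
print.genome_simulation <- function(x, ...) {
  cat(sprintf(
    "<genome_simulation> %d genomes, %d families, %d genes (seed %d)\n",
    ncol(x$presence), nrow(x$presence), nrow(x$genes), x$config$seed))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits per-genome assembly, CDS and protein FASTA files, a hosts TSV, a
#' Newick tree and a truth JSON under `dir`. Output is deterministic:
#' identical simulations produce byte-identical files.
#'
#' @param sim A `genome_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("assemblies", "cds", "proteins"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  for (g in colnames(sim$presence)) {
    write_fasta(as.list(sim$assemblies[[g]]),
                file.path(dir, "assemblies", paste0(g, ".fna")))
    rows <- sim$genes[sim$genes$genome_id == g, ]
    write_fasta(stats::setNames(as.list(rows$nucleotide), rows$gene_id),
                file.path(dir, "cds", paste0(g, ".ffn")))
    write_fasta(stats::setNames(as.list(rows$protein), rows$gene_id),
                file.path(dir, "proteins", paste0(g, ".faa")))
  }
  hosts <- data.frame(genome_id = names(sim$host_labels),
                      host = unname(sim$host_labels))
  utils::write.table(hosts, file.path(dir, "hosts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$tree_newick, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$presence <- list(families = rownames(sim$presence),
                         genomes = colnames(sim$presence),
                         matrix = unname(apply(sim$presence, 1, as.integer,
                                               simplify = FALSE)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
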