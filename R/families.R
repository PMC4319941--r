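## Gene-family construction under the 50/50 homology rule: a pair of genes
## belongs to the same family when amino-acid identity is above 50% and the
## alignment covers more than 50% of the longer gene. Families are the
## connected components (single linkage) of the resulting pair graph.

#' Build a gene table
#'
#' Normalises per-gene records into the data frame used throughout the
#' package: one row per coding sequence with `gene_id`, `genome_id`,
#' `protein` and optionally `nucleotide`.
#'
#' @param gene_id,genome_id Character vectors.
#' @param protein Amino-acid sequences (required).
#' @param nucleotide Optional nucleotide sequences.
#' @return A `data.frame` of class `gene_table`.
#' @export
gene_table <- function(gene_id, genome_id, protein, nucleotide = NULL) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids", call. = FALSE)
  df <- data.frame(gene_id = as.character(gene_id),
                   genome_id = as.character(genome_id),
                   protein = toupper(as.character(protein)),
                   stringsAsFactors = FALSE)
  if (!is.null(nucleotide)) df$nucleotide <- toupper(as.character(nucleotide))
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Homology verdict for one gene pair
#'
#' Aligns two protein sequences and applies the family rule: same family
#' when identity is strictly above `min_identity` percent and the aligned
#' span covers strictly more than `min_coverage` of the longer gene.
#'
#' @param a,b Protein sequences (character scalars).
#' @param scoring Protein [scoring_scheme()].
#' @param a_id,b_id Optional gene ids.
#' @param min_identity Identity threshold in percent (default 50).
#' @param min_coverage Coverage-of-longer-gene threshold as a fraction
#'   (default 0.5).
#' @return A list of class `homology_verdict` with `identity_pct`,
#'   `longer_gene_coverage` and `same_family`.
#' @export
homology_pair_verdict <- function(a, b, scoring = scoring_scheme("protein"),
                                  a_id = NULL, b_id = NULL,
                                  min_identity = 50, min_coverage = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("missing protein sequence", call. = FALSE)
  aln <- local_align(a, b, scoring, a_id = a_id, b_id = b_id)
  la <- nchar(a); lb <- nchar(b)
  if (is.null(aln)) {
    v <- list(gene_a = a_id, gene_b = b_id, identity_pct = 0,
              longer_gene_coverage = 0, same_family = FALSE)
  } else {
    cov <- if (la >= lb) aln$query_coverage else aln$subject_coverage
    v <- list(gene_a = a_id, gene_b = b_id,
              identity_pct = aln$identity_pct,
              longer_gene_coverage = cov,
              same_family = aln$identity_pct > min_identity && cov > min_coverage)
  }
  class(v) <- "homology_verdict"
  v
}

## iterative union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster genes into families
#'
#' All-vs-all application of the pairwise 50/50 rule followed by
#' single-linkage clustering (connected components of the homology graph).
#' A shared k-mer prefilter skips pairs that cannot be homologous, plus a
#' provably safe length filter (identity > 50% over > 50% of the longer
#' gene forces the shorter gene to exceed a quarter of the longer one).
#' Family ids are assigned deterministically in order of each family's
#' lexicographically smallest member id. The longest member (ties: smallest
#' gene id) is marked as the family representative.
#'
#' @param genes A [gene_table()] (or data frame with `gene_id`, `genome_id`,
#'   `protein`).
#' @param scoring Protein [scoring_scheme()].
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"` (hierarchical complete linkage on the verdict graph).
#' @param prefilter Use the shared 3-mer prefilter (`FALSE` = exact mode,
#'   align every length-compatible pair).
#' @param min_shared_kmers Minimum shared distinct 3-mers for a pair to be
#'   aligned when `prefilter` is on.
#' @param min_identity,min_coverage Rule thresholds, see
#'   [homology_pair_verdict()].
#' @return A `gene_family_set`: list with `members` (data frame `family_id`,
#'   `gene_id`, `genome_id`, `is_representative`) and `gene_index`
#'   (gene id -> family id).
#' @export
build_families <- function(genes, scoring = scoring_scheme("protein"),
                           linkage = c("single", "complete"),
                           prefilter = TRUE, min_shared_kmers = 1L,
                           min_identity = 50, min_coverage = 0.5) {
  linkage <- match.arg(linkage)
  if (nrow(genes) < 1) stop("need at least one gene", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids", call. = FALSE)
  n <- nrow(genes)
  prot <- genes$protein
  lens <- nchar(prot)

  ## candidate pairs
  enc <- lapply(prot, encode_seq, scoring = scoring, check_alphabet = FALSE)
  if (n > 1) {
    if (prefilter) {
      cand <- shared_kmer_pairs_cpp(enc, scoring$seed_k, scoring$ambig_code,
                                    as.integer(min_shared_kmers))
      ii <- cand[, 1L]; jj <- cand[, 2L]
    } else {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      ii <- idx[, 1L]; jj <- idx[, 2L]
    }
    ## safe length filter: shorter > 0.25 * longer is necessary for the rule
    keep <- pmin(lens[ii], lens[jj]) > 0.25 * pmax(lens[ii], lens[jj])
    ii <- ii[keep]; jj <- jj[keep]
  } else {
    ii <- jj <- integer(0)
  }

  edge_i <- integer(0); edge_j <- integer(0)
  if (length(ii)) {
    same <- logical(length(ii))
    for (e in seq_along(ii)) {
      raw <- sw_align_cpp(enc[[ii[e]]], enc[[jj[e]]], scoring$matrix,
                          scoring$gap_open, scoring$gap_extend,
                          scoring$ident_ok)
      if (is.null(raw)) next
      ident <- 100 * raw$n_ident / raw$align_len
      span <- if (lens[ii[e]] >= lens[jj[e]])
        (raw$qend - raw$qstart) / lens[ii[e]]
      else (raw$send - raw$sstart) / lens[jj[e]]
      same[e] <- ident > min_identity && span > min_coverage
    }
    edge_i <- ii[same]; edge_j <- jj[same]
  }

  comp <- if (linkage == "single") {
    .components_single(n, edge_i, edge_j)
  } else {
    .components_complete(n, edge_i, edge_j)
  }

  ## deterministic family ids by sorted smallest member gene id
  smallest <- tapply(genes$gene_id, comp, function(x) min(x))
  ord <- order(smallest)
  relabel <- integer(length(smallest))
  relabel[ord] <- seq_along(ord)
  fam_num <- relabel[match(comp, as.integer(names(smallest)))]
  width <- max(4L, nchar(as.character(max(fam_num))))
  fam_id <- sprintf("FAM%0*d", width, fam_num)

  members <- data.frame(family_id = fam_id,
                        gene_id = genes$gene_id,
                        genome_id = genes$genome_id,
                        protein_length = lens,
                        is_representative = FALSE,
                        stringsAsFactors = FALSE)
  members <- members[order(members$family_id, members$gene_id), ]
  rownames(members) <- NULL
  for (f in unique(members$family_id)) {
    rows <- which(members$family_id == f)
    rep_row <- rows[order(-members$protein_length[rows], members$gene_id[rows])][1]
    members$is_representative[rep_row] <- TRUE
  }
  structure(
    list(members = members,
         gene_index = stats::setNames(members$family_id, members$gene_id),
         genes = genes),
    class = "gene_family_set")
}

.components_single <- function(n, edge_i, edge_j) {
  parent <- .uf_new(n)
  for (e in seq_along(edge_i)) {
    ri <- .uf_find(parent, edge_i[e])
    rj <- .uf_find(parent, edge_j[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
}

## complete linkage on the 0/1 homology "distance": hclust complete, cut
## strictly below 1 (only fully connected merges survive).
.components_complete <- function(n, edge_i, edge_j) {
  if (n == 1) return(1L)
  d <- matrix(1, n, n)
  d[cbind(edge_i, edge_j)] <- 0
  d[cbind(edge_j, edge_i)] <- 0
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  stats::cutree(hc, h = 0.5)
}

#' @export
print.gene_family_set <- function(x, ...) {
  cat(sprintf("<gene_family_set> %d genes, %d families, %d genomes\n",
              nrow(x$members), length(unique(x$members$family_id)),
              length(unique(x$members$genome_id))))
  invisible(x)
}

#' Representative gene of a family
#'
#' The longest member by protein length; ties broken by lexicographically
#' smallest gene id.
#'
#' @param families A `gene_family_set`.
#' @param family_id Family identifier.
#' @return The representative gene id.
#' @export
select_representative <- function(families, family_id) {
  rows <- families$members[families$members$family_id == family_id, ]
  if (nrow(rows) == 0) stop("empty or unknown family: ", family_id, call. = FALSE)
  rows$gene_id[order(-rows$protein_length, rows$gene_id)][1]
}

#' Family presence/absence matrix
#'
#' @param families A `gene_family_set`, or its `members` data frame.
#' @param genomes Optional genome ids forcing the column set (genomes with
#'   no annotated member get all-FALSE columns).
#' @return Logical matrix, families x genomes.
#' @export
presence_matrix <- function(families, genomes = NULL) {
  m <- if (inherits(families, "gene_family_set")) families$members else families
  fams <- sort(unique(m$family_id))
  gens <- if (is.null(genomes)) sort(unique(m$genome_id)) else genomes
  out <- matrix(FALSE, length(fams), length(gens), dimnames = list(fams, gens))
  out[cbind(match(m$family_id, fams), match(m$genome_id, gens))] <- TRUE
  out
}

#' Rescue family presences missed by gene prediction
#'
#' For every (family, genome) pair where the genome has no annotated
#' member, the family representative protein is searched against all six
#' reading frames of each assembly contig (a tblastn-style search). The
#' family is marked present when a hit satisfies the same 50/50 rule
#' measured against the representative length. Annotated presences are
#' never removed: rescue only flips absences to presences.
#'
#' @param families A `gene_family_set`.
#' @param assemblies Named list (genome id -> named character vector of
#'   contig sequences).
#' @param scoring Protein [scoring_scheme()].
#' @param presence Optional starting presence matrix (defaults to the
#'   annotated one); its column set defines the genomes searched.
#' @param min_identity,min_coverage Rule thresholds (identity percent,
#'   fraction of the representative length).
#' @return List with the updated logical `presence` matrix and a `rescued`
#'   data frame (`family_id`, `genome_id`, `identity_pct`, `coverage`).
#' @export
rescue_missing_members <- function(families, assemblies,
                                   scoring = scoring_scheme("protein"),
                                   presence = NULL,
                                   min_identity = 50, min_coverage = 0.5) {
  if (is.null(presence))
    presence <- presence_matrix(families, genomes = names(assemblies))
  reps <- families$members[families$members$is_representative, ]
  rep_seq <- stats::setNames(
    families$genes$protein[match(reps$gene_id, families$genes$gene_id)],
    reps$family_id)
  rescued <- list()
  frames_cache <- list()
  for (g in colnames(presence)) {
    absent <- rownames(presence)[!presence[, g]]
    if (!length(absent)) next
    if (is.null(assemblies[[g]]))
      stop("no assembly available for genome ", g, call. = FALSE)
    if (is.null(frames_cache[[g]])) {
      fr <- unlist(lapply(assemblies[[g]], translate_six_frames))
      fr <- fr[nchar(fr) > 0]
      frames_cache[[g]] <- lapply(fr, encode_seq, scoring = scoring,
                                  check_alphabet = FALSE)
    }
    for (f in absent) {
      rp <- rep_seq[[f]]
      if (is.null(rp)) next
      rp_enc <- encode_seq(rp, scoring, check_alphabet = FALSE)
      hit <- NULL
      for (fr_name in sort(names(frames_cache[[g]]))) {
        cand <- .align_encoded(rp_enc, frames_cache[[g]][[fr_name]], scoring,
                               a_id = f, b_id = fr_name)
        if (is.null(cand)) next
        if (is.null(hit) || cand$score > hit$score ||
            (cand$score == hit$score && cand$identity_pct > hit$identity_pct))
          hit <- cand
      }
      if (is.null(hit)) next
      if (hit$identity_pct > min_identity && hit$query_coverage > min_coverage) {
        presence[f, g] <- TRUE
        rescued[[length(rescued) + 1L]] <- data.frame(
          family_id = f, genome_id = g,
          identity_pct = hit$identity_pct, coverage = hit$query_coverage,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(presence = presence,
       rescued = if (length(rescued)) do.call(rbind, rescued)
                 else data.frame(family_id = character(0), genome_id = character(0),
                                 identity_pct = numeric(0), coverage = numeric(0)))
}
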