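## Pipeline orchestration: run the analysis stages (families -> pancore ->
## ani -> aai -> hostcore -> treestats) over an input directory, writing
## per-stage outputs and a manifest under one output directory. Completed
## stages are skipped on re-runs unless forced.

#' Run configuration
#'
#' Bundles every numeric threshold of the analysis with the seed and
#' backend switches. The configuration is echoed into the manifest of
#' every pipeline run for provenance.
#'
#' @param family_identity,family_coverage 50/50 homology rule thresholds
#'   (percent, fraction).
#' @param aai_identity,aai_min_alignment_length,aai_coverage AAI filters.
#' @param ani_fragment_length,ani_identity,ani_coverage ANI fragmentation
#'   and retention parameters.
#' @param species_cutoff ANI species-delineation threshold in percent.
#' @param permutations Accumulation-curve orderings.
#' @param seed Integer seed.
#' @param linkage Family clustering linkage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(family_identity = 50, family_coverage = 0.5,
                       aai_identity = 30, aai_min_alignment_length = 30,
                       aai_coverage = 0.7, ani_fragment_length = 1020,
                       ani_identity = 30, ani_coverage = 0.7,
                       species_cutoff = 95, permutations = 100, seed = 1,
                       linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(family_identity >= 0, family_identity <= 100,
            family_coverage >= 0, family_coverage <= 1,
            aai_identity >= 0, aai_identity <= 100,
            aai_min_alignment_length >= 0,
            aai_coverage >= 0, aai_coverage <= 1,
            ani_fragment_length > 0,
            ani_identity >= 0, ani_identity <= 100,
            ani_coverage >= 0, ani_coverage <= 1,
            species_cutoff > 0, species_cutoff <= 100,
            permutations >= 1)
  structure(as.list(environment()), class = "run_config")
}

.stage_done <- function(manifest, stage) {
  !is.null(manifest$stages[[stage]]) &&
    isTRUE(manifest$stages[[stage]]$complete)
}

#' Run the full comparative-genomics pipeline
#'
#' Expects an input directory laid out as written by [write_simulation()]:
#' `proteins/` (required), optionally `assemblies/`, `hosts.tsv`,
#' `tree.nwk`, `annotations.tsv`. Stage outputs land under `out_dir`
#' together with `manifest.json` (stage status, configuration echo, input
#' counts). Stages with missing inputs are skipped and recorded as such;
#' completed stages are not recomputed unless `force = TRUE`.
#'
#' @param input_dir Input directory.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param hosts_compare Two host labels for the node-depth comparison.
#' @param force Recompute completed stages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config(),
                         hosts_compare = c("bee", "human"), force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force)
    jsonlite::read_json(manifest_path)
  else list(stages = list())
  manifest$config <- unclass(config)

  prot_dir <- file.path(input_dir, "proteins")
  if (!dir.exists(prot_dir))
    stop("missing required input: ", prot_dir, call. = FALSE)
  genes <- read_gene_set(prot_dir, "aa")
  prot_scoring <- scoring_scheme("protein")

  mark <- function(stage, info = list()) {
    manifest$stages[[stage]] <<- c(list(complete = TRUE), info)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  ## families
  pm_path <- file.path(out_dir, "presence_matrix.tsv")
  fam_path <- file.path(out_dir, "families.tsv")
  if (force || !.stage_done(manifest, "families")) {
    fams <- build_families(genes, prot_scoring, linkage = config$linkage,
                           min_identity = config$family_identity,
                           min_coverage = config$family_coverage)
    utils::write.table(fams$members, fam_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_presence_matrix(presence_matrix(fams), pm_path)
    mark("families", list(n_genes = nrow(genes),
                          n_families = length(unique(fams$members$family_id))))
  }
  pm <- read_presence_matrix(pm_path)

  ## pancore
  if (force || !.stage_done(manifest, "pancore")) {
    curve <- accumulation_curves(pm, config$permutations, config$seed)
    utils::write.table(
      data.frame(n = curve$n, pan_mean = curve$pan_mean,
                 core_mean = curve$core_mean),
      file.path(out_dir, "accumulation.csv"), sep = ",", quote = FALSE,
      row.names = FALSE)
    fit <- fit_power(curve$n, curve$pan_mean)
    jsonlite::write_json(
      list(pan_fit = unclass(fit),
           core_fit = unclass(fit_power(curve$n, curve$core_mean)),
           new_per_genome_mean = curve$new_per_genome_mean,
           core_size = length(core_families(pm))),
      file.path(out_dir, "pancore.json"), auto_unbox = TRUE, digits = NA)
    mark("pancore", list(core_size = length(core_families(pm))))
  }

  ## ani / aai
  asm_dir <- file.path(input_dir, "assemblies")
  if (dir.exists(asm_dir) && (force || !.stage_done(manifest, "ani"))) {
    asm <- read_genome_set(asm_dir)
    m <- pairwise_identity_matrix(asm, "ani",
                                  fragment_length = config$ani_fragment_length,
                                  min_identity = config$ani_identity,
                                  min_coverage = config$ani_coverage)
    utils::write.table(data.frame(genome_id = rownames(m), round(m, 2),
                                  check.names = FALSE),
                       file.path(out_dir, "ani.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mark("ani", list(n_genomes = length(asm)))
  }
  if (force || !.stage_done(manifest, "aai")) {
    proteomes <- split(stats::setNames(genes$protein, genes$gene_id),
                       genes$genome_id)
    m <- pairwise_identity_matrix(proteomes, "aai",
                                  min_identity = config$aai_identity,
                                  min_alignment_length = config$aai_min_alignment_length,
                                  min_coverage = config$aai_coverage)
    utils::write.table(data.frame(genome_id = rownames(m), round(m, 2),
                                  check.names = FALSE),
                       file.path(out_dir, "aai.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mark("aai", list(n_genomes = length(proteomes)))
  }

  ## hostcore
  hosts_path <- file.path(input_dir, "hosts.tsv")
  if (file.exists(hosts_path) && (force || !.stage_done(manifest, "hostcore"))) {
    hosts <- read_hosts(hosts_path)
    profiles <- group_core_sets(pm, hosts)
    venn <- venn_partition(lapply(profiles, `[[`, "core"))
    jsonlite::write_json(
      list(group_core_sizes = lapply(profiles, function(p) length(p$core)),
           regions = venn$regions),
      file.path(out_dir, "hostcore.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    mark("hostcore", list(n_groups = length(profiles)))
  }

  ## treestats
  tree_path <- file.path(input_dir, "tree.nwk")
  if (file.exists(tree_path) && file.exists(hosts_path) &&
      (force || !.stage_done(manifest, "treestats"))) {
    tree <- parse_newick(paste(readLines(tree_path), collapse = ""))
    hosts <- read_hosts(hosts_path)
    rep <- node_depth_report(tree, hosts)
    utils::write.table(rep, file.path(out_dir, "node_depths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    present <- intersect(hosts_compare, rep$host)
    if (length(present) == 2) {
      w <- compare_node_depths(tree, hosts, hosts_compare)
      jsonlite::write_json(
        list(groups = hosts_compare, W = w$rank_sum_statistic,
             p_value = w$p_value, method = w$method),
        file.path(out_dir, "node_depth_test.json"), auto_unbox = TRUE,
        digits = NA)
    }
    mark("treestats", list(n_tips = length(tree$tip.label)))
  }

  invisible(manifest)
}
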