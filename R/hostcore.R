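## Host-grouped core-genome analysis: per-host core family sets, the
## disjoint Venn partition of k core sets, host-specific families, and
## tabulation of COG-style functional categories.

#' Per-host core family sets
#'
#' Groups the genomes of a presence matrix by host label and computes, for
#' each selected host, the families present in every member genome.
#' Genomes on the exclusion list (e.g. non-gastrointestinal isolates) are
#' dropped before grouping.
#'
#' @param matrix Logical presence matrix (families x genomes).
#' @param host_map Named character vector (genome id -> host label).
#' @param hosts Host labels to profile (default: all hosts present).
#' @param exclude Genome ids to drop before grouping.
#' @return Named list of host profiles: each a list with `host`, `genomes`,
#'   `core` (family id vector).
#' @export
group_core_sets <- function(matrix, host_map, hosts = NULL,
                            exclude = character(0)) {
  matrix <- .check_pam(matrix)
  keep <- setdiff(colnames(matrix), exclude)
  host_map <- host_map[names(host_map) %in% keep]
  if (is.null(hosts)) hosts <- sort(unique(unname(host_map)))
  out <- lapply(hosts, function(h) {
    gens <- names(host_map)[host_map == h]
    if (!length(gens))
      stop("host group has no genomes after exclusions: ", h, call. = FALSE)
    list(host = h, genomes = gens, core = core_families(matrix, gens))
  })
  stats::setNames(out, hosts)
}

#' Disjoint Venn partition of k core sets
#'
#' Assigns every family in the union of the core sets to exactly one
#' region according to its membership signature. Region names join the
#' member group labels with `&`.
#'
#' @param core_sets Named list of character vectors (2 to 5 groups), or the
#'   output of [group_core_sets()].
#' @return A `venn_partition`: list with `regions` (region name -> family
#'   ids), `sizes`, `groups`, plus `shared_all` and `unique` accessor
#'   fields.
#' @export
venn_partition <- function(core_sets) {
  if (length(core_sets) && is.list(core_sets[[1]]) &&
      !is.null(core_sets[[1]]$core))
    core_sets <- lapply(core_sets, `[[`, "core")
  k <- length(core_sets)
  if (k < 2 || k > 5)
    stop("need between 2 and 5 groups, got ", k, call. = FALSE)
  groups <- names(core_sets)
  if (is.null(groups)) groups <- paste0("G", seq_len(k))
  fams <- sort(unique(unlist(core_sets)))
  sig <- vapply(fams, function(f)
    paste(groups[vapply(core_sets, function(s) f %in% s, logical(1))],
          collapse = "&"), character(1))
  regions <- split(fams, sig)
  all_name <- paste(groups, collapse = "&")
  uniq <- stats::setNames(
    lapply(groups, function(g) regions[[g]] %||% character(0)), groups)
  structure(
    list(regions = regions,
         sizes = vapply(regions, length, integer(1)),
         groups = groups,
         shared_all = regions[[all_name]] %||% character(0),
         unique = uniq),
    class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d groups (%s), %d regions\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              length(x$regions)))
  for (r in names(x$sizes)) cat(sprintf("  %-30s %d\n", r, x$sizes[[r]]))
  invisible(x)
}

#' Functional-category distribution of a family set
#'
#' Tabulates one-letter COG-style categories over a set of families.
#' Multi-letter assignments (e.g. `"KL"`) are split fractionally (1/m to
#' each letter) by default; `mode = "primary"` counts only the first
#' letter. Families without an annotation are counted as unannotated.
#' Percentages are over annotated families only.
#'
#' @param family_ids Character vector of family ids.
#' @param annotations Named character vector (family id -> category
#'   letters).
#' @param mode `"fractional"` or `"primary"`.
#' @return A `category_distribution`: data frame `category`, `count`,
#'   `percentage`, with attribute `unannotated`.
#' @export
category_distribution <- function(family_ids, annotations,
                                  mode = c("fractional", "primary")) {
  mode <- match.arg(mode)
  ann <- annotations[family_ids]
  ann <- ann[!is.na(ann) & nzchar(ann)]
  counts <- numeric(0)
  for (a in ann) {
    letters <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
    letters <- letters[letters %in% LETTERS]
    if (!length(letters)) next
    if (mode == "primary") letters <- letters[1]
    wt <- 1 / length(letters)
    for (l in letters) counts[l] <- (counts[l] %||NA% 0) + wt
  }
  out <- data.frame(category = names(counts) %||% character(0),
                    count = unname(counts),
                    percentage = if (length(counts) && sum(counts) > 0)
                      100 * unname(counts) / sum(counts) else numeric(0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$category), ]
  rownames(out) <- NULL
  attr(out, "unannotated") <- length(family_ids) - length(ann)
  class(out) <- c("category_distribution", "data.frame")
  out
}

`%||NA%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
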