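## Tree statistics: Newick ingestion (ape-backed), outgroup rooting, the
## nodes-to-MRCA tip depth, an exact/approximate Wilcoxon rank-sum test,
## and concatenation of per-family alignments into a supermatrix.

#' Parse a Newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Branch lengths,
#' internal (support) labels and quoted labels are supported. Basic
#' syntax problems are reported with a character offset.
#'
#' @param text Newick string (must end with `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("empty Newick input", call. = FALSE)
  s <- trimws(text)
  depth <- 0L
  in_quote <- FALSE
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0)
        stop(sprintf("Newick parse error at character %d: unbalanced ')'", i),
             call. = FALSE)
    }
  }
  if (depth != 0)
    stop(sprintf("Newick parse error at character %d: %d unclosed '('",
                 nchar(s), depth), call. = FALSE)
  if (!endsWith(s, ";"))
    stop(sprintf("Newick parse error at character %d: missing terminating ';'",
                 nchar(s) + 1L), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = s),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("Newick parse error at character 1: not a valid tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  tree
}

#' Serialise a tree to canonical Newick
#'
#' @param tree A `phylo` object.
#' @return Newick string (with terminating semicolon).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Re-root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup tips from the
#' ingroup. Errors when the outgroup is not separable (not monophyletic on
#' the unrooted topology) or equals the full tip set.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of outgroup tip labels.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup tips not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (setequal(outgroup, tree$tip.label))
    stop("outgroup cannot contain every tip", call. = FALSE)
  out <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e)
      stop_classed("corepan_not_monophyletic",
                   "outgroup is not separable on the unrooted topology: ",
                   conditionMessage(e)))
  out
}

#' Number of internal nodes from each tip to the root (MRCA)
#'
#' Counts the internal nodes on the path from a tip to the root, excluding
#' the tip itself and including the root, so every tip of a two-tip tree
#' scores 1. The statistic depends only on topology, never on branch
#' lengths.
#'
#' @param tree A rooted `phylo` object.
#' @param tips Tip labels (default: all tips).
#' @return Named integer vector of node counts.
#' @export
nodes_to_mrca <- function(tree, tips = tree$tip.label) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(stats::setNames(match(tips, tree$tip.label), tips), function(node) {
    d <- 0L
    while (node != root) {
      node <- parent[node]
      d <- d + 1L
    }
    d
  }, integer(1))
}

#' Wilcoxon rank-sum (Mann-Whitney) two-sample test
#'
#' Midranks are used for ties. The exact distribution is obtained by
#' complete enumeration of the \eqn{\binom{n_x+n_y}{n_x}} label
#' assignments when `min(n_x, n_y) <= 10` and `n_x + n_y <= 20` (method
#' `"auto"`); otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used. The exact two-sided p-value is
#' `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of x relative
#'   to y).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return A `wilcoxon_result`: list with `rank_sum_statistic` (rank sum of
#'   `x`), `p_value`, `alternative`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (method == "auto")
    method <- if (min(nx, ny) <= 10 && N <= 20) "exact" else "normal"
  eps <- 1e-9
  if (method == "exact") {
    combos <- utils::combn(N, nx)
    ws <- colSums(matrix(r[combos], nrow = nx))
    p_le <- mean(ws <= w + eps)
    p_ge <- mean(ws >= w - eps)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
  } else {
    ties <- table(r)
    mu <- nx * (N + 1) / 2
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
      less = stats::pnorm((w - mu + 0.5) / sigma),
      greater = stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE),
      two.sided = {
        z <- (w - mu - sign(w - mu) * 0.5) / sigma
        min(1, 2 * stats::pnorm(-abs(z)))
      })
  }
  structure(list(rank_sum_statistic = w, p_value = p,
                 alternative = alternative, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %g, p = %.4g (%s, %s)\n",
              x$rank_sum_statistic, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Node-depth report for a host-labelled tree
#'
#' @param tree A rooted `phylo` object.
#' @param hosts Named character vector (tip label -> host).
#' @return Data frame `tip`, `host`, `nodes_to_mrca`.
#' @export
node_depth_report <- function(tree, hosts) {
  d <- nodes_to_mrca(tree)
  data.frame(tip = names(d),
             host = unname(hosts[names(d)]),
             nodes_to_mrca = unname(d),
             stringsAsFactors = FALSE)
}

#' Compare node depths between two host groups
#'
#' Runs [wilcoxon_rank_sum()] on the nodes-to-MRCA counts of two host
#' groups (e.g. bee versus human isolates).
#'
#' @param tree A rooted `phylo` object.
#' @param hosts Named character vector (tip label -> host).
#' @param groups Length-2 character vector of host labels to compare.
#' @param ... Passed to [wilcoxon_rank_sum()].
#' @return A `wilcoxon_result` with an added `report` data frame.
#' @export
compare_node_depths <- function(tree, hosts, groups, ...) {
  stopifnot(length(groups) == 2)
  rep <- node_depth_report(tree, hosts)
  x <- rep$nodes_to_mrca[rep$host %in% groups[1]]
  y <- rep$nodes_to_mrca[rep$host %in% groups[2]]
  if (!length(x) || !length(y))
    stop("no tips for host group(s): ",
         paste(groups[c(!length(x), !length(y))], collapse = ", "),
         call. = FALSE)
  out <- wilcoxon_rank_sum(x, y, ...)
  out$report <- rep
  out$groups <- groups
  out
}

#' Concatenate per-family alignment blocks into a supermatrix
#'
#' Blocks are joined in sorted block-name order; genomes missing from a
#' block are padded with gap characters. A 1-based inclusive partition
#' table is emitted alongside.
#'
#' @param blocks Named list; each element a named character vector
#'   (genome id -> aligned sequence, equal widths within a block).
#' @param gap Gap character (default `-`).
#' @return List with `alignment` (named character vector) and `partitions`
#'   (data frame `block`, `start`, `end`).
#' @export
concatenate_alignments <- function(blocks, gap = "-") {
  if (!length(blocks)) stop("no alignment blocks", call. = FALSE)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  blocks <- blocks[order(names(blocks))]
  widths <- vapply(blocks, function(b) {
    w <- unique(nchar(b))
    if (length(w) != 1)
      stop("ragged block: unequal sequence lengths", call. = FALSE)
    w
  }, integer(1))
  genomes <- sort(unique(unlist(lapply(blocks, names))))
  rows <- stats::setNames(rep("", length(genomes)), genomes)
  for (b in seq_along(blocks)) {
    pad <- strrep(gap, widths[b])
    piece <- stats::setNames(rep(pad, length(genomes)), genomes)
    piece[names(blocks[[b]])] <- blocks[[b]]
    rows <- paste0(rows, piece)
  }
  ends <- cumsum(widths)
  list(alignment = stats::setNames(rows, genomes),
       partitions = data.frame(block = names(blocks),
                               start = c(1L, utils::head(ends, -1) + 1L),
                               end = ends,
                               stringsAsFactors = FALSE))
}
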