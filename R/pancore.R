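## Pan/core-genome analytics on a family presence/absence matrix:
## accumulation curves over random genome orderings (exhaustive when the
## genome count permits), core-family extraction, and power-law fits
## y = kappa * n^gamma to the curves.

.check_pam <- function(matrix) {
  if (!is.matrix(matrix) || !is.logical(matrix))
    matrix <- matrix > 0
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("presence matrix needs family rownames and genome colnames", call. = FALSE)
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("duplicate family or genome ids", call. = FALSE)
  matrix
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Pan- and core-genome accumulation curves
#'
#' For each genome ordering, pan(n) is the number of families present in at
#' least one of the first n genomes and core(n) the number present in all of
#' them. Means are taken across orderings: all N! orderings when N <= 6
#' (exhaustive mode), otherwise `n_permutations` random orderings under
#' `seed`. The mean marginal pan growth, (pan(N) - pan(1)) / (N - 1)
#' averaged over orderings, is reported as `new_per_genome_mean`.
#'
#' @param matrix Logical presence matrix (families x genomes).
#' @param n_permutations Number of random orderings (ignored in exhaustive
#'   mode).
#' @param seed Integer seed for the orderings.
#' @return An `accumulation_curve`: list with `n`, `pan_mean`, `core_mean`,
#'   `new_per_genome_mean`, per-ordering traces `pan` and `core`
#'   (orderings x n), and `exhaustive`.
#' @export
accumulation_curves <- function(matrix, n_permutations = 100, seed = 1) {
  matrix <- .check_pam(matrix)
  G <- ncol(matrix)
  if (G < 2) stop("need at least 2 genomes", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  exhaustive <- G <= 6
  orders <- if (exhaustive) {
    .all_permutations(G)
  } else {
    with_seed(seed, t(vapply(seq_len(n_permutations),
                             function(i) sample.int(G), integer(G))))
  }
  P <- nrow(orders)
  pan <- core <- base::matrix(0, P, G)
  for (p in seq_len(P)) {
    m <- matrix[, orders[p, ], drop = FALSE]
    first_true <- max.col(m * 1, ties.method = "first")
    all_true <- rowSums(m) == G
    first_false <- ifelse(all_true, G + 1L,
                          max.col((!m) * 1, ties.method = "first"))
    pan[p, ] <- cumsum(tabulate(first_true, nbins = G))
    core[p, ] <- nrow(m) - cumsum(tabulate(first_false, nbins = G))
  }
  structure(
    list(n = seq_len(G),
         pan_mean = colMeans(pan),
         core_mean = colMeans(core),
         new_per_genome_mean = mean((pan[, G] - pan[, 1]) / (G - 1)),
         pan = pan, core = core, exhaustive = exhaustive),
    class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  G <- length(x$n)
  cat(sprintf(
    "<accumulation_curve> %d genomes (%s, %d orderings)\n  pan: %.1f -> %.1f   core: %.1f -> %.1f   new families/genome: %.1f\n",
    G, if (x$exhaustive) "exhaustive" else "sampled", nrow(x$pan),
    x$pan_mean[1], x$pan_mean[G], x$core_mean[1], x$core_mean[G],
    x$new_per_genome_mean))
  invisible(x)
}

#' Core families of a genome subset
#'
#' Families present in every genome of the subset.
#'
#' @param matrix Logical presence matrix.
#' @param genomes Genome ids (default: all columns).
#' @return Character vector of family ids.
#' @export
core_families <- function(matrix, genomes = colnames(matrix)) {
  matrix <- .check_pam(matrix)
  if (length(genomes) == 0) stop("empty genome subset", call. = FALSE)
  unknown <- setdiff(genomes, colnames(matrix))
  if (length(unknown))
    stop("unknown genome id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sub <- matrix[, genomes, drop = FALSE]
  rownames(sub)[rowSums(sub) == length(genomes)]
}

#' Fit a power function to an accumulation curve
#'
#' Fits y = kappa * n^gamma by ordinary least squares on log y versus
#' log n (closed form, deterministic). The root-mean-square residual is
#' reported on the original scale.
#'
#' @param n Genome counts (>= 1).
#' @param y Curve values (> 0).
#' @return List of class `power_fit` with `kappa`, `gamma`, `fit_rmse`.
#' @export
fit_power <- function(n, y) {
  if (length(n) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(y <= 0)) stop("all y values must be positive", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(n))
  kappa <- exp(unname(stats::coef(fit)[1]))
  gamma <- unname(stats::coef(fit)[2])
  pred <- kappa * n^gamma
  structure(list(kappa = kappa, gamma = gamma,
                 fit_rmse = sqrt(mean((y - pred)^2))),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> y = %.4g * n^%.4g  (rmse %.4g)\n",
              x$kappa, x$gamma, x$fit_rmse))
  invisible(x)
}
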