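## Independent reference implementations used as oracles. These share no
## code with the package paths they check: the aligner oracle is a plain-R
## full dynamic program, clustering uses igraph, the Wilcoxon oracle
## enumerates label assignments directly, and the accumulation oracle
## walks orderings with set operations.

## Full-DP affine-gap local alignment in plain R, mirroring the package's
## conventions (gap_open for the first gap column; diag > E > F preference;
## first strict maximum wins) so results are comparable field by field.
ref_local_align <- function(a, b, scoring) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  code <- function(ch) {
    i <- match(ch, scoring$alphabet)
    i[is.na(i)] <- scoring$ambig_code + 1L
    i
  }
  ca <- code(A); cb <- code(B)
  m <- length(ca); n <- length(cb)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  tH <- matrix(0L, m + 1, n + 1)
  tE <- matrix(0L, m + 1, n + 1)
  tF <- matrix(0L, m + 1, n + 1)
  go <- scoring$gap_open; ge <- scoring$gap_extend
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    eo <- H[i, j - 1] + go; ee <- E[i, j - 1] + ge
    E[i, j] <- max(eo, ee); tE[i, j] <- if (eo >= ee) 0L else 1L
    fo <- H[i - 1, j] + go; fe <- F[i - 1, j] + ge
    F[i, j] <- max(fo, fe); tF[i, j] <- if (fo >= fe) 0L else 1L
    d <- H[i - 1, j - 1] + scoring$matrix[ca[i - 1], cb[j - 1]]
    h <- 0; t <- 0L
    if (d > h) { h <- d; t <- 1L }
    if (E[i, j] > h) { h <- E[i, j]; t <- 2L }
    if (F[i, j] > h) { h <- F[i, j]; t <- 3L }
    H[i, j] <- h; tH[i, j] <- t
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best <= 0) return(NULL)
  i <- bi; j <- bj; state <- 0L
  alen <- 0L; nid <- 0L
  qend <- bi - 1L; send <- bj - 1L; qstart <- qend; sstart <- send
  repeat {
    if (state == 0L) {
      t <- tH[i, j]
      if (t == 0L) break
      if (t == 1L) {
        alen <- alen + 1L
        if (ca[i - 1] == cb[j - 1] && scoring$ident_ok[ca[i - 1]])
          nid <- nid + 1L
        i <- i - 1L; j <- j - 1L
        qstart <- i; sstart <- j
      } else state <- if (t == 2L) 1L else 2L
    } else if (state == 1L) {
      alen <- alen + 1L
      t <- tE[i, j]
      j <- j - 1L
      qstart <- i; sstart <- j
      state <- if (t == 0L) 0L else 1L
    } else {
      alen <- alen + 1L
      t <- tF[i, j]
      i <- i - 1L
      qstart <- i; sstart <- j
      state <- if (t == 0L) 0L else 2L
    }
  }
  list(score = best,
       identity_pct = 100 * nid / alen,
       alignment_length = alen,
       query_span = c(qstart - 1L, qend),
       subject_span = c(sstart - 1L, send))
}

## connected components of the 50/50 homology graph via igraph
ref_cluster <- function(genes, scoring = scoring_scheme("protein")) {
  n <- nrow(genes)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      v <- homology_pair_verdict(genes$protein[i], genes$protein[j], scoring)
      if (v$same_family) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

## agreement of two flat clusterings as partitions (label-invariant)
same_partition <- function(x, y) {
  length(x) == length(y) &&
    all(outer(x, x, "==") == outer(y, y, "=="))
}

## pairwise-clustering F1 between a predicted and a true partition
pair_f1 <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  p <- outer(pred, pred, "==")[upper.tri(diag(length(pred)))]
  t <- outer(truth, truth, "==")[upper.tri(diag(length(truth)))]
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

## exact Wilcoxon by direct enumeration of all label assignments
ref_wilcoxon_exact <- function(x, y, alternative = "two.sided") {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ws <- apply(utils::combn(N, nx), 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

## accumulation curves by direct set operations over explicit orderings
ref_accumulation <- function(mat, orders) {
  G <- ncol(mat)
  pan <- core <- matrix(0, nrow(orders), G)
  for (p in seq_len(nrow(orders))) {
    seen <- character(0); common <- NULL
    for (k in seq_len(G)) {
      fams <- rownames(mat)[mat[, orders[p, k]]]
      seen <- union(seen, fams)
      common <- if (is.null(common)) fams else intersect(common, fams)
      pan[p, k] <- length(seen)
      core[p, k] <- length(common)
    }
  }
  list(pan_mean = colMeans(pan), core_mean = colMeans(core))
}

all_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## random protein / presence-matrix generators for property tests
random_protein <- function(len, seed = NULL) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A","C","G","T"), len, replace = TRUE), collapse = "")
}

mutate_string <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
  paste(ch, collapse = "")
}

random_presence <- function(nf, ng, p = 0.6) {
  m <- matrix(runif(nf * ng) < p, nf, ng,
              dimnames = list(sprintf("f%03d", seq_len(nf)),
                              sprintf("g%02d", seq_len(ng))))
  ## ensure invariant: every family somewhere, no empty genome column issues
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(ng, sum(empty), replace = TRUE))] <- TRUE
  m
}
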