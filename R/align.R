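## Pairwise local alignment engine: scoring schemes, Smith-Waterman with
## affine gaps (Rcpp core), a seeded fast path for long subjects, six-frame
## translation, and best-hit search. This stands in for BLAST throughout
## the pipeline.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")
.NT_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a scoring scheme for local alignment
#'
#' A scoring scheme bundles a symmetric substitution matrix with affine gap
#' penalties. Protein schemes default to BLOSUM62 with gap open -11 / extend
#' -1; nucleotide schemes to match +1 / mismatch -1 with gap open -5 /
#' extend -2 (BLAST-like defaults). A gap of length L costs
#' \code{gap_open + (L - 1) * gap_extend}. Ambiguity codes (N for
#' nucleotide, X for protein) never count as identical columns.
#'
#' @param kind `"protein"` or `"nucleotide"`.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein schemes).
#' @param matrix Optional substitution matrix (rows/columns named by
#'   residue); defaults to BLOSUM62 for proteins.
#' @param gap_open,gap_extend Negative gap penalties.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(kind = c("protein", "nucleotide"),
                           match = 1, mismatch = -1, matrix = NULL,
                           gap_open = NULL, gap_extend = NULL) {
  kind <- match.arg(kind)
  if (kind == "protein") {
    alphabet <- .AA_ALPHABET
    if (is.null(matrix)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      matrix <- e$BLOSUM62[alphabet, alphabet]
    } else {
      matrix <- matrix[alphabet, alphabet]
    }
    if (is.null(gap_open)) gap_open <- -11
    if (is.null(gap_extend)) gap_extend <- -1
    ident_ok <- !(alphabet %in% c("X", "*"))
    ambig_code <- match("X", alphabet) - 1L
  } else {
    alphabet <- .NT_ALPHABET
    if (is.null(matrix)) {
      matrix <- base::matrix(mismatch, 5, 5, dimnames = list(alphabet, alphabet))
      diag(matrix) <- match
      matrix["N", ] <- mismatch
      matrix[, "N"] <- mismatch
    } else {
      matrix <- matrix[alphabet, alphabet]
    }
    if (is.null(gap_open)) gap_open <- -5
    if (is.null(gap_extend)) gap_extend <- -2
    ident_ok <- alphabet != "N"
    ambig_code <- match("N", alphabet) - 1L
  }
  if (gap_open >= 0 || gap_extend >= 0)
    stop("gap penalties must be negative", call. = FALSE)
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  structure(
    list(kind = kind, alphabet = alphabet, matrix = matrix,
         gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
         ident_ok = ident_ok, ambig_code = ambig_code,
         seed_k = if (kind == "protein") 3L else 11L),
    class = "scoring_scheme")
}

## Integer-encode a sequence (0-based codes); unknown residues map to the
## ambiguity code. Errors when the sequence is clearly the wrong alphabet.
encode_seq <- function(x, scoring, check_alphabet = TRUE) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- match(chars, scoring$alphabet)
  if (check_alphabet && anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    if (scoring$kind == "nucleotide" &&
        any(!bad %in% c("U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-")))
      stop("sequence contains non-nucleotide characters: ",
           paste(utils::head(bad, 5), collapse = ","), call. = FALSE)
    if (scoring$kind == "protein" && any(!bad %in% c("B", "Z", "J", "U", "O", "-")))
      stop("sequence contains non-protein characters: ",
           paste(utils::head(bad, 5), collapse = ","), call. = FALSE)
  }
  codes[is.na(codes)] <- scoring$ambig_code + 1L
  codes - 1L
}

.mk_alignment <- function(raw, query_id, subject_id, qlen, slen, qoff = 0L, soff = 0L) {
  qspan <- c(raw$qstart + qoff, raw$qend + qoff)
  sspan <- c(raw$sstart + soff, raw$send + soff)
  structure(
    list(query_id = query_id, subject_id = subject_id,
         score = raw$score,
         identity_pct = 100 * raw$n_ident / raw$align_len,
         alignment_length = raw$align_len,
         n_identical = raw$n_ident,
         n_gap_columns = raw$n_gap_cols,
         query_span = qspan, subject_span = sspan,
         query_coverage = (qspan[2] - qspan[1]) / qlen,
         subject_coverage = (sspan[2] - sspan[1]) / slen),
    class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "<local_alignment> %s vs %s  score=%.1f  identity=%.2f%%  len=%d  qcov=%.2f scov=%.2f\n",
    x$query_id %||% "query", x$subject_id %||% "subject",
    x$score, x$identity_pct, x$alignment_length,
    x$query_coverage, x$subject_coverage))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps. Sequence pairs whose DP
#' matrix fits in memory are aligned exactly; longer pairs go through a
#' k-mer seeded path (best seed diagonals define a subject window that is
#' then aligned exactly). Returns `NULL` when no alignment scores above 0.
#'
#' @param a,b Character scalars (query, subject).
#' @param scoring A [scoring_scheme()].
#' @param a_id,b_id Optional sequence identifiers carried into the result.
#' @param max_dp_cells Cell budget above which the seeded path is used.
#' @return A `local_alignment` (score, identity percentage computed over
#'   all aligned columns including gaps, 0-based half-open spans,
#'   coverages) or `NULL`.
#' @export
local_align <- function(a, b, scoring = scoring_scheme("protein"),
                        a_id = NULL, b_id = NULL, max_dp_cells = 8e6) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    stop("sequences must be character scalars", call. = FALSE)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  .align_encoded(encode_seq(a, scoring), encode_seq(b, scoring), scoring,
                 a_id, b_id, max_dp_cells)
}

## core dispatcher over pre-encoded sequences (used directly by the
## ANI/AAI/rescue loops so large subjects are encoded once)
.align_encoded <- function(ea, eb, scoring, a_id = NULL, b_id = NULL,
                           max_dp_cells = 8e6) {
  m <- length(ea); n <- length(eb)
  if (as.double(m + 1) * (n + 1) <= max_dp_cells) {
    raw <- sw_align_cpp(ea, eb, scoring$matrix, scoring$gap_open,
                        scoring$gap_extend, scoring$ident_ok)
    if (is.null(raw)) return(NULL)
    return(.mk_alignment(raw, a_id, b_id, m, n))
  }
  .seeded_align(ea, eb, scoring, a_id, b_id, m, n)
}

## Seed-and-extend: cluster seed diagonals, align the query against a
## subject window around each of the best clusters, keep the best result.
.seeded_align <- function(ea, eb, scoring, a_id, b_id, m, n,
                          band = 48L, pad = 100L, top = 3L) {
  seeds <- seed_matches_cpp(ea, eb, scoring$seed_k, scoring$ambig_code)
  if (nrow(seeds) == 0) {
    if (as.double(m + 1) * (n + 1) <= 6e7) {
      raw <- sw_align_cpp(ea, eb, scoring$matrix, scoring$gap_open,
                          scoring$gap_extend, scoring$ident_ok)
      if (is.null(raw)) return(NULL)
      return(.mk_alignment(raw, a_id, b_id, m, n))
    }
    return(NULL)
  }
  diag <- seeds[, "spos"] - seeds[, "qpos"]
  ord <- order(diag)
  diag <- diag[ord]
  ## cluster diagonals closer than `band`
  brk <- c(0L, which(base::diff(diag) > band), length(diag))
  clusters <- data.frame(
    lo = diag[utils::head(brk, -1) + 1L],
    hi = diag[utils::tail(brk, -1)],
    size = base::diff(brk))
  clusters <- clusters[order(-clusters$size), , drop = FALSE]
  clusters <- utils::head(clusters, top)
  best <- NULL
  for (r in seq_len(nrow(clusters))) {
    ws <- max(0L, clusters$lo[r] - pad)
    we <- min(n, clusters$hi[r] + m + pad)
    if (we - ws < scoring$seed_k) next
    raw <- sw_align_cpp(ea, eb[(ws + 1L):we], scoring$matrix, scoring$gap_open,
                        scoring$gap_extend, scoring$ident_ok)
    if (is.null(raw)) next
    cand <- .mk_alignment(raw, a_id, b_id, m, n, soff = ws)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$identity_pct > best$identity_pct))
      best <- cand
  }
  best
}

#' Best local alignment of a query against a set of subjects
#'
#' Scans every subject with [local_align()] and returns the highest-scoring
#' hit; ties are broken by higher identity percentage, then by the
#' lexicographically smallest subject id.
#'
#' @param query Character scalar.
#' @param subjects Named character vector of subject sequences.
#' @param scoring A [scoring_scheme()].
#' @param query_id Optional query identifier.
#' @return A `local_alignment` or `NULL` when no subject yields a positive
#'   score.
#' @export
best_local_hit <- function(query, subjects, scoring = scoring_scheme("protein"),
                           query_id = NULL) {
  if (length(subjects) == 0) stop("empty subject collection", call. = FALSE)
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  best <- NULL
  for (sid in sort(names(subjects))) {
    hit <- local_align(query, subjects[[sid]], scoring,
                       a_id = query_id, b_id = sid)
    if (is.null(hit)) next
    if (is.null(best) ||
        hit$score > best$score ||
        (hit$score == best$score && hit$identity_pct > best$identity_pct))
      best <- hit
  }
  best
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1, +2, +3 translate the forward strand at offsets 0..2; frames
#' -1, -2, -3 translate the reverse complement likewise. Trailing partial
#' codons are dropped; stop codons are rendered as `*` and preserved in
#' place; ambiguous codons translate to `X`.
#'
#' @param dna Character scalar of length >= 3.
#' @return Named character vector of the six frame translations
#'   (`"+1"`,...,`"-3"`).
#' @export
translate_six_frames <- function(dna) {
  if (!is.character(dna) || length(dna) != 1 || nchar(dna) < 3)
    stop("need a nucleotide sequence of length >= 3", call. = FALSE)
  s <- toupper(chartr("U", "T", dna))
  s <- gsub("[^ACGTRYSWKMBDHVN]", "N", s)
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(x, off) {
    L <- length(x) - off
    L <- L - (L %% 3L)
    if (L < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + L),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  c("+1" = one(fwd, 0L), "+2" = one(fwd, 1L), "+3" = one(fwd, 2L),
    "-1" = one(rev, 0L), "-2" = one(rev, 1L), "-3" = one(rev, 2L))
}
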