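## Whole-genome distance statistics.
##
## ANI follows the fragment method of Goris et al.: the query assembly is
## cut into consecutive 1020-nt windows, each window is locally aligned to
## the other assembly, and windows whose best hit reaches >= 30% identity
## over >= 70% of the window length are retained; ANI is the mean identity
## of retained windows, averaged over both directions.
##
## AAI averages the identity of best blastp-style hits after removing hits
## with (i) identity below 30%, (ii) alignment length below 30 aa, or
## (iii) alignment spanning less than 70% of the query protein.

#' Cut an assembly into ANI fragments
#'
#' Consecutive non-overlapping windows per contig. A terminal window
#' shorter than `fragment_length` is kept only when it is at least
#' `min_tail` nt long.
#'
#' @param assembly Named character vector of contig sequences.
#' @param fragment_length Window size in nt (default 1020).
#' @param min_tail Minimum length of the terminal remainder (default 100).
#' @return Data frame with `fragment_id` (contig:offset, 0-based),
#'   `contig`, `start` (0-based), `seq`.
#' @export
fragment_genome <- function(assembly, fragment_length = 1020, min_tail = 100) {
  if (length(assembly) == 0 || all(!nzchar(assembly)))
    stop("empty assembly", call. = FALSE)
  if (is.null(names(assembly)))
    names(assembly) <- paste0("contig", seq_along(assembly))
  out <- lapply(names(assembly), function(ct) {
    s <- assembly[[ct]]
    L <- nchar(s)
    starts <- seq(0L, max(0L, L - 1L), by = fragment_length)
    ends <- pmin(starts + fragment_length, L)
    keep <- (ends - starts) >= ifelse(ends - starts < fragment_length,
                                      min_tail, 1L)
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    data.frame(fragment_id = paste0(ct, ":", starts),
               contig = ct, start = starts,
               seq = substring(s, starts + 1L, ends),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.directional_ani <- function(frags, subject, scoring, min_identity, min_coverage) {
  idents <- numeric(0)
  subj_enc <- lapply(subject, encode_seq, scoring = scoring)
  for (r in seq_len(nrow(frags))) {
    q <- encode_seq(frags$seq[r], scoring)
    best <- NULL
    for (ct in names(subject)) {
      hit <- .align_encoded(q, subj_enc[[ct]], scoring,
                            a_id = frags$fragment_id[r], b_id = ct)
      if (is.null(hit)) next
      if (is.null(best) || hit$score > best$score ||
          (hit$score == best$score && hit$identity_pct > best$identity_pct))
        best <- hit
    }
    if (!is.null(best) &&
        best$identity_pct >= min_identity &&
        best$alignment_length >= min_coverage * length(q))
      idents <- c(idents, best$identity_pct)
  }
  list(mean_identity = if (length(idents)) mean(idents) else NA_real_,
       retained = length(idents), total = nrow(frags))
}

#' Average nucleotide identity of two assemblies
#'
#' Fragment-based ANI (Goris method). The reciprocal mean of the two
#' directional means is reported; set `reciprocal = FALSE` for the
#' one-way A-vs-B value.
#'
#' @param assembly_a,assembly_b Named character vectors of contig
#'   sequences.
#' @param scoring Nucleotide [scoring_scheme()]; defaults to match +1 /
#'   mismatch -1, gap -5/-2.
#' @param fragment_length Fragment size in nt (default 1020).
#' @param min_identity Retention identity threshold in percent (default 30).
#' @param min_coverage Minimum alignment length as a fraction of the
#'   fragment (default 0.7).
#' @param reciprocal Average both directions (default TRUE).
#' @return An `ani_result`: list with `ani`, per-direction mean identities
#'   and fragment counts.
#' @export
ani <- function(assembly_a, assembly_b,
                scoring = scoring_scheme("nucleotide"),
                fragment_length = 1020, min_identity = 30,
                min_coverage = 0.7, reciprocal = TRUE) {
  fa <- fragment_genome(assembly_a, fragment_length)
  fb <- fragment_genome(assembly_b, fragment_length)
  fwd <- .directional_ani(fa, assembly_b, scoring, min_identity, min_coverage)
  rev <- if (reciprocal)
    .directional_ani(fb, assembly_a, scoring, min_identity, min_coverage)
  else list(mean_identity = NA_real_, retained = NA_integer_, total = nrow(fb))
  vals <- c(fwd$mean_identity, if (reciprocal) rev$mean_identity)
  if (all(is.na(vals)))
    stop_classed("corepan_undefined_distance",
                 "no retained fragments in either direction; ANI undefined")
  structure(
    list(ani = mean(vals, na.rm = TRUE),
         forward_mean_identity = fwd$mean_identity,
         reverse_mean_identity = rev$mean_identity,
         fragments_total = c(forward = fwd$total, reverse = rev$total),
         fragments_retained = c(forward = fwd$retained, reverse = rev$retained)),
    class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> ANI = %.2f%%  (fwd %.2f over %d/%d, rev %s over %s/%s)\n",
              x$ani, x$forward_mean_identity,
              x$fragments_retained["forward"], x$fragments_total["forward"],
              formatC(x$reverse_mean_identity, format = "f", digits = 2),
              x$fragments_retained["reverse"], x$fragments_total["reverse"]))
  invisible(x)
}

.directional_aai <- function(qprot, sprot, scoring, min_identity,
                             min_alignment_length, min_coverage, prefilter) {
  qenc <- lapply(qprot, encode_seq, scoring = scoring, check_alphabet = FALSE)
  senc <- lapply(sprot, encode_seq, scoring = scoring, check_alphabet = FALSE)
  cand <- NULL
  if (prefilter && length(qprot) * length(sprot) > 2000) {
    nq <- length(qprot)
    pr <- shared_kmer_pairs_cpp(c(qenc, senc), scoring$seed_k,
                                scoring$ambig_code, 1L)
    keep <- (pr[, 1L] <= nq) != (pr[, 2L] <= nq)
    pr <- pr[keep, , drop = FALSE]
    qi <- ifelse(pr[, 1L] <= nq, pr[, 1L], pr[, 2L])
    si <- ifelse(pr[, 1L] <= nq, pr[, 2L], pr[, 1L]) - nq
    cand <- split(si, qi)
  }
  idents <- numeric(0)
  for (q in seq_along(qprot)) {
    subj_idx <- if (is.null(cand)) seq_along(sprot) else cand[[as.character(q)]]
    if (is.null(subj_idx) || !length(subj_idx)) next
    best <- NULL
    for (s in sort(names(sprot)[subj_idx])) {
      hit <- .align_encoded(qenc[[q]], senc[[s]], scoring,
                            a_id = names(qprot)[q], b_id = s)
      if (is.null(hit)) next
      if (hit$identity_pct < min_identity) next
      if (hit$alignment_length < min_alignment_length) next
      if (hit$query_coverage < min_coverage) next
      if (is.null(best) || hit$score > best$score ||
          (hit$score == best$score && hit$identity_pct > best$identity_pct))
        best <- hit
    }
    if (!is.null(best)) idents <- c(idents, best$identity_pct)
  }
  list(mean_identity = if (length(idents)) mean(idents) else NA_real_,
       retained = length(idents), total = length(qprot))
}

#' Average amino acid identity of two proteomes
#'
#' For each protein of one proteome, local alignments against every protein
#' of the other are filtered by the three removal rules (identity < 30%,
#' alignment length < 30 aa, alignment spanning < 70% of the query
#' protein); among surviving hits only the best (highest score, ties by
#' identity then subject id) contributes its identity. The reciprocal mean
#' of the two directional means is reported.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences.
#' @param scoring Protein [scoring_scheme()].
#' @param min_identity Filter (i) threshold in percent (default 30).
#' @param min_alignment_length Filter (ii) threshold in aa (default 30).
#' @param min_coverage Filter (iii) threshold as a fraction of the query
#'   protein length (default 0.7).
#' @param reciprocal Average both directions (default TRUE).
#' @param prefilter Use the shared 3-mer prefilter on large proteome pairs.
#' @return An `aai_result`: list with `aai`, per-direction mean identities
#'   and retained-hit counts.
#' @export
aai <- function(proteome_a, proteome_b,
                scoring = scoring_scheme("protein"),
                min_identity = 30, min_alignment_length = 30,
                min_coverage = 0.7, reciprocal = TRUE, prefilter = TRUE) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("empty proteome", call. = FALSE)
  if (is.null(names(proteome_a)))
    names(proteome_a) <- paste0("a", seq_along(proteome_a))
  if (is.null(names(proteome_b)))
    names(proteome_b) <- paste0("b", seq_along(proteome_b))
  fwd <- .directional_aai(proteome_a, proteome_b, scoring, min_identity,
                          min_alignment_length, min_coverage, prefilter)
  rev <- if (reciprocal)
    .directional_aai(proteome_b, proteome_a, scoring, min_identity,
                     min_alignment_length, min_coverage, prefilter)
  else list(mean_identity = NA_real_, retained = NA_integer_,
            total = length(proteome_b))
  vals <- c(fwd$mean_identity, if (reciprocal) rev$mean_identity)
  if (all(is.na(vals)))
    stop_classed("corepan_undefined_distance",
                 "zero retained hits in both directions; AAI undefined")
  structure(
    list(aai = mean(vals, na.rm = TRUE),
         forward_mean_identity = fwd$mean_identity,
         reverse_mean_identity = rev$mean_identity,
         hits_retained = c(forward = fwd$retained, reverse = rev$retained)),
    class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  cat(sprintf("<aai_result> AAI = %.2f%%  (fwd %.2f on %d hits, rev %s on %s hits)\n",
              x$aai, x$forward_mean_identity, x$hits_retained["forward"],
              formatC(x$reverse_mean_identity, format = "f", digits = 2),
              x$hits_retained["reverse"]))
  invisible(x)
}

#' Pairwise ANI or AAI matrix for a genome set
#'
#' @param inputs Named list: assemblies (for `ani`) or proteomes (for
#'   `aai`), one element per genome.
#' @param method `"ani"` or `"aai"`.
#' @param ... Passed to [ani()] or [aai()].
#' @return Symmetric numeric matrix (percent, diagonal 100).
#' @export
pairwise_identity_matrix <- function(inputs, method = c("ani", "aai"), ...) {
  method <- match.arg(method)
  ids <- names(inputs)
  out <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        v <- if (method == "ani") ani(inputs[[i]], inputs[[j]], ...)$ani
             else aai(inputs[[i]], inputs[[j]], ...)$aai
        out[i, j] <- out[j, i] <- v
      }
    }
  }
  out
}
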