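#' Best local alignment of two DNA sequences over both strands
#'
#' Finds the best-scoring Smith-Waterman local alignment of `query` against
#' `target`, trying the forward and the reverse-complement orientation of the
#' target and keeping the higher-scoring one (forward wins ties). `N` bases
#' match nothing, including other `N`s. Identity is defined as
#' matches / alignment columns, where gap positions count as columns, and
#' coverage of each sequence is the aligned fraction of its length.
#'
#' @param query,target DNA sequences (single character strings over
#'   `{A,C,G,T,N}`).
#' @param match,mismatch,gap alignment scores; `gap` is a linear per-base gap
#'   penalty (must be negative).
#' @param mode `"local"` for Smith-Waterman, `"global"` for end-to-end
#'   Needleman-Wunsch (used by full-length coverage rules, where terminal
#'   gaps must count as alignment columns).
#' @return an object of class `alignment_result`: a list with `identity`,
#'   `query_coverage`, `target_coverage`, `strand` (`"+"`/`"-"`),
#'   `query_span` and `target_span` (0-based half-open intervals on the
#'   original sequences), `n_match`, `n_columns` and `score`.
#' @examples
#' local_align("ACGTACGT", "TTACGTACGTTT")
#' @export
local_align <- function(query, target, match = 1, mismatch = -1, gap = -2,
                        mode = c("local", "global")) {
  mode <- match.arg(mode)
  query <- .check_dna(query, "query")
  target <- .check_dna(target, "target")
  stopifnot(length(query) == 1L, length(target) == 1L, gap < 0)
  res <- .align_batch(query, c(target, rev_comp(target)), match, mismatch,
                      gap, mode)
  nm <- .nmatch_nfree(res, query, c(target, rev_comp(target)))
  fwd <- .extract_alignment(res, 1L, query, target, strand = "+", nm = nm)
  rev <- .extract_alignment(res, 2L, query, target, strand = "-", nm = nm)
  if (rev$score > fwd$score) rev else fwd
}

# Vectorised alignment of one query against many targets (one orientation).
# Returns the PairwiseAlignments object.
.align_batch <- function(query, targets, match = 1, mismatch = -1, gap = -2,
                         mode = "local") {
  pat <- Biostrings::DNAStringSet(rep(query, length(targets)))
  Biostrings::pairwiseAlignment(
    pattern = pat,
    subject = Biostrings::DNAStringSet(targets),
    type = mode,
    substitutionMatrix = .sub_matrix(match, mismatch),
    gapOpening = 0,
    gapExtension = -gap
  )
}


# nmatch() counts positions where the aligned characters are equal, which
# would let N "match" N; subtract aligned N-N pairs (N matches nothing).
.nmatch_nfree <- function(pa, query, targets) {
  nm <- Biostrings::nmatch(pa)
  if (!grepl("N", query, fixed = TRUE)) return(nm)
  idx <- which(grepl("N", targets, fixed = TRUE))
  if (length(idx) == 0L) return(nm)
  ap <- as.character(Biostrings::alignedPattern(pa))[idx]
  as_ <- as.character(Biostrings::alignedSubject(pa))[idx]
  for (k in seq_along(idx)) {
    pc <- strsplit(ap[k], "")[[1]]
    sc <- strsplit(as_[k], "")[[1]]
    nm[idx[k]] <- nm[idx[k]] - sum(pc == "N" & sc == "N")
  }
  nm
}

# Alignment columns: Biostrings nchar() covers the aligned region only; in
# end-to-end alignments the unaligned sequence ends are end gaps and count
# as columns too.
.aln_columns <- function(pa, qlens, tlens) {
  nc <- Biostrings::nchar(pa)
  if (Biostrings::type(pa) == "local") return(nc)
  qsp <- IRanges::end(Biostrings::pattern(pa)) -
    IRanges::start(Biostrings::pattern(pa)) + 1L
  tsp <- IRanges::end(Biostrings::subject(pa)) -
    IRanges::start(Biostrings::subject(pa)) + 1L
  nc + (qlens - qsp) + (tlens - tsp)
}

# Pull alignment i out of a PairwiseAlignments object into an
# alignment_result, mapping minus-strand target coordinates back to the
# original target (targets at even positions are assumed reverse-complemented
# when strand == "-").
.extract_alignment <- function(pa, i, query, target, strand,
                               nm = Biostrings::nmatch(pa)) {
  qlen <- nchar(query)
  tlen <- nchar(target)
  ncol <- .aln_columns(pa, qlen, tlen)[i]
  nmat <- nm[i]
  qs <- IRanges::start(Biostrings::pattern(pa))[i]
  qe <- IRanges::end(Biostrings::pattern(pa))[i]
  ts <- IRanges::start(Biostrings::subject(pa))[i]
  te <- IRanges::end(Biostrings::subject(pa))[i]
  if (strand == "-") {
    # coordinates were on the reverse complement; map back
    ts2 <- tlen - te + 1L
    te <- tlen - ts + 1L
    ts <- ts2
  }
  structure(list(
    identity = if (ncol > 0) nmat / ncol else 0,
    query_coverage = max(0L, qe - qs + 1L) / qlen,
    target_coverage = max(0L, te - ts + 1L) / tlen,
    strand = strand,
    query_span = c(qs - 1L, qe),
    target_span = c(ts - 1L, te),
    n_match = nmat,
    n_columns = ncol,
    score = Biostrings::score(pa)[i]
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment> identity %.3f (%d/%d), strand %s, query cov %.3f, target cov %.3f\n",
    x$identity, x$n_match, x$n_columns, x$strand,
    x$query_coverage, x$target_coverage))
  invisible(x)
}

# Does any alignment of `query` vs the current representative meet the
# identity/coverage thresholds? Vectorised over representatives; returns the
# index of the first representative (in `reps` order) that matches, or 0L.
# Representatives are screened with a shared-word prefilter for long
# sequences (both >= 200 nt), where a true match at these thresholds always
# shares exact 12-mers.
.first_matching_rep <- function(query, reps, identity_min, coverage_rule,
                                coverage_min, match = 1, mismatch = -1,
                                gap = -2, qwords = NULL, rep_words = NULL) {
  if (length(reps) == 0L) return(0L)
  qlen <- nchar(query)
  rlens <- nchar(reps)
  cand <- rep(TRUE, length(reps))

  # exact identity shortcut
  exact <- reps == query
  if (any(exact)) return(which(exact)[1L])

  # identity upper bound: matches <= min(len), columns >= max(len)
  if (coverage_rule == "both_full") {
    cand <- cand & (pmin(qlen, rlens) / pmax(qlen, rlens) >= identity_min)
  }
  # word prefilter for long sequences
  long <- cand & qlen >= 200L & rlens >= 200L
  if (any(long)) {
    if (is.null(qwords)) qwords <- .seq_words(query, 12L)
    keep <- vapply(which(long), function(j) {
      if (!is.null(rep_words) && !is.null(rep_words[[j]])) {
        length(intersect(qwords, rep_words[[j]])) > 0L
      } else {
        .shares_word(qwords, reps[j], 12L)
      }
    }, logical(1))
    cand[which(long)[!keep]] <- FALSE
  }
  idx <- which(cand)
  if (length(idx) == 0L) return(0L)

  mode <- if (coverage_rule == "both_full") "global" else "local"
  for (orient in c("+", "-")) {
    tg <- if (orient == "+") reps[idx] else rev_comp(reps[idx])
    pa <- .align_batch(query, tg, match, mismatch, gap, mode)
    ncol <- .aln_columns(pa, qlen, rlens[idx])
    idn <- ifelse(ncol > 0, .nmatch_nfree(pa, query, tg) / ncol, 0)
    qcov <- (IRanges::end(Biostrings::pattern(pa)) -
               IRanges::start(Biostrings::pattern(pa)) + 1L) / qlen
    tcov <- (IRanges::end(Biostrings::subject(pa)) -
               IRanges::start(Biostrings::subject(pa)) + 1L) / rlens[idx]
    ok <- idn >= identity_min & switch(
      coverage_rule,
      both_full = rep(TRUE, length(idx)),  # global alignment: full span
      shorter_min = ifelse(qlen <= rlens[idx], qcov, tcov) >= coverage_min,
      both_min = qcov >= coverage_min & tcov >= coverage_min
    )
    if (orient == "+") hit_fwd <- ok else hit_rev <- ok
  }
  hit <- hit_fwd | hit_rev
  if (any(hit)) idx[which(hit)[1L]] else 0L
}

# Best-of-both-strands alignment statistics of one query against many
# targets, vectorised. Returns a data.frame with one row per target:
# identity, query_coverage, target_coverage, strand, target span (0-based
# half-open, on the original target).
.batch_align_stats <- function(query, targets, match = 1, mismatch = -1,
                               gap = -2, mode = "local") {
  qlen <- nchar(query)
  tlens <- nchar(targets)
  stats_one <- function(tg, strand) {
    pa <- .align_batch(query, tg, match, mismatch, gap, mode)
    ncol <- .aln_columns(pa, qlen, tlens)
    ts <- IRanges::start(Biostrings::subject(pa))
    te <- IRanges::end(Biostrings::subject(pa))
    if (strand == "-") {
      ts2 <- tlens - te + 1L
      te <- tlens - ts + 1L
      ts <- ts2
    }
    data.frame(
      identity = ifelse(ncol > 0, .nmatch_nfree(pa, query, tg) / ncol, 0),
      query_coverage = (IRanges::end(Biostrings::pattern(pa)) -
                          IRanges::start(Biostrings::pattern(pa)) + 1L) / qlen,
      target_coverage = (te - ts + 1L) / tlens,
      strand = strand, tstart = ts - 1L, tend = te,
      score = Biostrings::score(pa))
  }
  fwd <- stats_one(targets, "+")
  rev <- stats_one(rev_comp(targets), "-")
  use_rev <- rev$score > fwd$score
  out <- fwd
  out[use_rev, ] <- rev[use_rev, ]
  out
}

.seq_words <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

.shares_word <- function(qwords, target, k) {
  if (length(qwords) == 0L) return(FALSE)
  twords <- c(.seq_words(target, k), .seq_words(rev_comp(target), k))
  length(intersect(qwords, twords)) > 0L
}
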