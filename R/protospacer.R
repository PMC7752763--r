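#' Find protospacer matches of spacers on contigs
#'
#' Seed-and-extend search of each non-redundant spacer against every contig
#' on both strands: exact seed words of `word_size` nucleotides anchor
#' candidate windows, which are then locally aligned and filtered on identity
#' and spacer coverage. Overlapping hits of the same spacer on the same
#' contig are merged, keeping the highest-identity one.
#'
#' @param spacers named character vector of spacer representative sequences
#'   (names are spacer cluster ids).
#' @param contigs named character vector of contig sequences.
#' @param identity_min minimum identity (default 0.95).
#' @param coverage_min minimum spacer (query) coverage (default 0.95).
#' @param word_size seed word length in nt (default 7).
#' @return data.frame of hits: `spacer`, `contig`, `strand`, `start`, `end`
#'   (0-based half-open contig interval), `identity`, `coverage`.
#' @export
find_hits <- function(spacers, contigs, identity_min = 0.95,
                      coverage_min = 0.95, word_size = 7) {
  stopifnot(length(contigs) > 0, !is.null(names(contigs)))
  empty <- data.frame(spacer = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      coverage = numeric(0))
  if (length(spacers) == 0L) return(empty)
  if (is.null(names(spacers))) names(spacers) <- paste0("sp_", seq_along(spacers))

  # oriented queries: forward spacer (+) and reverse complement (-); both are
  # searched against the forward contig so hit coordinates are direct
  oriented <- data.frame(
    spacer = rep(names(spacers), 2L),
    strand = rep(c("+", "-"), each = length(spacers)),
    seq = c(unname(spacers), rev_comp(unname(spacers))))

  seeds <- .seed_table(oriented$seq, word_size)
  if (nrow(seeds) == 0L) return(empty)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$word))

  out <- list()
  for (ct in names(contigs)) {
    tseq <- .check_dna(contigs[[ct]], "contig")
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(tseq))
    cnt <- S4Vectors::elementNROWS(m)
    hit_idx <- which(cnt > 0L)
    if (length(hit_idx) == 0L) next
    cand <- do.call(rbind, lapply(hit_idx, function(k) {
      st <- IRanges::start(m[[k]])
      data.frame(q = seeds$query[k], anchor = st - seeds$offset[k])
    }))
    # collapse nearby anchors of the same oriented query
    cand <- unique(cand)
    sp <- split(cand$anchor, cand$q)
    windows <- do.call(rbind, lapply(names(sp), function(qn) {
      a <- sort(unique(sp[[qn]]))
      keep <- c(TRUE, diff(a) > 4L)
      data.frame(q = as.integer(qn), anchor = a[keep])
    }))
    pad <- 6L
    tlen <- nchar(tseq)
    qlens <- nchar(oriented$seq)[windows$q]
    ws <- pmax(1L, windows$anchor - pad)
    we <- pmin(tlen, windows$anchor + qlens + pad)
    # orientation is explicit in the query, so windows are aligned forward
    # only, in one vectorised call
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(oriented$seq[windows$q]),
      subject = Biostrings::DNAStringSet(substring(tseq, ws, we)),
      type = "local", substitutionMatrix = .sub_matrix(),
      gapOpening = 0, gapExtension = 2)
    ncols <- Biostrings::nchar(pa)
    nm <- Biostrings::nmatch(pa)
    nn <- grepl("N", oriented$seq[windows$q], fixed = TRUE) &
      grepl("N", substring(tseq, ws, we), fixed = TRUE)
    for (k in which(nn)) {  # N never matches, not even another N
      pc <- strsplit(as.character(Biostrings::alignedPattern(pa)[k]), "")[[1]]
      sc <- strsplit(as.character(Biostrings::alignedSubject(pa)[k]), "")[[1]]
      nm[k] <- nm[k] - sum(pc == "N" & sc == "N")
    }
    idn <- ifelse(ncols > 0, nm / ncols, 0)
    qcov <- (IRanges::end(Biostrings::pattern(pa)) -
               IRanges::start(Biostrings::pattern(pa)) + 1L) / qlens
    ok <- idn >= identity_min & qcov >= coverage_min
    if (any(ok)) {
      out[[length(out) + 1L]] <- data.frame(
        spacer = oriented$spacer[windows$q[ok]], contig = ct,
        strand = oriented$strand[windows$q[ok]],
        start = ws[ok] - 1L + IRanges::start(Biostrings::subject(pa))[ok] - 1L,
        end = ws[ok] - 1L + IRanges::end(Biostrings::subject(pa))[ok],
        identity = idn[ok], coverage = qcov[ok])
    }
  }
  if (length(out) == 0L) return(empty)
  hits <- do.call(rbind, out)
  .merge_overlapping_hits(hits)
}

# k-mer seed table for a set of oriented queries: one row per (query, offset)
.seed_table <- function(qseqs, word_size) {
  out <- list()
  for (i in seq_along(qseqs)) {
    s <- qseqs[i]
    n <- nchar(s)
    if (n < word_size) next
    off <- 0:(n - word_size)
    w <- substring(s, off + 1L, off + word_size)
    ok <- !grepl("N", w, fixed = TRUE)
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(query = i, offset = off[ok],
                                          word = w[ok])
  }
  if (length(out) == 0L) {
    return(data.frame(query = integer(0), offset = integer(0),
                      word = character(0)))
  }
  do.call(rbind, out)
}

# keep the highest-identity hit among overlapping same-spacer same-contig hits
.merge_overlapping_hits <- function(hits) {
  hits <- hits[order(hits$spacer, hits$contig, -hits$identity,
                     hits$start), ]
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$spacer, hits$contig)
  for (g in split(seq_len(nrow(hits)), key)) {
    if (length(g) < 2L) next
    taken <- list()
    for (i in g) {
      ov <- any(vapply(taken, function(iv) {
        hits$start[i] < iv[2L] && hits$end[i] > iv[1L]
      }, logical(1)))
      if (ov) keep[i] <- FALSE
      else taken[[length(taken) + 1L]] <- c(hits$start[i], hits$end[i])
    }
  }
  res <- hits[keep, ]
  res <- res[order(res$contig, res$start, res$spacer), ]
  rownames(res) <- NULL
  res
}

#' Define protospacer-containing contigs (PSCCs)
#'
#' A PSCC is a contig carrying at least one retained protospacer hit and no
#' CRISPR signal of its own: contigs containing a repeat match (at the
#' repeat-stage thresholds) or flagged as CRISPR-locus contigs are excluded
#' to avoid array self-matching.
#'
#' @param hits data.frame from [find_hits()].
#' @param repeat_seqs named character vector of repeat representative
#'   sequences screened against candidate contigs.
#' @param contigs named character vector of contig sequences.
#' @param crispr_locus_contigs character vector of contig ids known to encode
#'   CRISPR loci (excluded outright).
#' @param repeat_identity_min,repeat_coverage_min repeat-screen thresholds
#'   (defaults 0.75 and 0.80, the repeat linking thresholds).
#' @param seed_word exact word (nt) a repeat must share with a contig before
#'   gapped alignment is attempted, mirroring the default BLASTN word size;
#'   prevents unconstrained dynamic programming from reporting weak chance
#'   alignments that a sequence-search tool would never emit (default 11).
#' @return an object of class `pscc_set`: list with `contigs` (PSCC ids),
#'   `hits` (hits on PSCCs), `excluded` (contigs removed by the repeat /
#'   locus screen) and `n_protospacers` (named count per PSCC).
#' @export
define_psccs <- function(hits, repeat_seqs, contigs,
                         crispr_locus_contigs = character(0),
                         repeat_identity_min = 0.75,
                         repeat_coverage_min = 0.80, seed_word = 11) {
  cand <- unique(hits$contig)
  excluded <- intersect(cand, crispr_locus_contigs)
  screen <- setdiff(cand, excluded)
  if (length(screen)) {
    ct_words <- lapply(screen, function(ct) {
      c(.seq_words(contigs[[ct]], seed_word),
        .seq_words(rev_comp(contigs[[ct]]), seed_word))
    })
    names(ct_words) <- screen
    for (rp in repeat_seqs) {
      if (length(screen) == 0L) break
      rp_words <- .seq_words(rp, seed_word)
      seeded <- vapply(screen, function(ct) {
        length(intersect(rp_words, ct_words[[ct]])) > 0L
      }, logical(1))
      if (!any(seeded)) next
      st <- .batch_align_stats(rp, unname(contigs[screen[seeded]]))
      bad <- screen[seeded][st$identity >= repeat_identity_min &
                             st$query_coverage >= repeat_coverage_min]
      excluded <- c(excluded, bad)
      screen <- setdiff(screen, bad)
    }
  }
  keep <- setdiff(cand, excluded)
  kept_hits <- hits[hits$contig %in% keep, ]
  rownames(kept_hits) <- NULL
  n_ps <- table(factor(kept_hits$contig, levels = keep))
  structure(list(contigs = keep, hits = kept_hits,
                 excluded = excluded,
                 n_protospacers = setNames(as.integer(n_ps), keep)),
            class = "pscc_set")
}

#' @export
print.pscc_set <- function(x, ...) {
  cat(sprintf(
    "<pscc_set> %d PSCCs, %d protospacers (%d contigs excluded); mean %.2f per PSCC\n",
    length(x$contigs), nrow(x$hits), length(x$excluded),
    if (length(x$contigs)) mean(x$n_protospacers) else NA_real_))
  invisible(x)
}
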