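#' Greedy incremental identity clustering of DNA sequences
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length (longest
#' first, ties broken lexicographically), then each sequence joins the first
#' existing cluster whose representative it matches at the given identity and
#' coverage thresholds (both strands are tried), or founds a new cluster.
#' Identical sequences are pooled before alignment, so exact duplicates never
#' trigger alignment work.
#'
#' Coverage rules:
#' \describe{
#'   \item{`both_full`}{both sequences must be covered end to end; matching
#'     uses a global alignment so terminal mismatches and length differences
#'     count against identity (used for spacers).}
#'   \item{`shorter_min`}{the aligned fraction of the shorter sequence must be
#'     at least `coverage_min` (used for repeats and mobile elements).}
#'   \item{`both_min`}{the aligned fractions of both sequences must be at
#'     least `coverage_min` (used for flanking sequences).}
#' }
#'
#' @param seqs character vector of DNA sequences; names are used as sequence
#'   ids (defaults to `seq_1 ... seq_n`).
#' @param identity_min minimum identity (matches / alignment columns), in
#'   `(0, 1]`.
#' @param coverage_rule one of `"both_full"`, `"shorter_min"`, `"both_min"`.
#' @param coverage_min minimum coverage fraction for the coverage-constrained
#'   rules, in `(0, 1]`; ignored for `both_full`.
#' @param element_kind free-text tag stored on each cluster (e.g. `"spacer"`).
#' @return an object of class `seq_clusters`: a list of clusters, each with
#'   `cluster_id`, `representative`, `rep_id`, `member_ids`, `member_seqs`
#'   and `element_kind`.
#' @examples
#' greedy_cluster(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTTTTTTT"),
#'                identity_min = 0.9, coverage_rule = "both_full")
#' @export
greedy_cluster <- function(seqs, identity_min,
                           coverage_rule = c("both_full", "shorter_min",
                                             "both_min"),
                           coverage_min = 1, element_kind = "sequence") {
  coverage_rule <- match.arg(coverage_rule)
  stopifnot(identity_min > 0, identity_min <= 1,
            coverage_min > 0, coverage_min <= 1)
  if (length(seqs) == 0L) {
    return(structure(list(), class = "seq_clusters"))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  seqs[] <- vapply(seqs, .check_dna, character(1))

  ord <- order(-nchar(seqs), seqs, names(seqs))
  seqs <- seqs[ord]

  # pool exact duplicates, keeping the ordered first occurrence as carrier
  uniq <- !duplicated(seqs)
  carriers <- seqs[uniq]
  dup_members <- split(names(seqs), match(seqs, carriers))

  reps <- character(0)
  rep_words <- list()  # cached 12-mer sets (fwd + revcomp) per representative
  assign_cl <- integer(length(carriers))
  for (i in seq_along(carriers)) {
    qwords <- if (nchar(carriers[i]) >= 200L) {
      .seq_words(carriers[i], 12L)
    } else NULL
    j <- .first_matching_rep(carriers[i], reps, identity_min, coverage_rule,
                             coverage_min, qwords = qwords,
                             rep_words = rep_words)
    if (j == 0L) {
      reps <- c(reps, carriers[i])
      rep_words[[length(reps)]] <- if (!is.null(qwords)) {
        c(qwords, .seq_words(rev_comp(carriers[i]), 12L))
      } else NA
      assign_cl[i] <- length(reps)
    } else {
      assign_cl[i] <- j
    }
  }

  clusters <- lapply(seq_along(reps), function(k) {
    idx <- which(assign_cl == k)
    member_ids <- unlist(dup_members[as.character(idx)], use.names = FALSE)
    member_seqs <- seqs[member_ids]
    list(cluster_id = sprintf("%s_cl_%03d", element_kind, k),
         representative = unname(reps[k]),
         rep_id = names(carriers)[idx[1L]],
         member_ids = member_ids,
         member_seqs = unname(member_seqs),
         element_kind = element_kind)
  })
  structure(clusters, class = "seq_clusters")
}

#' @export
print.seq_clusters <- function(x, ...) {
  cat(sprintf("<seq_clusters> %d clusters, %d members (%s)\n",
              length(x), sum(lengths(lapply(x, `[[`, "member_ids"))),
              if (length(x)) x[[1L]]$element_kind else "empty"))
  invisible(x)
}

#' Cluster membership as a table
#'
#' @param clusters a `seq_clusters` object.
#' @return data.frame with columns `cluster_id`, `member_id`, `representative`
#'   and `element_kind`.
#' @export
cluster_membership <- function(clusters) {
  stopifnot(inherits(clusters, "seq_clusters"))
  if (length(clusters) == 0L) {
    return(data.frame(cluster_id = character(0), member_id = character(0),
                      representative = character(0),
                      element_kind = character(0)))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, member_id = cl$member_ids,
               representative = cl$representative,
               element_kind = cl$element_kind)
  }))
}

#' Representative sequences of a clustering
#'
#' @param clusters a `seq_clusters` object.
#' @return named character vector (names = cluster ids).
#' @export
cluster_representatives <- function(clusters) {
  stopifnot(inherits(clusters, "seq_clusters"))
  setNames(vapply(clusters, `[[`, character(1), "representative"),
           vapply(clusters, `[[`, character(1), "cluster_id"))
}

#' Iterative tuning of repeat clustering parameters
#'
#' Starting from 99% identity and 100% coverage, both parameters are reduced
#' by 5 percentage points per iteration until the supplied repeats (known to
#' come from a single CRISPR locus) regroup into a single cluster. The first
#' parameter pair achieving a single cluster is returned.
#'
#' @param known_repeats character vector of at least two repeat sequences from
#'   one locus.
#' @param coverage_rule coverage rule used during the ladder; repeats use
#'   coverage of the shorter sequence.
#' @return named numeric vector `c(identity = ..., coverage = ...)`.
#' @export
tune_repeat_parameters <- function(known_repeats,
                                   coverage_rule = "shorter_min") {
  if (length(known_repeats) < 2L) {
    stop("at least two known repeats are required", call. = FALSE)
  }
  identity <- 0.99
  coverage <- 1.00
  while (identity >= 0.05 && coverage >= 0.05) {
    cl <- greedy_cluster(known_repeats, identity_min = identity,
                         coverage_rule = coverage_rule,
                         coverage_min = coverage, element_kind = "repeat")
    if (length(cl) == 1L) {
      return(c(identity = identity, coverage = coverage))
    }
    identity <- round(identity - 0.05, 10)
    coverage <- round(coverage - 0.05, 10)
  }
  stop("parameter ladder exhausted below (0.05, 0.05) without reaching a ",
       "single cluster", call. = FALSE)
}
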