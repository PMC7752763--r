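#' Transform a count matrix to counts per million (c.p.m.)
#'
#' Each sample column is scaled so that nonzero columns sum to one million;
#' all-zero columns are left at zero.
#'
#' @param counts nonnegative numeric matrix, features x samples.
#' @return matrix of c.p.m. values with a `value_kind` attribute `"cpm"`.
#' @export
to_cpm <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  tot <- colSums(counts)
  scale <- ifelse(tot > 0, 1e6 / tot, 0)
  out <- sweep(counts, 2L, scale, `*`)
  attr(out, "value_kind") <- "cpm"
  out
}

#' Presence calls from a c.p.m. matrix
#'
#' A feature is present in a sample when its value reaches the cutoff
#' (inclusive); the default cutoff of 1 c.p.m. retains low-abundance spacers
#' that recruit few reads.
#'
#' @param cpm numeric matrix (typically from [to_cpm()]).
#' @param cutoff minimum value deemed present (default 1).
#' @return logical matrix of the same shape.
#' @export
presence <- function(cpm, cutoff = 1) {
  stopifnot(is.matrix(cpm))
  cpm >= cutoff
}

#' Consolidate per-source spacer coverages into cluster abundances
#'
#' Raw abundance of a non-redundant spacer cluster in a sample is the sum of
#' the coverages of all its member detections in that sample, across sources.
#'
#' @param coverages data.frame with columns `member_id`, `sample`, `coverage`.
#' @param membership data.frame with columns `member_id`, `cluster_id`
#'   (every member must map to a cluster).
#' @param samples optional character vector fixing the column order.
#' @return numeric matrix, clusters x samples, with `value_kind = "raw"`.
#' @export
consolidate_spacer_abundance <- function(coverages, membership,
                                         samples = NULL) {
  stopifnot(all(c("member_id", "sample", "coverage") %in% names(coverages)),
            all(c("member_id", "cluster_id") %in% names(membership)))
  orphans <- setdiff(unique(coverages$member_id), membership$member_id)
  if (length(orphans)) {
    stop("members without a cluster: ",
         paste(head(orphans, 10L), collapse = ", "), call. = FALSE)
  }
  cl <- membership$cluster_id[match(coverages$member_id,
                                    membership$member_id)]
  if (is.null(samples)) samples <- sort(unique(as.character(coverages$sample)))
  clusters <- sort(unique(membership$cluster_id))
  m <- matrix(0, length(clusters), length(samples),
              dimnames = list(clusters, samples))
  agg <- tapply(coverages$coverage,
                list(cl, as.character(coverages$sample)), sum)
  m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  attr(m, "value_kind") <- "raw"
  m
}

#' Feature-level presence and relative abundance from depth tables
#'
#' Feature abundance per sample is the length-weighted mean metagenomic (MG)
#' depth of its contigs; relative abundance rescales each sample to 100%.
#' Presence uses detection in either the MG or the metatranscriptomic (MT)
#' data: a feature is present when its weighted MG or MT depth exceeds
#' `min_depth`.
#'
#' @param depth_mg,depth_mt contig-by-sample depth matrices (same dimnames).
#' @param contig2feature data.frame with columns `contig`, `feature`.
#' @param contig_lengths named numeric vector of contig lengths (> 0).
#' @param min_depth depth strictly above which a feature counts as detected
#'   (default 0).
#' @return list with `abundance` (length-weighted mean MG depth),
#'   `relative_abundance` (percent per sample, `value_kind = "relabund"`) and
#'   `presence` (logical matrix), all features x samples.
#' @export
feature_presence_and_relabund <- function(depth_mg, depth_mt, contig2feature,
                                          contig_lengths, min_depth = 0) {
  stopifnot(all(c("contig", "feature") %in% names(contig2feature)))
  cts <- contig2feature$contig
  if (any(is.na(contig_lengths[cts])) || any(contig_lengths[cts] <= 0)) {
    stop("all mapped contigs need a positive length", call. = FALSE)
  }
  missing <- setdiff(cts, rownames(depth_mg))
  if (length(missing)) {
    stop("contigs missing from depth table: ",
         paste(head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  feats <- sort(unique(contig2feature$feature))
  wmean <- function(depth) {
    out <- matrix(0, length(feats), ncol(depth),
                  dimnames = list(feats, colnames(depth)))
    for (f in feats) {
      fc <- cts[contig2feature$feature == f]
      w <- contig_lengths[fc]
      out[f, ] <- colSums(depth[fc, , drop = FALSE] * w) / sum(w)
    }
    out
  }
  ab_mg <- wmean(depth_mg)
  ab_mt <- wmean(depth_mt[rownames(depth_mg), colnames(depth_mg),
                          drop = FALSE])
  tot <- colSums(ab_mg)
  rel <- sweep(ab_mg, 2L, ifelse(tot > 0, 100 / tot, 0), `*`)
  attr(rel, "value_kind") <- "relabund"
  list(abundance = ab_mg,
       relative_abundance = rel,
       presence = ab_mg > min_depth | ab_mt > min_depth)
}
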