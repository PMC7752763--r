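#' Consolidate plasmid/phage predictor flags into iMGE labels
#'
#' Ensemble consolidation of two plasmid predictors and two phage predictors:
#' a contig is labelled `plasmid` if either plasmid predictor is positive and
#' no phage predictor is, `phage` in the mirrored case, `ambiguous` if both a
#' plasmid and a phage predictor are positive, `unclassified` if all four are
#' negative but the contig carries at least one protospacer, and `none`
#' (not an invasive element) otherwise.
#'
#' @param flags data.frame with columns `contig`, `plasmid_cbar`,
#'   `plasmid_plasflow`, `phage_virsorter`, `phage_virfinder` (logical).
#' @param pscc_contigs character vector of protospacer-containing contig ids.
#' @return data.frame with columns `contig`, `label`.
#' @export
consolidate_imge_labels <- function(flags, pscc_contigs = character(0)) {
  need <- c("contig", "plasmid_cbar", "plasmid_plasflow",
            "phage_virsorter", "phage_virfinder")
  stopifnot(all(need %in% names(flags)))
  pl <- flags$plasmid_cbar | flags$plasmid_plasflow
  ph <- flags$phage_virsorter | flags$phage_virfinder
  is_pscc <- flags$contig %in% pscc_contigs
  label <- ifelse(pl & ph, "ambiguous",
           ifelse(pl, "plasmid",
           ifelse(ph, "phage",
           ifelse(is_pscc, "unclassified", "none"))))
  data.frame(contig = flags$contig, label = label)
}

#' Cluster labelled iMGE contigs into representative elements
#'
#' Greedy identity clustering of invasive-element contigs at 80% identity
#' covering at least 50% of the shorter sequence; each cluster keeps the
#' label of its representative contig. A cluster counts as a PSCC when any
#' member contig carries a protospacer.
#'
#' @param seqs named character vector of contig sequences (contigs labelled
#'   `none` should be excluded by the caller).
#' @param labels data.frame from [consolidate_imge_labels()] covering `seqs`.
#' @param pscc_contigs character vector of PSCC contig ids.
#' @param identity_min,coverage_min clustering thresholds (defaults 0.80 and
#'   0.50 of the shorter sequence).
#' @return data.frame of iMGE records: `imge`, `representative_contig`,
#'   `label`, `is_pscc`, `n_members`, `member_contigs`
#'   (comma-separated).
#' @export
cluster_imges <- function(seqs, labels, pscc_contigs = character(0),
                          identity_min = 0.80, coverage_min = 0.50) {
  stopifnot(all(c("contig", "label") %in% names(labels)))
  if (length(seqs) == 0L) {
    return(data.frame(imge = character(0),
                      representative_contig = character(0),
                      label = character(0), is_pscc = logical(0),
                      n_members = integer(0), member_contigs = character(0)))
  }
  cl <- greedy_cluster(seqs, identity_min = identity_min,
                       coverage_rule = "shorter_min",
                       coverage_min = coverage_min, element_kind = "imge")
  lab <- setNames(labels$label, labels$contig)
  do.call(rbind, lapply(cl, function(x) {
    data.frame(imge = x$cluster_id,
               representative_contig = x$rep_id,
               label = unname(lab[x$rep_id]),
               is_pscc = any(x$member_ids %in% pscc_contigs),
               n_members = length(x$member_ids),
               member_contigs = paste(x$member_ids, collapse = ","))
  }))
}

#' Flag iMGEs detected only at the transcript level
#'
#' @param records iMGE record table from [cluster_imges()].
#' @param depth_mg,depth_mt contig-by-sample depth matrices.
#' @return `records` with a logical `mt_only` column: representative contig
#'   has zero metagenomic depth at every time point but nonzero
#'   metatranscriptomic depth somewhere.
#' @export
flag_mt_only <- function(records, depth_mg, depth_mt) {
  ct <- records$representative_contig
  mg0 <- rowSums(depth_mg[ct, , drop = FALSE] > 0) == 0
  mt1 <- rowSums(depth_mt[ct, , drop = FALSE] > 0) > 0
  records$mt_only <- unname(mg0 & mt1)
  records
}
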