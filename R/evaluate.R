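#' Compare a pipeline run against the planted ground truth
#'
#' Maps recovered spacer clusters and element records back to the planted
#' entities (via member ids) and scores the spacer-to-rMAG assignment, the
#' spacer-element links, the event categories and the gain lags.
#'
#' @param result a `pipeline_result` (stages through `events` required).
#' @param dataset the `synthetic_community` the pipeline ran on.
#' @return list with precision/recall of assignment and links, the fraction
#'   of correctly recovered event categories, the maximum absolute gain-lag
#'   error in days, the maximum sampling interval in days, and the recovered
#'   plasmid:phage ratio of the element records.
#' @export
evaluate_recovery <- function(result, dataset) {
  gt <- dataset$ground_truth
  # spacer cluster -> planted spacer id (strip the variant suffix)
  mem <- cluster_membership(result$spacer_clusters)
  mem$planted <- sub("_var$", "", mem$member_id)
  purity <- tapply(mem$planted, mem$cluster_id,
                   function(x) length(unique(x)))
  sp_map <- tapply(mem$planted, mem$cluster_id, function(x) x[1L])
  # element record -> planted element id (twins map to their original)
  rec <- result$imge_records
  members <- strsplit(rec$member_contigs, ",", fixed = TRUE)
  ct2imge <- setNames(
    c(gt$imges$imge_id, gt$twins$original_imge),
    c(gt$imges$contig, gt$twins$twin_contig))
  im_map <- setNames(vapply(members, function(m) {
    hits <- unique(stats::na.omit(ct2imge[m]))
    if (length(hits) == 1L) hits else NA_character_
  }, character(1)), rec$imge)

  # assignment recovery (spacer, rmag)
  truth_assign <- unique(paste(gt$spacers$spacer_id, gt$spacers$rmag))
  got_assign <- unique(paste(sp_map[result$assignment$spacer_cluster],
                             result$assignment$rmag))
  # link recovery (spacer, imge)
  truth_links <- unique(paste(gt$links$spacer_id, gt$links$imge_id))
  got_links <- unique(paste(sp_map[result$links$spacer],
                            im_map[result$links$imge]))
  pr <- function(got, truth) {
    c(precision = if (length(got)) mean(got %in% truth) else NA_real_,
      recall = if (length(truth)) mean(truth %in% got) else NA_real_)
  }

  # event categories per (spacer, imge, comparison)
  ev <- result$events
  ev$key <- paste(sp_map[ev$spacer], im_map[ev$imge], ev$comparison)
  ev <- ev[!duplicated(ev$key), ]
  truth_ev <- rbind(
    data.frame(key = paste(gt$links$spacer_id, gt$links$imge_id, "first"),
               category = gt$links$category_first),
    data.frame(key = paste(gt$links$spacer_id, gt$links$imge_id, "last"),
               category = gt$links$category_last))
  cmp <- merge(truth_ev, ev[, c("key", "category")], by = "key",
               suffixes = c("_truth", "_got"))
  event_recall <- if (nrow(truth_ev)) nrow(cmp) / nrow(truth_ev) else NA_real_
  event_accuracy <- if (nrow(cmp)) {
    mean(cmp$category_truth == cmp$category_got)
  } else NA_real_

  # gain lags (days) vs planted
  gains <- ev[ev$category == "gain", ]
  gt_gain <- gt$links[gt$links$category_first == "gain", ]
  gt_key <- paste(gt_gain$spacer_id, gt_gain$imge_id, "first")
  lag_err <- if (nrow(gains)) {
    planted <- setNames(gt_gain$lag_days, gt_key)[gains$key]
    abs(gains$lag_weeks * 7 - planted)
  } else numeric(0)

  labels <- table(result$imge_records$label)
  n_pl <- if ("plasmid" %in% names(labels)) labels[["plasmid"]] else 0L
  n_ph <- if ("phage" %in% names(labels)) labels[["phage"]] else 0L

  list(
    cluster_purity = mean(purity == 1),
    assignment = pr(got_assign, truth_assign),
    links = pr(got_links, truth_links),
    event_recall = event_recall,
    event_accuracy = event_accuracy,
    max_lag_error_days = if (length(lag_err)) max(lag_err, na.rm = TRUE)
                         else NA_real_,
    max_interval_days = max(as.numeric(diff(dataset$dates))),
    plasmid_phage_ratio = if (n_ph > 0) n_pl / n_ph else NA_real_)
}
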