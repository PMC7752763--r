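.pipeline_stages <- c("cluster", "link", "protospacer", "classify",
                      "abundance", "events", "networks", "model")

#' Run the full interaction-analysis pipeline
#'
#' Executes the analysis stages in dependency order on an in-memory dataset
#' (typically a `synthetic_community` or the result of [read_fixtures()]):
#' element clustering, locus-to-genome linking, protospacer detection,
#' element classification, abundance normalisation, event classification,
#' network construction and community linear modelling. Deterministic under
#' `seed`. If `out_dir` is given, stage outputs are written as TSV plus a
#' JSON manifest with checksums.
#'
#' @param dataset a `synthetic_community`-shaped list (see
#'   [simulate_community()] for the components).
#' @param stages character vector of stages to run (prerequisites must be
#'   included; default all).
#' @param out_dir optional output directory.
#' @param response_group family group modelled as response (default: the
#'   dataset's recorded response group, otherwise the most abundant bacterial
#'   group).
#' @param n_realizations random-model realizations (default 10000).
#' @param enrichment_N top-model set size for the enrichment step
#'   (default 50).
#' @param alpha coefficient significance level for the reduced model
#'   (default 0.05).
#' @param cpm_cutoff spacer presence cutoff in c.p.m. (default 1).
#' @param seed root seed; stage seeds are derived from it.
#' @return object of class `pipeline_result`: list of stage outputs (see the
#'   vignette for the full layout), plus `manifest` when `out_dir` is given.
#' @export
run_pipeline <- function(dataset, stages = .pipeline_stages, out_dir = NULL,
                         response_group = NULL, n_realizations = 10000,
                         enrichment_N = 50, alpha = 0.05, cpm_cutoff = 1,
                         seed = 1) {
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  need <- function(stage, deps) {
    missing <- setdiff(deps, stages)
    if (stage %in% stages && length(missing)) {
      stop("stage '", stage, "' requires stage(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  need("link", "cluster"); need("protospacer", "cluster")
  need("classify", "protospacer"); need("abundance", c("cluster", "classify"))
  need("events", c("link", "abundance")); need("networks", "events")
  need("model", "abundance")

  res <- list(config = list(seed = seed, stages = stages,
                            n_realizations = n_realizations,
                            enrichment_N = enrichment_N, alpha = alpha,
                            cpm_cutoff = cpm_cutoff))
  date_ids <- .iso_date(dataset$dates)
  el <- dataset$elements
  uniq_el <- function(kind) {
    e <- unique(el[el$kind == kind, c("element_id", "sequence")])
    setNames(e$sequence, e$element_id)
  }

  if ("cluster" %in% stages) {
    res$spacer_clusters <- greedy_cluster(uniq_el("spacer"), 0.90,
                                          "both_full",
                                          element_kind = "spacer")
    res$repeat_clusters <- greedy_cluster(uniq_el("repeat"), 0.80,
                                          "shorter_min", 0.75,
                                          element_kind = "repeat")
    res$flank_clusters <- greedy_cluster(uniq_el("flank"), 0.99,
                                         "both_min", 0.975,
                                         element_kind = "flank")
    res$locus_map <- build_locus_map(el, res$spacer_clusters,
                                     res$repeat_clusters, res$flank_clusters)
  }

  if ("link" %in% stages) {
    res$flank_candidates <- match_flanks_to_mags(
      res$flank_clusters, dataset$contigs, dataset$contig2mag)
    res$host_links <- confirm_with_repeats(
      res$flank_candidates, res$repeat_clusters, res$locus_map,
      dataset$contigs, dataset$contig2mag)
    res$assignment <- assign_spacers(res$host_links, res$locus_map,
                                     dataset$mag2rmag)
  }

  if ("protospacer" %in% stages) {
    res$hits <- find_hits(cluster_representatives(res$spacer_clusters),
                          dataset$contigs)
    res$pscc <- define_psccs(res$hits,
                             cluster_representatives(res$repeat_clusters),
                             dataset$contigs,
                             crispr_locus_contigs = unique(el$contig))
  }

  if ("classify" %in% stages) {
    res$labels <- consolidate_imge_labels(dataset$flags, res$pscc$contigs)
    imge_cts <- res$labels$contig[res$labels$label != "none"]
    res$imge_records <- cluster_imges(dataset$contigs[imge_cts], res$labels,
                                      res$pscc$contigs)
    res$imge_records <- flag_mt_only(res$imge_records, dataset$depth_mg,
                                     dataset$depth_mt)
  }

  if ("abundance" %in% stages) {
    sp_rows <- el[el$kind == "spacer", c("element_id", "sample", "coverage")]
    names(sp_rows)[1L] <- "member_id"
    mem <- cluster_membership(res$spacer_clusters)
    names(mem)[names(mem) == "member_id"] <- "member_id"
    res$spacer_raw <- consolidate_spacer_abundance(
      sp_rows, mem[, c("member_id", "cluster_id")], samples = date_ids)
    res$spacer_cpm <- to_cpm(res$spacer_raw)
    res$spacer_presence <- presence(res$spacer_cpm, cpm_cutoff)

    imge_ct_set <- unique(unlist(strsplit(res$imge_records$member_contigs,
                                          ",", fixed = TRUE)))
    host_map <- dataset$contig2mag[!dataset$contig2mag$contig %in%
                                     imge_ct_set, , drop = FALSE]
    host_map$feature <- dataset$mag2rmag$rmag[match(host_map$mag,
                                                    dataset$mag2rmag$mag)]
    lens <- setNames(nchar(dataset$contigs), names(dataset$contigs))
    res$rmag_profile <- feature_presence_and_relabund(
      dataset$depth_mg, dataset$depth_mt,
      host_map[, c("contig", "feature")], lens)
    imge_map <- data.frame(contig = res$imge_records$representative_contig,
                           feature = res$imge_records$imge)
    res$imge_profile <- feature_presence_and_relabund(
      dataset$depth_mg, dataset$depth_mt, imge_map, lens)
  }

  if ("events" %in% stages) {
    res$links <- spacer_imge_links(res$pscc$hits, res$imge_records)
    res$active_assignment <- filter_active_spacers(
      res$assignment, res$spacer_presence, res$rmag_profile$presence,
      data.frame(spacer = res$links$spacer))
    act <- merge(res$active_assignment, res$links,
                 by.x = "spacer_cluster", by.y = "spacer")
    names(act)[names(act) == "spacer_cluster"] <- "spacer"
    res$active_links <- act[order(act$spacer, act$imge, act$rmag), ]
    rownames(res$active_links) <- NULL
    res$events <- classify_events(res$active_links, res$spacer_presence,
                                  res$imge_profile$presence, dataset$dates)
    res$integration_lags <- lag_statistics(res$events, "gain")
    res$deletion_lags <- lag_statistics(res$events, "loss")
    res$timeline <- gain_loss_timeline(res$events, dataset$dates)
  }

  if ("networks" %in% stages) {
    res$networks <- list()
    for (lc in c("plasmid", "phage")) {
      gl <- build_global_network(res$active_links, lc)
      tp <- lapply(date_ids, function(d) {
        time_point_network(gl, res$rmag_profile$presence,
                           res$imge_profile$presence, d)
      })
      names(tp) <- date_ids
      qs <- .stage_seed(seed, match(lc, c("plasmid", "phage")))
      mod <- barber_modularity(gl, seed = qs)
      tp_q <- vapply(tp, function(nt) {
        barber_modularity(nt, n_restarts = 10, seed = qs)$Q
      }, numeric(1))
      res$networks[[lc]] <- list(
        global = gl, time_points = tp,
        Q = mod$Q, modules = mod$modules,
        Q_time_mean = mean(tp_q, na.rm = TRUE),
        nodf = nodf(gl),
        metrics = node_metrics(gl),
        projection = one_mode_projection(gl))
    }
  }

  if ("model" %in% stages) {
    feature_map <- rbind(
      data.frame(feature = dataset$rmag2family$rmag,
                 family = dataset$rmag2family$family, kind = "bacteria"),
      {
        rec <- res$imge_records
        mag <- dataset$contig2mag$mag[match(rec$representative_contig,
                                            dataset$contig2mag$contig)]
        rmag <- dataset$mag2rmag$rmag[match(mag, dataset$mag2rmag$mag)]
        fam <- dataset$rmag2family$family[match(rmag,
                                                dataset$rmag2family$rmag)]
        data.frame(feature = rec$imge, family = fam, kind = rec$label)
      })
    relabund <- rbind(res$rmag_profile$relative_abundance,
                      res$imge_profile$relative_abundance)
    res$groups <- group_by_family(relabund, feature_map)
    # constant (typically all-zero) group series carry no dynamics: they have
    # undefined correlations and cannot act as predictors
    flat <- apply(res$groups$series, 1L, sd) == 0
    if (any(flat)) {
      message(sum(flat), " constant family group(s) excluded: ",
              paste(rownames(res$groups$series)[flat], collapse = ", "))
      res$groups$series <- res$groups$series[!flat, , drop = FALSE]
      res$groups$info <- res$groups$info[
        res$groups$info$group %in% rownames(res$groups$series), ]
    }
    res$correlations <- correlate_groups(res$groups)
    res$group_clusters <- cluster_groups(res$correlations, height = 4)
    if (is.null(response_group)) {
      response_group <- dataset$ground_truth$model$response_group
    }
    bact <- res$groups$info$group[res$groups$info$kind == "bacteria"]
    if (is.null(response_group) || !response_group %in%
        rownames(res$groups$series)) {
      response_group <- bact[which.max(rowMeans(
        res$groups$series[bact, , drop = FALSE]))]
    }
    cand_groups <- res$groups$info$group[
      res$groups$info$kind %in% c("plasmid", "phage")]
    if (length(cand_groups) >= 1L) {
      y <- res$groups$series[response_group, ]
      X <- t(res$groups$series[cand_groups, , drop = FALSE])
      res$model_search <- random_model_search(
        y, X, n_realizations = n_realizations,
        seed = .stage_seed(seed, 11))
      res$enrichment <- enrichment_in_top(res$model_search,
                                          N = min(enrichment_N,
                                                  nrow(res$model_search)))
      enr <- res$enrichment$group[res$enrichment$enriched]
      if (length(enr)) {
        res$model <- global_and_reduced_model(y, X, enr, alpha = alpha)
        if (!res$model$reduced_empty) {
          res$ablation <- lapply(setNames(nm = res$model$significant),
                                 function(g) ablate_predictor(res$model, g))
        }
      }
      res$response_group <- response_group
    }
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) {
    res$manifest <- .write_pipeline_outputs(res, out_dir)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$spacer_clusters)) {
    cat(sprintf("  clusters: %d spacers, %d repeats, %d flanks\n",
                length(x$spacer_clusters), length(x$repeat_clusters),
                length(x$flank_clusters)))
  }
  if (!is.null(x$assignment)) {
    cat(sprintf("  assignment: %d spacer-rMAG rows\n", nrow(x$assignment)))
  }
  if (!is.null(x$pscc)) {
    cat(sprintf("  protospacers: %d hits on %d PSCCs\n",
                nrow(x$pscc$hits), length(x$pscc$contigs)))
  }
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d calls over %d active links\n",
                nrow(x$events), nrow(x$active_links)))
  }
  if (!is.null(x$networks)) {
    for (lc in names(x$networks)) {
      nw <- x$networks[[lc]]
      cat(sprintf("  %s-host network: %d hosts, %d elements, %d edges, Q = %.3f, NODF = %.1f\n",
                  lc, length(nw$global$hosts), length(nw$global$imges),
                  nrow(nw$global$edges), nw$Q, nw$nodf))
    }
  }
  if (!is.null(x$model)) {
    cat(sprintf("  model: reduced adj R2 = %.4f (%s)\n",
                x$model$reduced_adj_r2,
                paste(x$model$significant, collapse = ", ")))
  }
  invisible(x)
}

.write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths <<- c(paths, p)
  }
  if (!is.null(res$spacer_clusters)) {
    put(rbind(cluster_membership(res$spacer_clusters),
              cluster_membership(res$repeat_clusters),
              cluster_membership(res$flank_clusters)),
        "cluster_membership.tsv")
  }
  if (!is.null(res$assignment)) put(res$assignment, "spacer_assignment.tsv")
  if (!is.null(res$hits)) put(res$hits, "protospacer_hits.tsv")
  if (!is.null(res$pscc)) {
    put(data.frame(contig = res$pscc$contigs,
                   n_protospacers = res$pscc$n_protospacers),
        "pscc_table.tsv")
  }
  if (!is.null(res$imge_records)) put(res$imge_records, "imge_records.tsv")
  if (!is.null(res$events)) {
    ev <- res$events
    ev$spacer_date <- as.character(ev$spacer_date)
    ev$imge_date <- as.character(ev$imge_date)
    put(ev, "events.tsv")
    put(res$timeline$timeline, "gain_loss_timeline.tsv")
  }
  if (!is.null(res$networks)) {
    for (lc in names(res$networks)) {
      put(res$networks[[lc]]$global$edges,
          sprintf("network_%s_edges.tsv", lc))
      put(res$networks[[lc]]$metrics, sprintf("network_%s_metrics.tsv", lc))
    }
  }
  if (!is.null(res$model_search)) {
    put(head(as.data.frame(res$model_search), 100L), "model_top100.tsv")
    put(res$enrichment, "model_enrichment.tsv")
  }
  manifest <- list(
    files = as.list(setNames(unname(tools::md5sum(paths)), basename(paths))),
    config = res$config)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
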