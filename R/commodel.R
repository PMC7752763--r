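#' Group features into family-level abundance series
#'
#' Sums relative-abundance series of all features (rMAGs, plasmids or phages)
#' sharing a taxonomic family; plasmids and phages are grouped separately
#' from their host bacteria. Unmapped features are excluded with a message.
#'
#' @param relabund feature x sample relative-abundance matrix (rows named by
#'   feature id).
#' @param feature_map data.frame with columns `feature`, `family`, `kind`
#'   (`bacteria`/`plasmid`/`phage`).
#' @return object of class `family_groups`: list with `series` (groups x
#'   samples matrix, rownames `family|kind`) and `info` (data.frame `group`,
#'   `family`, `kind`, `n_members`).
#' @export
group_by_family <- function(relabund, feature_map) {
  stopifnot(all(c("feature", "family", "kind") %in% names(feature_map)))
  fm <- feature_map[!is.na(feature_map$family) &
                      feature_map$feature %in% rownames(relabund), ]
  unmapped <- setdiff(rownames(relabund), fm$feature)
  if (length(unmapped)) {
    message(length(unmapped), " feature(s) without family mapping excluded")
  }
  fm$group <- paste(fm$family, fm$kind, sep = "|")
  groups <- sort(unique(fm$group))
  series <- matrix(0, length(groups), ncol(relabund),
                   dimnames = list(groups, colnames(relabund)))
  for (g in groups) {
    feats <- fm$feature[fm$group == g]
    series[g, ] <- colSums(relabund[feats, , drop = FALSE])
  }
  info <- unique(fm[, c("group", "family", "kind")])
  info$n_members <- as.integer(table(fm$group)[info$group])
  info <- info[order(info$group), ]
  rownames(info) <- NULL
  structure(list(series = series, info = info), class = "family_groups")
}

#' @export
print.family_groups <- function(x, ...) {
  cat(sprintf("<family_groups> %d groups x %d samples (%s)\n",
              nrow(x$series), ncol(x$series),
              paste(sprintf("%d %s", table(x$info$kind),
                            names(table(x$info$kind))), collapse = ", ")))
  invisible(x)
}

#' Pairwise correlations between family-level groups
#'
#' Two-sided Pearson tests between all group pairs over an interval of
#' samples, with multiple-testing adjustment; a pair is flagged strong when
#' `|r| >= r_strong` and the adjusted p-value is at most `p_strong`.
#' Constant series yield `NA` correlations for their pairs.
#'
#' @param groups `family_groups` object or a groups x samples matrix.
#' @param interval optional integer vector of sample columns (default all).
#' @param adjust p-value adjustment method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @param r_strong,p_strong strong-correlation thresholds (defaults 0.7 and
#'   0.001).
#' @return data.frame with columns `group1`, `group2`, `r`, `p_raw`,
#'   `p_adjusted`, `strong`.
#' @export
correlate_groups <- function(groups, interval = NULL, adjust = "BH",
                             r_strong = 0.7, p_strong = 0.001) {
  m <- if (inherits(groups, "family_groups")) groups$series else groups
  if (!is.null(interval)) m <- m[, interval, drop = FALSE]
  if (ncol(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  gn <- rownames(m)
  pairs <- combn(length(gn), 2L)
  n <- ncol(pairs)
  r <- p <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    x <- m[pairs[1L, k], ]
    y <- m[pairs[2L, k], ]
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    r[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  p_adj <- p.adjust(p, method = adjust)
  data.frame(group1 = gn[pairs[1L, ]], group2 = gn[pairs[2L, ]],
             r = r, p_raw = p, p_adjusted = p_adj,
             strong = !is.na(r) & abs(r) >= r_strong &
               !is.na(p_adj) & p_adj <= p_strong)
}

#' Hierarchical clustering of groups from their correlation profiles
#'
#' Groups are clustered on the Euclidean distances between the rows of the
#' pairwise correlation matrix; the tree is cut at a fixed height.
#'
#' @param correlations data.frame from [correlate_groups()].
#' @param height tree cut height (default 4).
#' @param linkage agglomeration method (default `"complete"`).
#' @return named integer vector of cluster labels.
#' @export
cluster_groups <- function(correlations, height = 4, linkage = "complete") {
  gn <- sort(unique(c(correlations$group1, correlations$group2)))
  M <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  diag(M) <- 1
  M[cbind(correlations$group1, correlations$group2)] <- correlations$r
  M[cbind(correlations$group2, correlations$group1)] <- correlations$r
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
    stop("missing correlations; refusing to impute: ",
         paste(head(paste(gn[bad[, 1L]], gn[bad[, 2L]], sep = " ~ "), 5L),
               collapse = ", "), call. = FALSE)
  }
  hc <- hclust(dist(M, method = "euclidean"), method = linkage)
  cutree(hc, h = height)
}

# adjusted R^2 from an OLS fit of y on X (with intercept already in X)
.adj_r2 <- function(y, fit, p) {
  n <- length(y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

#' Randomised linear-model search over predictor subsets
#'
#' Draws random predictor subsets (size sampled uniformly on
#' `1..max_terms`, then a uniform subset of that size), fits ordinary least
#' squares of the response on each subset and ranks realizations by adjusted
#' R-squared. Rank-deficient designs are skipped and counted.
#'
#' @param response numeric response series (length n samples).
#' @param candidates samples x groups numeric matrix of candidate predictor
#'   series.
#' @param n_realizations number of random models (default 100000).
#' @param max_terms maximum predictors per model (default 15).
#' @param seed RNG seed.
#' @return object of class `model_search`: data.frame with columns
#'   `predictors` (comma-separated), `n_terms`, `r2`, `adj_r2`, sorted by
#'   `adj_r2` descending, with attributes `n_skipped`, `seed`,
#'   `n_realizations` and `candidate_names`.
#' @export
random_model_search <- function(response, candidates,
                                n_realizations = 100000, max_terms = 15,
                                seed = 1) {
  stopifnot(is.matrix(candidates), length(response) == nrow(candidates))
  n <- length(response)
  p_all <- ncol(candidates)
  max_terms <- min(max_terms, p_all)
  if (n <= max_terms + 1L) {
    stop("need more samples than max_terms + 1", call. = FALSE)
  }
  cn <- colnames(candidates)
  if (is.null(cn)) cn <- paste0("g", seq_len(p_all))
  .with_seed(seed, {
    sizes <- sample.int(max_terms, n_realizations, replace = TRUE)
    preds <- character(n_realizations)
    nt <- integer(n_realizations)
    r2 <- adj <- rep(NA_real_, n_realizations)
    skipped <- 0L
    ones <- rep(1, n)
    for (i in seq_len(n_realizations)) {
      idx <- sort(sample.int(p_all, sizes[i]))
      X <- cbind(ones, candidates[, idx, drop = FALSE])
      fit <- .lm.fit(X, response)
      if (fit$rank < ncol(X)) {
        skipped <- skipped + 1L
        next
      }
      st <- .adj_r2(response, fit, sizes[i])
      preds[i] <- paste(cn[idx], collapse = ",")
      nt[i] <- sizes[i]
      r2[i] <- st$r2
      adj[i] <- st$adj_r2
    }
    ok <- !is.na(adj)
    out <- data.frame(predictors = preds[ok], n_terms = nt[ok],
                      r2 = r2[ok], adj_r2 = adj[ok])
    out <- out[order(-out$adj_r2), ]
    rownames(out) <- NULL
    attr(out, "n_skipped") <- skipped
    attr(out, "seed") <- seed
    attr(out, "n_realizations") <- n_realizations
    attr(out, "candidate_names") <- cn
    class(out) <- c("model_search", "data.frame")
    out
  })
}

#' Enrichment of predictor groups among the best-ranked models
#'
#' Compares each group's frequency in the top `N` models with its overall
#' sampling frequency using a one-sided hypergeometric test.
#'
#' @param search a `model_search` object.
#' @param N size of the top set (25, 50 or 100 in practice; default 50).
#' @param alpha enrichment threshold on the adjusted p-value (default 0.05).
#' @param adjust adjustment method (default `"BH"`).
#' @return data.frame with columns `group`, `n_top`, `n_total`, `expected`,
#'   `p`, `p_adjusted`, `enriched`.
#' @export
enrichment_in_top <- function(search, N = 50, alpha = 0.05, adjust = "BH") {
  stopifnot(inherits(search, "model_search"), nrow(search) >= N)
  cn <- attr(search, "candidate_names")
  all_preds <- strsplit(search$predictors, ",", fixed = TRUE)
  top_preds <- all_preds[seq_len(N)]
  R <- nrow(search)
  n_total <- table(factor(unlist(all_preds), levels = cn))
  n_top <- table(factor(unlist(top_preds), levels = cn))
  p <- vapply(cn, function(g) {
    m <- n_total[[g]]
    if (m == 0L) return(1)
    phyper(n_top[[g]] - 1L, m, R - m, N, lower.tail = FALSE)
  }, numeric(1))
  p_adj <- p.adjust(p, method = adjust)
  data.frame(group = cn, n_top = as.integer(n_top[cn]),
             n_total = as.integer(n_total[cn]),
             expected = as.numeric(n_total[cn]) * N / R,
             p = unname(p), p_adjusted = unname(p_adj),
             enriched = unname(p_adj <= alpha & as.integer(n_top[cn]) > 0L))
}

#' Global and reduced linear models from the enriched groups
#'
#' The global model regresses the response on all enriched groups; the
#' reduced model keeps only the globally significant coefficients
#' (p <= `alpha`, intercept excluded).
#'
#' @param response numeric response series.
#' @param candidates samples x groups matrix.
#' @param enriched character vector of enriched group names.
#' @param alpha coefficient significance level (default 0.05).
#' @return object of class `imge_model`: list with `global` (`lm`),
#'   `reduced` (`lm` or `NULL`), `global_adj_r2`, `reduced_adj_r2`,
#'   `significant` (character), `reduced_empty` (logical).
#' @export
global_and_reduced_model <- function(response, candidates, enriched,
                                     alpha = 0.05) {
  stopifnot(length(enriched) > 0, all(enriched %in% colnames(candidates)))
  df <- as.data.frame(candidates[, enriched, drop = FALSE])
  safe <- make.names(colnames(df))
  name_map <- setNames(colnames(df), safe)
  colnames(df) <- safe
  df$.response <- response
  global <- lm(.response ~ ., data = df)
  cf <- summary(global)$coefficients
  sig_safe <- setdiff(rownames(cf)[cf[, 4L] <= alpha &
                                     !is.na(cf[, 4L])], "(Intercept)")
  sig_safe <- sub("^`|`$", "", sig_safe)
  significant <- unname(name_map[sig_safe])
  reduced <- NULL
  reduced_adj <- NA_real_
  if (length(significant)) {
    df2 <- df[, c(sig_safe, ".response"), drop = FALSE]
    reduced <- lm(.response ~ ., data = df2)
    reduced_adj <- summary(reduced)$adj.r.squared
  }
  structure(list(global = global, reduced = reduced,
                 global_adj_r2 = summary(global)$adj.r.squared,
                 reduced_adj_r2 = reduced_adj,
                 significant = significant,
                 name_map = name_map,
                 reduced_empty = length(significant) == 0L),
            class = "imge_model")
}

#' @export
print.imge_model <- function(x, ...) {
  cat(sprintf("<imge_model> global adj R2 = %.4f (%d terms); ",
              x$global_adj_r2, length(x$name_map)))
  if (x$reduced_empty) {
    cat("reduced model empty (no significant coefficients)\n")
  } else {
    cat(sprintf("reduced adj R2 = %.4f (%s)\n", x$reduced_adj_r2,
                paste(x$significant, collapse = ", ")))
  }
  invisible(x)
}

#' Adjusted R-squared drop from removing one predictor
#'
#' Refits the reduced model without the given group and reports the drop in
#' adjusted R-squared (positive = removing the group hurts the model).
#'
#' @param model an `imge_model` with a non-empty reduced model.
#' @param group group name to remove (must be in the reduced model).
#' @return list with `delta_adj_r2`, `full_adj_r2`, `ablated_adj_r2`.
#' @export
ablate_predictor <- function(model, group) {
  stopifnot(inherits(model, "imge_model"), !model$reduced_empty)
  if (!group %in% model$significant) {
    stop("group '", group, "' is not in the reduced model", call. = FALSE)
  }
  safe <- names(model$name_map)[model$name_map == group]
  dat <- model$reduced$model
  keep <- setdiff(colnames(dat), c(safe, ".response"))
  if (length(keep)) {
    fit <- lm(.response ~ ., data = dat[, c(keep, ".response"),
                                        drop = FALSE])
    abl <- summary(fit)$adj.r.squared
  } else {
    abl <- 0  # intercept-only model explains nothing
  }
  list(delta_adj_r2 = model$reduced_adj_r2 - abl,
       full_adj_r2 = model$reduced_adj_r2,
       ablated_adj_r2 = abl)
}
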