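#' Filter spacers active in host-element interactions
#'
#' A spacer-to-rMAG assignment is retained only when (1) the spacer is
#' encoded by the rMAG (it is in the assignment table), (2) spacer and rMAG
#' are co-present in at least one time point, and (3) the spacer targets at
#' least one invasive element. The co-occurrence condition is a biconditional:
#' assignments failing it are removed outright.
#'
#' @param assignment data.frame with columns `spacer_cluster`, `rmag`.
#' @param spacer_presence logical matrix, spacer clusters x samples.
#' @param rmag_presence logical matrix, rMAGs x samples (same column order).
#' @param links data.frame with a `spacer` column listing spacers with at
#'   least one element target (e.g. from [spacer_imge_links()]).
#' @return the filtered assignment table.
#' @export
filter_active_spacers <- function(assignment, spacer_presence, rmag_presence,
                                  links) {
  stopifnot(identical(colnames(spacer_presence), colnames(rmag_presence)))
  keep <- vapply(seq_len(nrow(assignment)), function(i) {
    sp <- assignment$spacer_cluster[i]
    rm <- assignment$rmag[i]
    if (!sp %in% rownames(spacer_presence)) return(FALSE)
    if (!rm %in% rownames(rmag_presence)) return(FALSE)
    cooccur <- any(spacer_presence[sp, ] & rmag_presence[rm, ])
    cooccur && sp %in% links$spacer
  }, logical(1))
  out <- assignment[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link spacers to representative invasive elements via protospacer hits
#'
#' @param hits protospacer hits retained on PSCCs (e.g. `pscc$hits`).
#' @param imge_records iMGE record table from [cluster_imges()].
#' @return data.frame with columns `spacer`, `imge`, `label` (unique pairs);
#'   hits on contigs that belong to no iMGE cluster are dropped.
#' @export
spacer_imge_links <- function(hits, imge_records) {
  members <- strsplit(imge_records$member_contigs, ",", fixed = TRUE)
  map <- data.frame(
    contig = unlist(members),
    imge = rep(imge_records$imge, lengths(members)),
    label = rep(imge_records$label, lengths(members)))
  m <- merge(hits[, c("spacer", "contig")], map, by = "contig")
  out <- unique(m[, c("spacer", "imge", "label")])
  out <- out[order(out$spacer, out$imge), ]
  rownames(out) <- NULL
  out
}

.event_first_categories <- c("gain", "probable_gain",
                             "probable_secondary_encounter")
.event_last_categories <- c("loss", "probable_loss",
                            "spacer_loss_before_imge_loss")

#' Classify spacer gain/loss events from presence time series
#'
#' For every (spacer, element) pair, the first-occurrence comparison yields
#' one of: `gain` (spacer first detected after its targeted element),
#' `probable_gain` (same time point) or `probable_secondary_encounter`
#' (spacer first); the last-occurrence comparison yields `loss` (spacer last
#' detected after the element), `probable_loss` (same time point) or
#' `spacer_loss_before_imge_loss`. Both calls are emitted per pair. Pairs in
#' which the spacer or the element is never present are skipped with a
#' message. Lags are reported in fractional weeks (days / 7) and are positive
#' for `gain` and `loss`, zero for the probable categories and negative
#' otherwise.
#'
#' @param links data.frame with columns `spacer`, `imge` and optionally
#'   `label` and `rmag` (carried through).
#' @param spacer_presence,imge_presence logical matrices with sample columns
#'   in date order.
#' @param dates `Date` vector, one per sample column.
#' @return data.frame of events: link columns plus `comparison`
#'   (`first`/`last`), `category`, `spacer_date`, `imge_date`, `lag_weeks`.
#' @export
classify_events <- function(links, spacer_presence, imge_presence, dates) {
  stopifnot(ncol(spacer_presence) == length(dates),
            ncol(imge_presence) == length(dates))
  dates <- as.Date(dates)
  out <- list()
  for (i in seq_len(nrow(links))) {
    sp <- links$spacer[i]
    im <- links$imge[i]
    s_ser <- if (sp %in% rownames(spacer_presence)) spacer_presence[sp, ]
             else rep(FALSE, length(dates))
    i_ser <- if (im %in% rownames(imge_presence)) imge_presence[im, ]
             else rep(FALSE, length(dates))
    if (!any(s_ser) || !any(i_ser)) {
      message("skipping pair ", sp, " / ", im,
              ": spacer or element never present")
      next
    }
    fs <- dates[which(s_ser)[1L]]
    fi <- dates[which(i_ser)[1L]]
    ls <- dates[max(which(s_ser))]
    li <- dates[max(which(i_ser))]
    first_cat <- if (fs > fi) "gain" else if (fs == fi) "probable_gain"
                 else "probable_secondary_encounter"
    last_cat <- if (ls > li) "loss" else if (ls == li) "probable_loss"
                else "spacer_loss_before_imge_loss"
    base <- links[i, , drop = FALSE]
    rownames(base) <- NULL
    f <- base; f$comparison <- "first"; f$category <- first_cat
    f$spacer_date <- fs; f$imge_date <- fi
    f$lag_weeks <- as.numeric(fs - fi) / 7
    l <- base; l$comparison <- "last"; l$category <- last_cat
    l$spacer_date <- ls; l$imge_date <- li
    l$lag_weeks <- as.numeric(ls - li) / 7
    out[[length(out) + 1L]] <- rbind(f, l)
  }
  if (length(out) == 0L) {
    base <- links[0, , drop = FALSE]
    base$comparison <- character(0); base$category <- character(0)
    base$spacer_date <- as.Date(character(0))
    base$imge_date <- as.Date(character(0))
    base$lag_weeks <- numeric(0)
    return(base)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Integration / deletion lag statistics in weeks
#'
#' Summarises lag times over the selected event categories, overall and per
#' element label (plasmid vs phage). Integration lags come from `gain`
#' events (spacer first detected after its element), deletion lags from
#' `loss` events. Same-date (probable) events contribute lag 0 and are
#' excluded by default. The standard deviation uses the n-1 denominator and
#' is `NA` for a single event; empty selections report `NA`, not zero.
#'
#' @param events event table from [classify_events()] (needs a `label`
#'   column for the per-label breakdown).
#' @param categories event categories to summarise (default `"gain"`).
#' @param include_probable also include the matching same-date category.
#' @return data.frame with rows `overall`, `plasmid`, `phage`: columns
#'   `group`, `n`, `mean_weeks`, `median_weeks`, `sd_weeks`.
#' @export
lag_statistics <- function(events, categories = "gain",
                           include_probable = FALSE) {
  if (include_probable) {
    if ("gain" %in% categories) categories <- c(categories, "probable_gain")
    if ("loss" %in% categories) categories <- c(categories, "probable_loss")
  }
  sel <- events[events$category %in% categories, , drop = FALSE]
  one <- function(x) {
    n <- length(x)
    data.frame(n = n,
               mean_weeks = if (n) mean(x) else NA_real_,
               median_weeks = if (n) median(x) else NA_real_,
               sd_weeks = if (n >= 2L) sd(x) else NA_real_)
  }
  groups <- list(overall = sel$lag_weeks)
  if ("label" %in% names(sel)) {
    groups$plasmid <- sel$lag_weeks[sel$label == "plasmid"]
    groups$phage <- sel$lag_weeks[sel$label == "phage"]
  }
  out <- do.call(rbind, lapply(groups, one))
  out <- cbind(group = names(groups), out)
  rownames(out) <- NULL
  out
}

#' Gain/loss event timeline and crossover date
#'
#' Counts gain events by spacer first-detection date and loss events by
#' spacer last-detection date, and reports the crossover: the date at which
#' the running balance of gains minus losses peaks, i.e. after which losses
#' dominate.
#'
#' @param events event table from [classify_events()].
#' @param dates `Date` vector of the sample axis.
#' @return list with `timeline` (data.frame `date`, `gains`, `losses`,
#'   `balance`) and `crossover` (`Date`, `NA` if gains never dominate or the
#'   event list is empty).
#' @export
gain_loss_timeline <- function(events, dates) {
  dates <- sort(as.Date(dates))
  g <- events[events$category == "gain", , drop = FALSE]
  l <- events[events$category == "loss", , drop = FALSE]
  timeline <- data.frame(
    date = dates,
    gains = as.integer(table(factor(as.character(g$spacer_date),
                                    levels = as.character(dates)))),
    losses = as.integer(table(factor(as.character(l$spacer_date),
                                     levels = as.character(dates)))))
  timeline$balance <- cumsum(timeline$gains - timeline$losses)
  crossover <- if (nrow(l) == 0L || all(timeline$balance <= 0)) {
    as.Date(NA)
  } else {
    dates[which.max(timeline$balance)]
  }
  list(timeline = timeline, crossover = crossover)
}
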