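#' Configuration for the synthetic community generator
#'
#' Defaults emulate the layout of a time-resolved wastewater-sludge
#' metagenomics study: 51 time points sampled on average every 8 days,
#' a ~16:1 plasmid:phage composition, hosts carrying repeat-spacer CRISPR
#' arrays with flanking sequences, invasive elements embedding protospacers,
#' a mid-series community shift, and planted spacer gain/loss events with
#' known lags.
#'
#' @param n_timepoints number of samples (default 51).
#' @param mean_interval_days,interval_sd_days sampling interval distribution;
#'   gaps are drawn as `max(1, round(Normal(mean, sd)))` days (defaults 8
#'   and 4).
#' @param start_date first sampling date (default `"2011-03-21"`).
#' @param n_hosts number of host rMAGs (default 12; 0 allowed for degenerate
#'   datasets).
#' @param n_extra_mags MAGs beyond the hosts that dereplicate into existing
#'   rMAGs, each carrying its own CRISPR locus (default 2).
#' @param n_families number of bacterial families (default 6).
#' @param n_imges number of invasive elements (default 170).
#' @param plasmid_phage_ratio plasmid:phage ratio (default 16).
#' @param spacer_len spacer length in nt (default 30).
#' @param repeat_len_range repeat length range in nt (default `c(28, 37)`).
#' @param flank_len flanking-sequence length in nt (default 150).
#' @param short_flank_frac fraction of loci given a short (80 nt) flank to
#'   exercise the short-flank matching branch (default 0.25).
#' @param n_spacers_per_host spacers per CRISPR locus (default 8).
#' @param imge_len invasive-element contig length in nt (default 600).
#' @param host_pad_len random padding around the CRISPR array (default 150).
#' @param host_extra_contig_len length of the extra non-CRISPR contig per MAG
#'   (default 800).
#' @param multi_protospacer_frac fraction of targeted elements carrying at
#'   least two protospacers (default 0.56).
#' @param second_target_frac fraction of spacers targeting a second element
#'   (default 0.10).
#' @param spacer_variant_frac fraction of spacers with a 1-substitution
#'   redundant variant detection (default 0.3).
#' @param n_twin_plasmids untargeted plasmids duplicated as slightly mutated
#'   twin contigs, exercising element clustering (default 6).
#' @param n_mt_only elements present only in metatranscriptomic data
#'   (default 4).
#' @param n_background non-element, non-host contigs (default 5).
#' @param n_slack always-present plasmids whose depths keep the total element
#'   depth constant per sample (default 8).
#' @param predictor_error_rate probability of flipping each predictor flag
#'   (default 0).
#' @param response_noise_frac Gaussian noise s.d. on the response family
#'   series, as a fraction of the deterministic response s.d. (default 0.05).
#' @param shift_window inclusive 1-based index range of the community shift
#'   (default: a 9-sample window starting at the series midpoint, i.e.
#'   `c(26, 34)` for 51 time points).
#' @param planted_event_table optional data.frame with columns `spacer_rank`
#'   (1-based spacer index), `category_first`, `category_last` overriding the
#'   randomly drawn event plan for those spacers.
#' @param seed RNG seed (all randomness flows from it).
#' @return validated configuration of class `sim_config`.
#' @export
simulation_config <- function(n_timepoints = 51, mean_interval_days = 8,
                              interval_sd_days = 4,
                              start_date = "2011-03-21",
                              n_hosts = 12, n_extra_mags = 2,
                              n_families = 6, n_imges = 170,
                              plasmid_phage_ratio = 16, spacer_len = 30,
                              repeat_len_range = c(28, 37), flank_len = 150,
                              short_flank_frac = 0.25,
                              n_spacers_per_host = 8, imge_len = 600,
                              host_pad_len = 150,
                              host_extra_contig_len = 800,
                              multi_protospacer_frac = 0.56,
                              second_target_frac = 0.10,
                              spacer_variant_frac = 0.3,
                              n_twin_plasmids = 6, n_mt_only = 4,
                              n_background = 5, n_slack = 8,
                              predictor_error_rate = 0,
                              response_noise_frac = 0.05,
                              shift_window = NULL,
                              planted_event_table = NULL, seed = 1) {
  if (is.null(shift_window)) {
    shift_window <- c(max(1, round(n_timepoints * 0.5)),
                      min(n_timepoints, round(n_timepoints * 0.5) + 8))
  }
  cfg <- as.list(environment())
  fail <- function(field, why) {
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  }
  if (n_timepoints < 1) fail("n_timepoints", "must be >= 1")
  if (mean_interval_days < 1) fail("mean_interval_days", "must be >= 1")
  if (n_hosts < 0) fail("n_hosts", "must be >= 0")
  if (n_families < 1) fail("n_families", "must be >= 1")
  if (n_imges < 0) fail("n_imges", "must be >= 0")
  if (plasmid_phage_ratio <= 0) fail("plasmid_phage_ratio", "must be > 0")
  if (spacer_len < 10) fail("spacer_len", "must be >= 10")
  if (n_spacers_per_host < 1) fail("n_spacers_per_host", "must be >= 1")
  if (predictor_error_rate < 0 || predictor_error_rate > 1) {
    fail("predictor_error_rate", "must be in [0, 1]")
  }
  if (length(shift_window) != 2 || shift_window[1] < 1 ||
      shift_window[2] > n_timepoints || shift_window[1] > shift_window[2]) {
    fail("shift_window", "must be an index range within the time series")
  }
  cfg$start_date <- as.Date(start_date)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d time points, %d hosts / %d families, ",
                     "%d elements (%g:1 plasmid:phage), seed %d\n"),
              x$n_timepoints, x$n_hosts, x$n_families, x$n_imges,
              x$plasmid_phage_ratio, x$seed))
  invisible(x)
}

# rejection-sample `n` random sequences of lengths `lens` with minimum edit
# distance to each other (and their reverse complements) of at least
# `min_frac` of the shorter length
.guarded_random_seqs <- function(n, lens, min_frac = 0.2,
                                 existing = character(0)) {
  lens <- rep_len(lens, n)
  out <- character(0)
  pool <- existing
  for (i in seq_len(n)) {
    repeat {
      s <- .random_dna(1L, lens[i])
      if (length(pool) == 0L) break
      dmin <- min(utils::adist(s, c(pool, rev_comp(pool))))
      if (dmin >= ceiling(min_frac * min(nchar(pool), lens[i]))) break
    }
    out <- c(out, s)
    pool <- c(pool, s)
  }
  out
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Generates hosts carrying CRISPR arrays, invasive elements embedding the
#' matching protospacers, dated depth-of-coverage tables with a mid-series
#' community shift, predictor flags, CRISPR element tables and a ground-truth
#' record of every planted spacer-element link, event category and model
#' coefficient. Deterministic under `config$seed`.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return object of class `synthetic_community`: list with `contigs`
#'   (named character), `elements`, `contig2mag`, `mag2rmag`, `rmag2family`,
#'   `depth_mg`, `depth_mt`, `flags`, `dates`, `ground_truth`, `config`.
#' @export
simulate_community <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_community_impl(config))
}

.simulate_community_impl <- function(cfg) {
  n <- cfg$n_timepoints
  gaps <- pmax(1, round(rnorm(max(0L, n - 1L), cfg$mean_interval_days,
                              cfg$interval_sd_days)))
  dates <- cfg$start_date + c(0, cumsum(gaps))
  date_ids <- .iso_date(dates)

  n_loci <- cfg$n_hosts + if (cfg$n_hosts > 0) cfg$n_extra_mags else 0L
  n_phage <- if (cfg$n_imges > 0) max(1L, round(cfg$n_imges /
                                     (cfg$plasmid_phage_ratio + 1))) else 0L
  n_plasmid <- cfg$n_imges - n_phage

  ## ---- hosts, MAGs, families --------------------------------------------
  hosts <- if (cfg$n_hosts > 0) sprintf("rmag_%02d", seq_len(cfg$n_hosts))
           else character(0)
  host_family <- if (cfg$n_hosts > 0) {
    sprintf("family_%02d", ((seq_len(cfg$n_hosts) - 1L) %% cfg$n_families) + 1L)
  } else character(0)
  mags <- if (n_loci > 0) sprintf("mag_%02d", seq_len(n_loci)) else character(0)
  # extra MAGs dereplicate into the first rMAGs
  mag_rmag <- if (n_loci > 0) {
    c(hosts, hosts[seq_len(n_loci - cfg$n_hosts)])
  } else character(0)
  mag2rmag <- data.frame(mag = mags, rmag = mag_rmag)
  rmag2family <- data.frame(rmag = hosts, family = host_family)

  ## ---- CRISPR loci ------------------------------------------------------
  S <- n_loci * cfg$n_spacers_per_host
  spacer_seqs <- .guarded_random_seqs(S, cfg$spacer_len)
  repeat_lens <- if (n_loci > 0) {
    sample(cfg$repeat_len_range[1]:cfg$repeat_len_range[2], n_loci,
           replace = TRUE)
  } else integer(0)
  repeat_seqs <- .guarded_random_seqs(n_loci, repeat_lens)
  flank_lens <- rep(cfg$flank_len, n_loci)
  if (n_loci > 0) {
    n_short <- round(cfg$short_flank_frac * n_loci)
    if (n_short > 0) flank_lens[seq_len(n_short)] <- 80L
  }
  flank_seqs <- .guarded_random_seqs(n_loci, flank_lens)

  spacer_ids <- character(0)
  spacer_locus <- integer(0)
  contigs <- list()
  contig2mag <- list()
  for (l in seq_len(n_loci)) {
    idx <- ((l - 1L) * cfg$n_spacers_per_host + 1L):(l * cfg$n_spacers_per_host)
    ids <- sprintf("sp_%02d_%02d", l, seq_along(idx))
    spacer_ids <- c(spacer_ids, ids)
    spacer_locus <- c(spacer_locus, rep(l, length(idx)))
    array_seq <- paste0(
      flank_seqs[l], repeat_seqs[l],
      paste0(spacer_seqs[idx], repeat_seqs[l], collapse = ""))
    ct <- sprintf("host_contig_%02d", l)
    contigs[[ct]] <- paste0(.random_dna(1L, cfg$host_pad_len), array_seq,
                            .random_dna(1L, cfg$host_pad_len))
    extra <- sprintf("host_extra_%02d", l)
    contigs[[extra]] <- .random_dna(1L, cfg$host_extra_contig_len)
    contig2mag[[length(contig2mag) + 1L]] <-
      data.frame(contig = c(ct, extra), mag = mags[l])
  }
  host_contigs <- if (n_loci > 0) sprintf("host_contig_%02d", seq_len(n_loci))
                  else character(0)

  ## ---- invasive elements and protospacer placements ---------------------
  imge_ids <- if (cfg$n_imges > 0) sprintf("imge_%03d", seq_len(cfg$n_imges))
              else character(0)
  imge_label <- c(rep("plasmid", n_plasmid), rep("phage", n_phage))
  imge_contig <- if (cfg$n_imges > 0) paste0(imge_ids, "_ct") else character(0)

  placements <- data.frame(spacer_id = character(0), imge_id = character(0),
                           strand = character(0), start = integer(0))
  targeted <- character(0)
  if (S > 0 && cfg$n_imges > 0) {
    extra_pl <- round(cfg$second_target_frac * S)
    P <- S + extra_pl
    T_n <- max(1L, min(cfg$n_imges, round(P / 1.67)))
    n_t_phage <- min(n_phage, max(if (n_phage > 0) 2L else 0L, round(T_n / 8)))
    n_t_plasmid <- min(n_plasmid, T_n - n_t_phage)
    T_n <- n_t_phage + n_t_plasmid
    targeted <- c(sample(imge_ids[imge_label == "plasmid"], n_t_plasmid),
                  sample(imge_ids[imge_label == "phage"], n_t_phage))
    counts <- rep(1L, T_n)
    n_multi <- min(T_n, round(cfg$multi_protospacer_frac * T_n))
    extra_slots <- P - T_n
    if (extra_slots < n_multi) n_multi <- extra_slots
    if (n_multi > 0) {
      multi_idx <- sample(seq_len(T_n), n_multi)
      counts[multi_idx] <- 2L
      rem <- extra_slots - n_multi
      while (rem > 0) {
        counts[sample(multi_idx, 1L)] <- counts[sample(multi_idx, 1L)] + 1L
        rem <- rem - 1L
      }
    }
    slots <- sample(rep(targeted, counts))
    sp_order <- sample(spacer_ids)
    slot_spacer <- character(length(slots))
    slot_spacer[seq_len(min(S, length(slots)))] <-
      sp_order[seq_len(min(S, length(slots)))]
    if (length(slots) > S) {
      for (i in (S + 1L):length(slots)) {
        already <- slot_spacer[slots == slots[i] & nzchar(slot_spacer)]
        pool <- setdiff(spacer_ids, already)
        slot_spacer[i] <- sample(pool, 1L)
      }
    }
    # drop duplicate (spacer, imge) pairs that the shuffle may create
    keep <- !duplicated(paste(slot_spacer, slots))
    slots <- slots[keep]; slot_spacer <- slot_spacer[keep]
    # positions: non-overlapping slots on each element contig
    step <- cfg$spacer_len + 12L
    placements <- do.call(rbind, lapply(unique(slots), function(im) {
      here <- which(slots == im)
      max_slots <- (cfg$imge_len - 20L) %/% step
      pos_slots <- sample(seq_len(max_slots), length(here))
      data.frame(spacer_id = slot_spacer[here], imge_id = im,
                 strand = sample(c("+", "-"), length(here), replace = TRUE),
                 start = 10L + (pos_slots - 1L) * step)
    }))
  }

  # element contig sequences with embedded protospacers
  if (cfg$n_imges > 0) {
    for (j in seq_len(cfg$n_imges)) {
      seqj <- .random_dna(1L, cfg$imge_len)
      pl <- placements[placements$imge_id == imge_ids[j], , drop = FALSE]
      if (nrow(pl)) for (k in seq_len(nrow(pl))) {
        sp_seq <- spacer_seqs[match(pl$spacer_id[k], spacer_ids)]
        ins <- if (pl$strand[k] == "+") sp_seq else rev_comp(sp_seq)
        substr(seqj, pl$start[k] + 1L,
               pl$start[k] + nchar(ins)) <- ins
      }
      contigs[[imge_contig[j]]] <- seqj
    }
  }

  ## ---- twins of untargeted plasmids --------------------------------------
  untargeted_plasmids <- setdiff(imge_ids[imge_label == "plasmid"], targeted)
  n_twin <- min(cfg$n_twin_plasmids, length(untargeted_plasmids))
  twin_of <- if (n_twin > 0) sample(untargeted_plasmids, n_twin)
             else character(0)
  twin_contigs <- character(0)
  for (im in twin_of) {
    orig <- contigs[[paste0(im, "_ct")]]
    tw <- substr(orig, 1L, nchar(orig) - 10L)
    tw <- .mutate_subs(tw, max(1L, round(0.02 * nchar(tw))))
    tc <- paste0(im, "_twin")
    contigs[[tc]] <- tw
    twin_contigs <- c(twin_contigs, tc)
  }

  ## ---- background contigs ------------------------------------------------
  bg_contigs <- if (cfg$n_background > 0) {
    sprintf("bg_contig_%02d", seq_len(cfg$n_background))
  } else character(0)
  for (bc in bg_contigs) contigs[[bc]] <- .random_dna(1L, 500L)

  ## ---- event plan: presence windows --------------------------------------
  sp_win <- matrix(NA_integer_, S, 2L,
                   dimnames = list(spacer_ids, c("first", "last")))
  im_win <- matrix(NA_integer_, cfg$n_imges, 2L,
                   dimnames = list(imge_ids, c("first", "last")))
  if (nrow(placements) > 0 && n >= 12L) {
    primary <- placements[!duplicated(placements$spacer_id), ]
    cat_first <- sample(c("gain", "probable_gain",
                          "probable_secondary_encounter"),
                        nrow(primary), replace = TRUE,
                        prob = c(0.6, 0.2, 0.2))
    cat_last <- sample(c("loss", "probable_loss",
                         "spacer_loss_before_imge_loss"),
                       nrow(primary), replace = TRUE,
                       prob = c(0.5, 0.2, 0.3))
    if (!is.null(cfg$planted_event_table)) {
      pet <- cfg$planted_event_table
      for (r in seq_len(nrow(pet))) {
        i <- pet$spacer_rank[r]
        if (i <= nrow(primary)) {
          cat_first[i] <- pet$category_first[r]
          cat_last[i] <- pet$category_last[r]
        }
      }
    }
    for (i in seq_len(nrow(primary))) {
      sp <- primary$spacer_id[i]
      im <- primary$imge_id[i]
      fi <- if (is.na(im_win[im, 1L])) sample(3:(n - 9L), 1L) else im_win[im, 1L]
      li <- if (is.na(im_win[im, 2L])) sample((fi + 5L):(n - 1L), 1L)
            else im_win[im, 2L]
      fs <- switch(cat_first[i],
        gain = fi + sample(1:4, 1L),
        probable_gain = fi,
        probable_secondary_encounter = max(1L, fi - sample(1:3, 1L)))
      ls <- switch(cat_last[i],
        loss = min(n, li + sample(1:3, 1L)),
        probable_loss = li,
        spacer_loss_before_imge_loss = max(fs, li - sample(1:3, 1L)))
      if (ls < fs) ls <- fs
      im_win[im, ] <- c(fi, li)
      sp_win[sp, ] <- c(fs, ls)
    }
    # elements reached only as secondary targets get their own windows
    for (im in setdiff(unique(placements$imge_id), rownames(im_win)[
      !is.na(im_win[, 1L])])) {
      fi <- sample(3:(n - 9L), 1L)
      im_win[im, ] <- c(fi, sample((fi + 5L):(n - 1L), 1L))
    }
  } else if (nrow(placements) > 0) {
    # very short series: everything present throughout
    sp_win[unique(placements$spacer_id), 1L] <- 1L
    sp_win[unique(placements$spacer_id), 2L] <- n
    im_win[unique(placements$imge_id), 1L] <- 1L
    im_win[unique(placements$imge_id), 2L] <- n
  }
  # spacers that ended up with no placement (possible when n_imges is tiny)
  no_pl <- is.na(sp_win[, 1L])
  if (any(no_pl)) {
    sp_win[no_pl, 1L] <- 1L
    sp_win[no_pl, 2L] <- n
  }

  ## ---- element binning (family association) ------------------------------
  # a targeted element is binned with the MAG of its first targeting spacer
  imge_mag <- setNames(rep(NA_character_, cfg$n_imges), imge_ids)
  if (nrow(placements) > 0 && n_loci > 0) {
    first_sp <- placements[!duplicated(placements$imge_id), ]
    imge_mag[first_sp$imge_id] <-
      mags[spacer_locus[match(first_sp$spacer_id, spacer_ids)]]
  }
  imge_rmag <- mag2rmag$rmag[match(imge_mag, mag2rmag$mag)]
  imge_family <- rmag2family$family[match(imge_rmag, rmag2family$rmag)]

  ## ---- element depth series ----------------------------------------------
  shift <- cfg$shift_window
  in_shift <- seq_len(n) >= shift[1] & seq_len(n) <= shift[2]
  depth_imge <- matrix(0, cfg$n_imges, n, dimnames = list(imge_contig, date_ids))
  if (cfg$n_imges > 0) {
    for (j in seq_len(cfg$n_imges)) {
      w <- im_win[j, ]
      if (is.na(w[1L])) {
        # untargeted: random window, small depth
        f <- sample(seq_len(max(1L, n - 4L)), 1L)
        w <- c(f, min(n, f + sample(3:12, 1L)))
      }
      tt <- w[1L]:w[2L]
      base <- runif(1, 1, 3)
      prof <- base * (1 + 0.5 * sin(2 * pi * (tt - sample.int(n, 1L)) / n))
      # family-1 plasmids surge during the community shift
      if (!is.na(imge_family[j]) && imge_family[j] == "family_01" &&
          imge_label[j] == "plasmid") {
        prof <- prof * ifelse(in_shift[tt], 3, 1)
      }
      depth_imge[j, tt] <- prof
    }
  }
  # metatranscriptome-only elements: depth moves to the MT table (before the
  # slack depths are computed, so the element total stays constant)
  mt_only_ids <- character(0)
  mt_profiles <- list()
  if (cfg$n_mt_only > 0 && cfg$n_imges > 0) {
    pool2 <- setdiff(imge_ids, twin_of)
    mt_only_ids <- sample(pool2, min(cfg$n_mt_only, length(pool2)))
    for (im in mt_only_ids) {
      j <- match(im, imge_ids)
      prof <- depth_imge[j, ]
      if (all(prof == 0)) prof[] <- 0.5
      mt_profiles[[im]] <- prof
      depth_imge[j, ] <- 0
    }
  }
  # slack plasmids keep the per-sample element depth total constant
  slack_ids <- character(0)
  pool <- setdiff(untargeted_plasmids, c(twin_of, mt_only_ids))
  n_slack <- min(cfg$n_slack, length(pool))
  if (n_slack > 0) {
    slack_ids <- sample(pool, n_slack)
    depth_imge[match(slack_ids, imge_ids), ] <- 0
    tot <- colSums(depth_imge)
    T_i <- 1.3 * max(tot, 1)
    depth_imge[match(slack_ids, imge_ids), ] <-
      matrix(rep((T_i - tot) / n_slack, each = n_slack), n_slack, n)
  }
  depth_imge_mt <- depth_imge * 0.5
  for (im in mt_only_ids) {
    depth_imge_mt[match(im, imge_ids), ] <- mt_profiles[[im]]
  }

  ## ---- host depth series and the planted linear model --------------------
  resp <- NULL
  model_truth <- NULL
  host_depth <- matrix(0, cfg$n_hosts, n, dimnames = list(hosts, date_ids))
  if (cfg$n_hosts > 0) {
    # element group series in relative-abundance units (element total is
    # constant by construction, so depth and relative abundance are
    # proportional)
    T_i_tot <- colSums(depth_imge)
    grp_key <- paste(imge_family, imge_label, sep = "|")
    grp_key[is.na(imge_family)] <- NA
    groups <- sort(unique(stats::na.omit(grp_key)))
    g_rel <- matrix(0, length(groups), n, dimnames = list(groups, date_ids))
    for (g in groups) {
      rows <- which(grp_key == g)
      g_rel[g, ] <- 100 * colSums(depth_imge[rows, , drop = FALSE]) /
        ifelse(T_i_tot > 0, T_i_tot, 1)
    }
    pred_pool <- c(intersect("family_01|plasmid", groups),
                   setdiff(groups, "family_01|plasmid"))
    preds <- head(pred_pool, 3L)
    signs <- c(-1, 1, -1)[seq_along(preds)]
    target_sd <- c(3, 2.5, 2)[seq_along(preds)]
    beta <- numeric(0)
    raw <- rep(0, n)
    if (length(preds)) {
      beta <- vapply(seq_along(preds), function(k) {
        s <- sd(g_rel[preds[k], ])
        signs[k] * target_sd[k] / max(s, 1e-6)
      }, numeric(1))
      names(beta) <- preds
      raw <- as.numeric(beta %*% g_rel[preds, , drop = FALSE])
    }
    beta0 <- 18 - min(raw)
    resp_det <- beta0 + raw
    noise_sd <- cfg$response_noise_frac * max(sd(resp_det), 1e-6)
    eps <- rnorm(n, 0, noise_sd)
    resp <- pmax(resp_det + eps, 1)

    # distribute the response over family-1 hosts; other hosts get modest
    # series, families 2-3 rising during the shift (acyclic behaviour)
    fam1_hosts <- hosts[host_family == "family_01"]
    shares <- if (length(fam1_hosts)) {
      sh <- seq(1.4, 0.6, length.out = length(fam1_hosts))
      sh / sum(sh)
    } else numeric(0)
    for (i in seq_along(fam1_hosts)) {
      host_depth[fam1_hosts[i], ] <- shares[i] * resp
    }
    other <- setdiff(hosts, fam1_hosts)
    for (h in other) {
      fam <- host_family[match(h, hosts)]
      base <- runif(1, 2, 4)
      ser <- base * (1 + 0.25 * sin(2 * pi * (seq_len(n) -
                                                sample.int(n, 1L)) / n))
      if (fam %in% c("family_02", "family_03")) {
        ser <- ser * ifelse(in_shift, 1.8, 1)
      }
      host_depth[h, ] <- ser
    }
    # a filler population keeps the host depth total constant per sample, so
    # bacterial relative abundances are exactly proportional to depths and
    # the planted linear relation carries over to the relative scale
    host_tot <- colSums(host_depth)
    T_h <- 1.25 * max(host_tot)
    filler_depth <- T_h - host_tot
    rel_scale <- 100 / T_h
    model_truth <- list(response_group = "family_01|bacteria",
                        predictor_groups = preds,
                        beta0 = beta0 * rel_scale,
                        beta = beta * rel_scale,
                        noise_sd = noise_sd * rel_scale,
                        response_series = round(resp * rel_scale, 6),
                        predictor_series = round(g_rel[preds, , drop = FALSE],
                                                 6))
  }

  ## ---- filler population --------------------------------------------------
  if (cfg$n_hosts > 0) {
    contigs[["filler_contig"]] <- .random_dna(1L, 800L)
    mag2rmag <- rbind(mag2rmag,
                      data.frame(mag = "mag_filler", rmag = "rmag_filler"))
    rmag2family <- rbind(rmag2family,
                         data.frame(rmag = "rmag_filler",
                                    family = "family_other"))
  }

  ## ---- depth tables -------------------------------------------------------
  all_contigs <- names(contigs)
  depth_mg <- matrix(0, length(all_contigs), n,
                     dimnames = list(all_contigs, date_ids))
  depth_mt <- depth_mg
  if (cfg$n_imges > 0) {
    depth_mg[imge_contig, ] <- depth_imge
    depth_mt[imge_contig, ] <- depth_imge_mt
  }
  # host contigs share their rMAG depth (split between the rMAG's MAGs is
  # irrelevant: every contig carries the rMAG series)
  for (l in seq_len(n_loci)) {
    r <- mag2rmag$rmag[l]
    d <- host_depth[r, ]
    depth_mg[sprintf("host_contig_%02d", l), ] <- d
    depth_mg[sprintf("host_extra_%02d", l), ] <- d
    depth_mt[sprintf("host_contig_%02d", l), ] <- 0.8 * d
    depth_mt[sprintf("host_extra_%02d", l), ] <- 0.8 * d
  }
  if (cfg$n_hosts > 0) {
    depth_mg["filler_contig", ] <- filler_depth
    depth_mt["filler_contig", ] <- 0.8 * filler_depth
  }
  for (im in twin_of) {
    w <- im_win[im, ]
    f <- if (is.na(w[1L])) 1L else w[1L]
    l2 <- if (is.na(w[2L])) min(n, f + 5L) else w[2L]
    depth_mg[paste0(im, "_twin"), f:l2] <- runif(1, 0.2, 0.6)
  }
  for (bc in bg_contigs) {
    f <- sample(seq_len(max(1L, n - 3L)), 1L)
    depth_mg[bc, f:min(n, f + sample(2:10, 1L))] <- runif(1, 0.5, 2)
  }
  depth_mg <- round(depth_mg, 6)
  depth_mt <- round(depth_mt, 6)

  ## ---- predictor flags ----------------------------------------------------
  flag_contigs <- c(imge_contig, twin_contigs)
  flag_label <- c(imge_label,
                  imge_label[match(twin_of, imge_ids)])
  fl <- data.frame(contig = all_contigs,
                   plasmid_cbar = FALSE, plasmid_plasflow = FALSE,
                   phage_virsorter = FALSE, phage_virfinder = FALSE)
  for (i in seq_along(flag_contigs)) {
    pick <- sample(3L, 1L)  # 1 = first predictor, 2 = second, 3 = both
    cols <- if (flag_label[i] == "plasmid") {
      c("plasmid_cbar", "plasmid_plasflow")
    } else c("phage_virsorter", "phage_virfinder")
    on <- switch(pick, cols[1L], cols[2L], cols)
    fl[fl$contig == flag_contigs[i], on] <- TRUE
  }
  if (cfg$predictor_error_rate > 0) {
    for (cn in c("plasmid_cbar", "plasmid_plasflow", "phage_virsorter",
                 "phage_virfinder")) {
      flip <- runif(nrow(fl)) < cfg$predictor_error_rate
      fl[[cn]] <- xor(fl[[cn]], flip)
    }
  }

  ## ---- CRISPR element tables ---------------------------------------------
  elements <- list()
  add_el <- function(id, kind, seqs, samples, contig, coverage) {
    elements[[length(elements) + 1L]] <<- data.frame(
      element_id = id, kind = kind, sequence = seqs,
      sample = samples, contig = contig, coverage = coverage)
  }
  variant_sp <- if (S > 0) {
    sample(spacer_ids, round(cfg$spacer_variant_frac * S))
  } else character(0)
  for (i in seq_len(S)) {
    sp <- spacer_ids[i]
    l <- spacer_locus[i]
    win <- sp_win[sp, 1L]:sp_win[sp, 2L]
    add_el(sp, "spacer", spacer_seqs[i], date_ids[win],
           sprintf("host_contig_%02d", l), 10)
    if (sp %in% variant_sp && length(win) > 1L) {
      vs <- .mutate_subs(spacer_seqs[i], 1L)
      sub <- sort(sample(win, max(1L, length(win) %/% 2L)))
      add_el(paste0(sp, "_var"), "spacer", vs, date_ids[sub],
             sprintf("host_contig_%02d", l), 5)
    }
  }
  for (l in seq_len(n_loci)) {
    n_cp <- cfg$n_spacers_per_host + 1L
    rp_samples <- date_ids[sort(sample.int(n, min(3L, n)))]
    for (cp in seq_len(n_cp)) {
      add_el(sprintf("rp_%02d_%02d", l, cp), "repeat", repeat_seqs[l],
             rp_samples, sprintf("host_contig_%02d", l), 8)
    }
    # one mildly diverged repeat copy exercises repeat clustering
    add_el(sprintf("rp_%02d_var", l), "repeat",
           .mutate_subs(repeat_seqs[l], 2L), rp_samples[1L],
           sprintf("host_contig_%02d", l), 4)
    add_el(sprintf("fl_%02d", l), "flank", flank_seqs[l],
           date_ids[sort(sample.int(n, min(3L, n)))],
           sprintf("host_contig_%02d", l), 6)
  }
  elements <- if (length(elements)) do.call(rbind, elements) else
    data.frame(element_id = character(0), kind = character(0),
               sequence = character(0), sample = character(0),
               contig = character(0), coverage = numeric(0))

  ## ---- ground truth -------------------------------------------------------
  link_truth <- placements
  if (nrow(link_truth)) {
    fs <- sp_win[link_truth$spacer_id, 1L]
    ls <- sp_win[link_truth$spacer_id, 2L]
    fi <- im_win[link_truth$imge_id, 1L]
    li <- im_win[link_truth$imge_id, 2L]
    link_truth$category_first <- ifelse(fs > fi, "gain",
                                 ifelse(fs == fi, "probable_gain",
                                        "probable_secondary_encounter"))
    link_truth$category_last <- ifelse(ls > li, "loss",
                                ifelse(ls == li, "probable_loss",
                                       "spacer_loss_before_imge_loss"))
    link_truth$lag_days <- as.numeric(dates[fs] - dates[fi])
  } else {
    link_truth$category_first <- character(0)
    link_truth$category_last <- character(0)
    link_truth$lag_days <- numeric(0)
  }
  spacer_truth <- data.frame(
    spacer_id = spacer_ids,
    sequence = spacer_seqs,
    locus = spacer_locus,
    mag = if (S > 0) mags[spacer_locus] else character(0),
    rmag = if (S > 0) mag2rmag$rmag[spacer_locus] else character(0),
    first_idx = if (S > 0) sp_win[, 1L] else integer(0),
    last_idx = if (S > 0) sp_win[, 2L] else integer(0))
  imge_truth <- data.frame(
    imge_id = imge_ids, contig = imge_contig, label = imge_label,
    family = unname(imge_family), mag = unname(imge_mag),
    targeted = imge_ids %in% targeted,
    slack = imge_ids %in% slack_ids,
    mt_only = imge_ids %in% mt_only_ids,
    first_idx = unname(im_win[, 1L]), last_idx = unname(im_win[, 2L]))
  twins <- data.frame(twin_contig = twin_contigs,
                      original_imge = twin_of)

  contig2mag <- if (length(contig2mag)) do.call(rbind, contig2mag) else
    data.frame(contig = character(0), mag = character(0))
  if (cfg$n_hosts > 0) {
    contig2mag <- rbind(contig2mag,
                        data.frame(contig = "filler_contig",
                                   mag = "mag_filler"))
  }
  # binned elements join their MAG
  binned <- !is.na(imge_mag)
  if (any(binned)) {
    contig2mag <- rbind(contig2mag,
                        data.frame(contig = imge_contig[binned],
                                   mag = unname(imge_mag[binned])))
  }

  structure(list(
    contigs = vapply(contigs, identity, character(1)),
    elements = elements,
    contig2mag = contig2mag,
    mag2rmag = mag2rmag,
    rmag2family = rmag2family,
    depth_mg = depth_mg,
    depth_mt = depth_mt,
    flags = fl,
    dates = dates,
    ground_truth = list(spacers = spacer_truth, links = link_truth,
                        imges = imge_truth, twins = twins,
                        model = model_truth,
                        host_contigs = host_contigs),
    config = cfg), class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_community> %d time points (%s .. %s), ",
                     "%d contigs, %d hosts, %d elements, %d planted links\n"),
              length(x$dates), .iso_date(x$dates[1]),
              .iso_date(x$dates[length(x$dates)]),
              length(x$contigs), nrow(x$rmag2family),
              nrow(x$ground_truth$imges), nrow(x$ground_truth$links)))
  invisible(x)
}
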