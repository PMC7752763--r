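#' Match CRISPR flanking sequences to MAG contigs
#'
#' Stage one of locus-to-genome anchoring: each non-redundant flanking
#' sequence is aligned against every MAG contig and candidate links are
#' retained when identity is at least `identity_min` and the aligned fraction
#' of the flank meets a length-dependent coverage rule: flanks of at least
#' `long_flank_len` bases need `coverage_long`, shorter flanks need the
#' stricter `coverage_short`.
#'
#' @param flank_clusters `seq_clusters` of flanking sequences.
#' @param contigs named character vector of MAG contig sequences.
#' @param contig2mag data.frame with columns `contig`, `mag`.
#' @param identity_min minimum identity (default 0.95).
#' @param coverage_long,coverage_short flank-coverage minima for long/short
#'   flanks (defaults 0.80 and 0.95).
#' @param long_flank_len length (nt) at or above which the long-flank branch
#'   applies (default 100).
#' @return data.frame of candidate links: `flank_cluster`, `mag`, `contig`,
#'   `flank_len`, `identity`, `flank_coverage`, `strand`.
#' @export
match_flanks_to_mags <- function(flank_clusters, contigs, contig2mag,
                                 identity_min = 0.95, coverage_long = 0.80,
                                 coverage_short = 0.95, long_flank_len = 100) {
  stopifnot(inherits(flank_clusters, "seq_clusters"),
            !is.null(names(contigs)),
            all(c("contig", "mag") %in% names(contig2mag)))
  contigs <- contigs[names(contigs) %in% contig2mag$contig]
  reps <- cluster_representatives(flank_clusters)
  out <- list()
  for (fc in names(reps)) {
    flank <- reps[[fc]]
    cov_min <- if (nchar(flank) >= long_flank_len) coverage_long
               else coverage_short
    st <- .batch_align_stats(flank, unname(contigs))
    ok <- st$identity >= identity_min & st$query_coverage >= cov_min
    if (any(ok)) {
      out[[length(out) + 1L]] <- data.frame(
        flank_cluster = fc,
        mag = contig2mag$mag[match(names(contigs)[ok], contig2mag$contig)],
        contig = names(contigs)[ok], flank_len = nchar(flank),
        identity = st$identity[ok], flank_coverage = st$query_coverage[ok],
        strand = st$strand[ok])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(flank_cluster = character(0), mag = character(0),
                      contig = character(0), flank_len = integer(0),
                      identity = numeric(0), flank_coverage = numeric(0),
                      strand = character(0)))
  }
  do.call(rbind, out)
}

#' Confirm flank-anchored candidate links with repeat matches
#'
#' Stage two: a candidate (flank, MAG) link is confirmed when one of the
#' repeats sharing a locus with the flank aligns to any contig of the same
#' MAG at `identity_min` identity and `coverage_min` repeat coverage.
#' Candidates whose flank has no associated repeat are dropped with a warning.
#'
#' @param candidates data.frame from [match_flanks_to_mags()].
#' @param repeat_clusters `seq_clusters` of repeats.
#' @param locus_map data.frame associating clusters that originate from the
#'   same CRISPR locus, with columns `flank_cluster` and `repeat_cluster`.
#' @param contigs named character vector of MAG contig sequences.
#' @param contig2mag data.frame with columns `contig`, `mag`.
#' @param identity_min minimum repeat identity (default 0.75).
#' @param coverage_min minimum repeat coverage (default 0.80).
#' @return data.frame of confirmed links: candidate columns plus
#'   `repeat_cluster`, `repeat_identity`, `repeat_coverage`,
#'   `repeat_contig`, `same_contig`.
#' @export
confirm_with_repeats <- function(candidates, repeat_clusters, locus_map,
                                 contigs, contig2mag,
                                 identity_min = 0.75, coverage_min = 0.80) {
  stopifnot(inherits(repeat_clusters, "seq_clusters"),
            all(c("flank_cluster", "repeat_cluster") %in% names(locus_map)))
  reps <- cluster_representatives(repeat_clusters)
  out <- list()
  if (nrow(candidates)) for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    rcs <- unique(locus_map$repeat_cluster[
      locus_map$flank_cluster == cand$flank_cluster])
    rcs <- rcs[rcs %in% names(reps)]
    if (length(rcs) == 0L) {
      warning("candidate flank ", cand$flank_cluster,
              " has no associated repeat; dropped", call. = FALSE)
      next
    }
    mag_contigs <- contig2mag$contig[contig2mag$mag == cand$mag]
    mag_contigs <- mag_contigs[mag_contigs %in% names(contigs)]
    for (rc in rcs) {
      hit <- NULL
      if (length(mag_contigs)) {
        st <- .batch_align_stats(reps[[rc]], unname(contigs[mag_contigs]))
        ok <- which(st$identity >= identity_min &
                      st$query_coverage >= coverage_min)
        if (length(ok)) {
          j <- ok[1L]
          hit <- list(contig = mag_contigs[j], identity = st$identity[j],
                      coverage = st$query_coverage[j])
        }
      }
      if (!is.null(hit)) {
        row <- cand
        row$repeat_cluster <- rc
        row$repeat_identity <- hit$identity
        row$repeat_coverage <- hit$coverage
        row$repeat_contig <- hit$contig
        row$same_contig <- hit$contig == cand$contig
        out[[length(out) + 1L]] <- row
        break
      }
    }
  }
  if (length(out) == 0L) {
    empty <- candidates[0, ]
    empty$repeat_cluster <- character(0)
    empty$repeat_identity <- numeric(0)
    empty$repeat_coverage <- numeric(0)
    empty$repeat_contig <- character(0)
    empty$same_contig <- logical(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign spacers of confirmed CRISPR loci to MAGs and rMAGs
#'
#' Every spacer belonging to a confirmed locus (shared flank) is associated
#' with the linked MAG and propagated to its representative genome (rMAG).
#' A spacer may legitimately end up on several rMAGs.
#'
#' @param links confirmed links from [confirm_with_repeats()].
#' @param locus_map data.frame with columns `flank_cluster`,
#'   `spacer_cluster` associating spacers with their locus flank.
#' @param mag2rmag data.frame with columns `mag`, `rmag`.
#' @return data.frame with columns `spacer_cluster`, `mag`, `rmag` (unique
#'   rows).
#' @export
assign_spacers <- function(links, locus_map, mag2rmag) {
  stopifnot(all(c("flank_cluster", "spacer_cluster") %in% names(locus_map)),
            all(c("mag", "rmag") %in% names(mag2rmag)))
  if (nrow(links) == 0L) {
    return(data.frame(spacer_cluster = character(0), mag = character(0),
                      rmag = character(0)))
  }
  missing <- setdiff(unique(links$mag), mag2rmag$mag)
  if (length(missing)) {
    stop("MAG(s) missing from the rMAG map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sp <- merge(links[, c("flank_cluster", "mag")],
              locus_map[, c("flank_cluster", "spacer_cluster")],
              by = "flank_cluster")
  sp <- sp[!is.na(sp$spacer_cluster), ]
  sp$rmag <- mag2rmag$rmag[match(sp$mag, mag2rmag$mag)]
  out <- unique(sp[, c("spacer_cluster", "mag", "rmag")])
  out <- out[order(out$spacer_cluster, out$mag), ]
  rownames(out) <- NULL
  out
}

#' Derive locus membership of clustered CRISPR elements
#'
#' CRISPR elements reported from the same source contig are taken to belong
#' to one locus; the table relates the flank cluster of each locus to its
#' repeat and spacer clusters.
#'
#' @param elements element table with columns `element_id`, `kind`
#'   (`spacer`/`repeat`/`flank`) and `contig` (source contig).
#' @param spacer_clusters,repeat_clusters,flank_clusters `seq_clusters`
#'   objects whose member ids are `element_id`s.
#' @return data.frame with columns `locus_contig`, `flank_cluster`,
#'   `repeat_cluster`, `spacer_cluster` (one row per locus x repeat x spacer).
#' @export
build_locus_map <- function(elements, spacer_clusters, repeat_clusters,
                            flank_clusters) {
  stopifnot(all(c("element_id", "kind", "contig") %in% names(elements)))
  el2cl <- function(cl) {
    m <- cluster_membership(cl)
    setNames(m$cluster_id, m$member_id)
  }
  sp_map <- el2cl(spacer_clusters)
  rp_map <- el2cl(repeat_clusters)
  fl_map <- el2cl(flank_clusters)
  el <- unique(elements[, c("element_id", "kind", "contig")])
  out <- list()
  for (ct in unique(el$contig)) {
    sub <- el[el$contig == ct, ]
    fls <- unique(fl_map[sub$element_id[sub$kind == "flank"]])
    rps <- unique(rp_map[sub$element_id[sub$kind == "repeat"]])
    sps <- unique(sp_map[sub$element_id[sub$kind == "spacer"]])
    fls <- fls[!is.na(fls)]; rps <- rps[!is.na(rps)]; sps <- sps[!is.na(sps)]
    if (length(fls) == 0L) next
    grid <- expand.grid(
      flank_cluster = fls,
      repeat_cluster = if (length(rps)) rps else NA_character_,
      spacer_cluster = if (length(sps)) sps else NA_character_,
      stringsAsFactors = FALSE)
    grid$locus_contig <- ct
    out[[length(out) + 1L]] <- grid
  }
  if (length(out) == 0L) {
    return(data.frame(locus_contig = character(0),
                      flank_cluster = character(0),
                      repeat_cluster = character(0),
                      spacer_cluster = character(0)))
  }
  res <- do.call(rbind, out)
  res[, c("locus_contig", "flank_cluster", "repeat_cluster",
          "spacer_cluster")]
}
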