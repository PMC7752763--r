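# Independent oracles, implemented from first principles in plain R so they
# share no code with the package internals.

# Dynamic-programming pairwise alignment with linear gap penalty and full
# traceback; N matches nothing. mode "local" = Smith-Waterman, "global" =
# Needleman-Wunsch with end gaps penalised. Returns score, matches, columns,
# identity and the aligned span of each sequence (1-based).
oracle_align_one <- function(q, t, match = 1, mismatch = -1, gap = -2,
                             mode = "local") {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 0 stop, 1 diag, 2 up (gap in t), 3 left
  if (mode == "global") {
    H[, 1L] <- gap * (0:n); H[1L, ] <- gap * (0:m)
    P[2:(n + 1L), 1L] <- 2L; P[1L, 2:(m + 1L)] <- 3L
  }
  for (i in 1:n) for (j in 1:m) {
    s <- if (qc[i] == tc[j] && qc[i] != "N") match else mismatch
    cand <- c(H[i, j] + s, H[i, j + 1L] + gap, H[i + 1L, j] + gap)
    if (mode == "local") cand <- c(cand, 0)
    k <- which.max(cand)
    H[i + 1L, j + 1L] <- cand[k]
    P[i + 1L, j + 1L] <- if (mode == "local" && k == 4L) 0L else k
  }
  if (mode == "local") {
    best <- which(H == max(H), arr.ind = TRUE)[1L, ]
  } else {
    best <- c(n + 1L, m + 1L)
  }
  i <- best[1L]; j <- best[2L]
  qe <- i - 1L; te <- j - 1L
  matches <- 0L; columns <- 0L
  while (i > 1L || j > 1L) {
    if (mode == "local" && (P[i, j] == 0L || H[i, j] == 0 && P[i, j] == 0L)) break
    if (mode == "local" && P[i, j] == 0L) break
    op <- P[i, j]
    if (op == 0L) break
    columns <- columns + 1L
    if (op == 1L) {
      if (qc[i - 1L] == tc[j - 1L] && qc[i - 1L] != "N") matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (op == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = H[best[1L], best[2L]], matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else 0,
       q_span = c(i - 1L, qe), t_span = c(j - 1L, te))
}

oracle_align <- function(q, t, match = 1, mismatch = -1, gap = -2,
                         mode = "local") {
  rc <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  fwd <- oracle_align_one(q, t, match, mismatch, gap, mode)
  rev <- oracle_align_one(q, rc(t), match, mismatch, gap, mode)
  if (rev$score > fwd$score) c(rev, strand = "-") else c(fwd, strand = "+")
}

# Independent greedy clustering: same ordering rule (length desc, then
# lexicographic) and first-match-wins assignment, but decisions are made from
# the all-pairs oracle alignments.
oracle_greedy_cluster <- function(seqs, identity_min, coverage_rule,
                                  coverage_min = 1) {
  ord <- order(-nchar(seqs), seqs, names(seqs))
  seqs <- seqs[ord]
  reps <- integer(0)  # indices into seqs
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (r in reps) {
      if (oracle_match(seqs[i], seqs[r], identity_min, coverage_rule,
                       coverage_min)) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      assign[i] <- i
    } else {
      assign[i] <- hit
    }
  }
  split(names(seqs), assign)
}

oracle_match <- function(q, r, identity_min, coverage_rule, coverage_min) {
  if (q == r) return(TRUE)
  mode <- if (coverage_rule == "both_full") "global" else "local"
  a <- oracle_align(q, r, mode = mode)
  if (a$identity < identity_min) return(FALSE)
  if (coverage_rule == "both_full") return(TRUE)
  qcov <- (a$q_span[2] - a$q_span[1]) / nchar(q)
  rcov <- (a$t_span[2] - a$t_span[1]) / nchar(r)
  switch(coverage_rule,
         shorter_min = (if (nchar(q) <= nchar(r)) qcov else rcov) >=
           coverage_min,
         both_min = qcov >= coverage_min && rcov >= coverage_min)
}

# Exhaustive Barber modularity: enumerate every set partition of the joint
# node set (restricted growth strings) and return the maximum Q. Partition
# tables are memoised per node count; Q is evaluated vectorised over all
# partitions at once.
.partition_cache <- new.env(parent = emptyenv())
all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  parts <- matrix(1L, 1L, 1L)
  if (n > 1L) for (v in 2:n) {
    mx <- apply(parts, 1L, max)
    parts <- parts[rep(seq_len(nrow(parts)), mx + 1L), , drop = FALSE]
    newcol <- unlist(lapply(mx, function(x) seq_len(x + 1L)))
    parts <- cbind(parts, newcol)
  }
  .partition_cache[[key]] <- parts
  parts
}

oracle_barber_q <- function(A) {
  nr <- nrow(A); nc <- ncol(A)
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  parts <- all_set_partitions(nr + nc)
  q <- numeric(nrow(parts))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    q <- q + B[i, j] * (parts[, i] == parts[, nr + j])
  }
  max(q) / m
}

# one full default-scale run shared by the end-to-end checks
.default_run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.default_run_cache$run)) {
    d <- simulate_community(simulation_config(seed = 23))
    r <- suppressMessages(run_pipeline(d, seed = 2))
    .default_run_cache$run <- list(dataset = d, result = r)
  }
  .default_run_cache$run
}

# small, fast simulation configuration for unit tests
small_sim <- function(seed = 1, ...) {
  simulate_community(simulation_config(
    n_timepoints = 15, n_hosts = 4, n_extra_mags = 1, n_families = 3,
    n_imges = 30, n_spacers_per_host = 4, n_twin_plasmids = 2,
    n_mt_only = 2, n_background = 2, n_slack = 3, seed = seed, ...))
}
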