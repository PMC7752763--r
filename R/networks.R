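#' Build a global bipartite host-element interaction network
#'
#' One edge per (host rMAG, invasive element) pair supported by at least one
#' active spacer link of the requested label class. Ambiguous and
#' unclassified elements are excluded by default.
#'
#' @param links data.frame with columns `rmag`, `imge`, `spacer`, `label`
#'   (active spacer links joined to their host assignment).
#' @param label_class `"plasmid"` or `"phage"`.
#' @return object of class `bipartite_net`: list with `hosts`, `imges`,
#'   `edges` (data.frame `host`, `imge`, `n_spacers`, `spacers`),
#'   `label_class` and `date` (`NA` for the global network).
#' @export
build_global_network <- function(links, label_class = c("plasmid", "phage")) {
  label_class <- match.arg(label_class)
  sel <- links[links$label == label_class, , drop = FALSE]
  if (nrow(sel) == 0L) {
    edges <- data.frame(host = character(0), imge = character(0),
                        n_spacers = integer(0), spacers = character(0))
    return(structure(list(hosts = character(0), imges = character(0),
                          edges = edges, label_class = label_class,
                          date = as.Date(NA)),
                     class = "bipartite_net"))
  }
  key <- paste(sel$rmag, sel$imge, sep = "\r")
  sp <- split(unique(sel[, c("rmag", "imge", "spacer")]), key)
  # split() keys sort lexicographically; rebuild in that order
  edges <- do.call(rbind, lapply(sp, function(d) {
    data.frame(host = d$rmag[1L], imge = d$imge[1L],
               n_spacers = length(unique(d$spacer)),
               spacers = paste(sort(unique(d$spacer)), collapse = ","))
  }))
  rownames(edges) <- NULL
  structure(list(hosts = sort(unique(edges$host)),
                 imges = sort(unique(edges$imge)),
                 edges = edges, label_class = label_class,
                 date = as.Date(NA)),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("<bipartite_net> %s-host: %d hosts, %d elements, %d edges%s\n",
              x$label_class, length(x$hosts), length(x$imges),
              nrow(x$edges),
              if (!is.na(x$date)) paste0(" @ ", x$date) else ""))
  invisible(x)
}

#' Time-point-specific interaction network
#'
#' Restricts a global network to one date: an edge is retained when both
#' endpoints are present (detected in either MG or MT data) at that date;
#' present nodes whose partners are all absent are kept as orphans.
#'
#' @param net global `bipartite_net`.
#' @param host_presence,imge_presence logical matrices (nodes x samples) with
#'   column names containing the date axis.
#' @param date the date (coercible to character matching a column name).
#' @return a `bipartite_net` stamped with `date`, possibly with orphan nodes.
#' @export
time_point_network <- function(net, host_presence, imge_presence, date) {
  dt <- as.character(date)
  if (!dt %in% colnames(host_presence) || !dt %in% colnames(imge_presence)) {
    stop("date ", dt, " is not on the sample axis", call. = FALSE)
  }
  hp <- rownames(host_presence)[host_presence[, dt]]
  ip <- rownames(imge_presence)[imge_presence[, dt]]
  edges <- net$edges[net$edges$host %in% hp & net$edges$imge %in% ip, ,
                     drop = FALSE]
  rownames(edges) <- NULL
  structure(list(hosts = intersect(net$hosts, hp),
                 imges = intersect(net$imges, ip),
                 edges = edges, label_class = net$label_class,
                 date = as.Date(dt)),
            class = "bipartite_net")
}

#' Incidence matrix of a bipartite network
#'
#' @param net a `bipartite_net`.
#' @return 0/1 matrix, hosts x elements (orphans give empty rows/columns).
#' @export
incidence_matrix <- function(net) {
  m <- matrix(0L, length(net$hosts), length(net$imges),
              dimnames = list(net$hosts, net$imges))
  if (nrow(net$edges)) {
    m[cbind(net$edges$host, net$edges$imge)] <- 1L
  }
  m
}

#' Barber bipartite modularity
#'
#' Maximises Barber's bipartite modularity
#' \deqn{Q = \frac{1}{m} \sum_{ij} (A_{ij} - k_i d_j / m)\,\delta(g_i, g_j)}
#' over joint module assignments of hosts (rows) and elements (columns) by
#' label propagation with random restarts followed by greedy module merging.
#' Deterministic under the given seed.
#'
#' @param net a `bipartite_net` or a 0/1 incidence matrix.
#' @param n_restarts random restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @return list with `Q` (numeric; `NA` for an edgeless network) and
#'   `modules` (named integer vector over rows then columns).
#' @export
barber_modularity <- function(net, n_restarts = 20, seed = 1) {
  A <- if (inherits(net, "bipartite_net")) incidence_matrix(net) else net
  if (length(A) == 0L || sum(A) == 0) {
    return(list(Q = NA_real_, modules = integer(0)))
  }
  .with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      res <- .lp_modularity_once(A, random_init = r > 1L)
      if (is.null(best) || res$Q > best$Q + 1e-12) best <- res
    }
    best
  })
}

# Barber Q for given row/column module assignments
.barber_q <- function(A, gr, gc) {
  m <- sum(A)
  k <- rowSums(A)
  d <- colSums(A)
  same <- outer(gr, gc, `==`)
  sum((A - outer(k, d) / m) * same) / m
}

# One label-propagation run: alternate locally optimal module moves for
# columns and rows, then greedily merge modules while Q improves.
.lp_modularity_once <- function(A, random_init = FALSE, max_sweeps = 50L) {
  nr <- nrow(A); nc <- ncol(A)
  m <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  gr <- if (random_init) sample.int(max(1L, nr), nr, replace = TRUE)
        else seq_len(nr)
  gc <- integer(nc)
  B <- A - outer(k, d) / m  # modularity matrix

  next_mod <- max(gr) + 1L
  assign_side <- function(scores_by_mod, mods) {
    # scores_by_mod: modules x nodes matrix of contribution sums; a node
    # whose best module contribution is negative founds its own module
    out <- integer(ncol(scores_by_mod))
    for (j in seq_len(ncol(scores_by_mod))) {
      s <- scores_by_mod[, j]
      mx <- max(s)
      if (mx < -1e-12) {
        out[j] <- next_mod
        next_mod <<- next_mod + 1L
      } else {
        out[j] <- mods[which(s >= mx - 1e-12)[1L]]
      }
    }
    out
  }
  sweep_once <- function(gr, gc) {
    mods <- sort(unique(gr))
    rowsum_by_mod <- rowsum(B, group = match(gr, mods))  # modules x nc
    gc <- assign_side(rowsum_by_mod, mods)
    mods <- sort(unique(gc))
    colsum_by_mod <- rowsum(t(B), group = match(gc, mods))  # modules x nr
    gr <- assign_side(colsum_by_mod, mods)
    list(gr = gr, gc = gc)
  }
  q_old <- -Inf
  for (it in seq_len(max_sweeps)) {
    st <- sweep_once(gr, gc)
    gr <- st$gr; gc <- st$gc
    q <- .barber_q(A, gr, gc)
    if (q <= q_old + 1e-12) break
    q_old <- q
  }
  # greedy merging of module pairs while it improves Q
  repeat {
    mods <- sort(unique(c(gr, gc)))
    if (length(mods) < 2L) break
    improved <- FALSE
    best_gain <- 1e-12; best_pair <- NULL
    for (a in seq_along(mods)) for (b in seq_along(mods)) {
      if (a >= b) next
      # gain of merging b into a: cross terms between the two modules
      ra <- gr == mods[a]; rb <- gr == mods[b]
      ca <- gc == mods[a]; cb <- gc == mods[b]
      gain <- (sum(B[ra, cb, drop = FALSE]) +
                 sum(B[rb, ca, drop = FALSE])) / m
      if (gain > best_gain) {
        best_gain <- gain; best_pair <- c(mods[a], mods[b])
        improved <- TRUE
      }
    }
    if (!improved) break
    gr[gr == best_pair[2L]] <- best_pair[1L]
    gc[gc == best_pair[2L]] <- best_pair[1L]
  }
  q <- .barber_q(A, gr, gc)
  modules <- c(setNames(gr, rownames(A)), setNames(gc, colnames(A)))
  # relabel modules 1..K in order of first appearance
  modules <- match(modules, unique(modules))
  names(modules) <- c(rownames(A), colnames(A))
  list(Q = q, modules = modules)
}

#' NODF nestedness of a binary incidence matrix
#'
#' Nestedness metric based on overlap and decreasing fill: for every ordered
#' pair of rows (and of columns) with strictly decreasing marginal totals,
#' the paired overlap is the percentage of the smaller fill shared with the
#' larger row/column, otherwise 0; NODF is the mean paired overlap over all
#' row pairs and column pairs. Ranges 0-100 and is invariant to row/column
#' permutation.
#'
#' @param x a `bipartite_net` or a binary matrix.
#' @return NODF value in `[0, 100]`; `NA` for an empty matrix.
#' @export
nodf <- function(x) {
  A <- if (inherits(x, "bipartite_net")) incidence_matrix(x) else x
  if (length(A) == 0L) return(NA_real_)
  A <- (A > 0) * 1L
  pair_overlaps <- function(M) {
    n <- nrow(M)
    if (n < 2L) return(numeric(0))
    fill <- rowSums(M)
    out <- numeric(0)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      hi <- if (fill[i] >= fill[j]) i else j
      lo <- if (fill[i] >= fill[j]) j else i
      out <- c(out,
               if (fill[hi] > fill[lo] && fill[lo] > 0)
                 100 * sum(M[hi, ] & M[lo, ]) / fill[lo]
               else 0)
    }
    out
  }
  ov <- c(pair_overlaps(A), pair_overlaps(t(A)))
  if (length(ov) == 0L) return(NA_real_)
  mean(ov)
}

#' Node-level network metrics
#'
#' Degree, betweenness and closeness on the unweighted bipartite graph.
#' Betweenness is normalised by `(n-1)(n-2)/2` of the full vertex set;
#' closeness of a node is `(reachable - 1) / sum(distances to reachable)`,
#' 0 for orphans.
#'
#' @param net a `bipartite_net`.
#' @return data.frame with columns `node`, `side` (`host`/`imge`), `degree`,
#'   `betweenness`, `closeness`.
#' @export
node_metrics <- function(net) {
  nodes <- c(net$hosts, net$imges)
  side <- c(rep("host", length(net$hosts)), rep("imge", length(net$imges)))
  if (length(nodes) == 0L) {
    return(data.frame(node = character(0), side = character(0),
                      degree = numeric(0), betweenness = numeric(0),
                      closeness = numeric(0)))
  }
  g <- igraph::graph_from_data_frame(
    net$edges[, c("host", "imge")], directed = FALSE,
    vertices = data.frame(name = nodes))
  n <- length(nodes)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  D <- igraph::distances(g)
  clo <- apply(D, 1L, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0L) 0 else length(d) / sum(d)
  })
  data.frame(node = nodes, side = side, degree = unname(deg[nodes]),
             betweenness = unname(btw[nodes]) / norm,
             closeness = unname(clo[nodes]))
}

#' One-mode host projection of a bipartite network
#'
#' @param net a `bipartite_net`.
#' @return data.frame with columns `host1`, `host2`, `weight` (number of
#'   shared elements, only pairs with weight > 0).
#' @export
one_mode_projection <- function(net) {
  A <- incidence_matrix(net)
  empty <- data.frame(host1 = character(0), host2 = character(0),
                      weight = integer(0))
  if (nrow(A) < 2L) return(empty)
  W <- A %*% t(A)
  out <- list()
  hs <- rownames(W)
  for (i in 1:(nrow(W) - 1L)) for (j in (i + 1L):nrow(W)) {
    if (W[i, j] > 0) {
      out[[length(out) + 1L]] <- data.frame(host1 = hs[i], host2 = hs[j],
                                            weight = as.integer(W[i, j]))
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Interaction counts over time and their correlation with a focal series
#'
#' @param networks list of time-point `bipartite_net`s (names or `date`
#'   stamps give the date axis).
#' @param focal numeric series aligned to the networks (e.g. relative
#'   abundance of a focal family).
#' @return list with `counts` (named integer vector of per-date edge counts),
#'   `r` and `p` (two-sided Pearson test; `NA` when fewer than 3 overlapping
#'   dates or a constant series).
#' @export
interaction_counts_and_correlation <- function(networks, focal) {
  counts <- vapply(networks, function(nt) nrow(nt$edges), integer(1))
  if (is.null(names(counts))) {
    names(counts) <- vapply(networks, function(nt) as.character(nt$date),
                            character(1))
  }
  ok <- !is.na(focal) & !is.na(counts)
  if (sum(ok) < 3L || sd(counts[ok]) == 0 || sd(focal[ok]) == 0) {
    return(list(counts = counts, r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(counts[ok], focal[ok], method = "pearson")
  list(counts = counts, r = unname(ct$estimate), p = ct$p.value)
}
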