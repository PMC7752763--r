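mk_links <- function(...) {
  df <- data.frame(...)
  if (!"spacer" %in% names(df)) df$spacer <- paste0("s", seq_len(nrow(df)))
  df
}

test_that("global networks separate plasmid and phage interactions", {
  links <- mk_links(rmag = c("H", "H", "G"),
                    imge = c("P1", "F1", "P1"),
                    label = c("plasmid", "phage", "plasmid"),
                    spacer = c("s1", "s1", "s2"))
  pl <- build_global_network(links, "plasmid")
  ph <- build_global_network(links, "phage")
  expect_equal(nrow(pl$edges), 2L)
  expect_equal(nrow(ph$edges), 1L)
  # one spacer targeting a plasmid and a phage contributes to both networks
  expect_true("P1" %in% pl$edges$imge && "F1" %in% ph$edges$imge)
  empty <- build_global_network(links[0, ], "plasmid")
  expect_equal(nrow(empty$edges), 0L)
  expect_length(empty$hosts, 0L)
})

test_that("time-point networks keep co-present edges and orphan nodes", {
  links <- mk_links(rmag = c("H", "G"), imge = c("P1", "P2"),
                    label = "plasmid", spacer = c("s1", "s2"))
  net <- build_global_network(links, "plasmid")
  dates <- c("2011-05-01", "2011-05-09")
  hp <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2,
               dimnames = list(c("H", "G"), dates))
  ip <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2,
               dimnames = list(c("P1", "P2"), dates))
  t1 <- time_point_network(net, hp, ip, dates[1])
  expect_equal(nrow(t1$edges), 1L)              # H-P1 retained
  expect_setequal(t1$hosts, c("H", "G"))        # G kept as orphan
  expect_equal(t1$imges, "P1")
  t2 <- time_point_network(net, hp, ip, dates[2])
  expect_equal(nrow(t2$edges), 0L)
  expect_equal(t2$hosts, "H")                   # orphan host
  expect_error(time_point_network(net, hp, ip, "1999-01-01"),
               "not on the sample axis")
  # edges of every time-point network are a subset of the global edges
  for (tp in list(t1, t2)) {
    expect_true(all(paste(tp$edges$host, tp$edges$imge) %in%
                      paste(net$edges$host, net$edges$imge)))
  }
})

test_that("Barber modularity matches exhaustive values on known graphs", {
  # two disjoint complete 2x2 blocks: Q = 0.5
  A <- matrix(0, 4, 4, dimnames = list(paste0("h", 1:4), paste0("p", 1:4)))
  A[1:2, 1:2] <- 1; A[3:4, 3:4] <- 1
  expect_equal(barber_modularity(A, seed = 1)$Q, 0.5, tolerance = 1e-12)
  # a single complete 2x2 block: no partition beats one module, Q = 0
  B <- matrix(1, 2, 2, dimnames = list(c("h1", "h2"), c("p1", "p2")))
  expect_equal(barber_modularity(B, seed = 1)$Q, 0, tolerance = 1e-12)
  # heuristic equals brute force on small random graphs
  set.seed(14)
  for (i in 1:5) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    repeat {
      M <- matrix(rbinom(nr * nc, 1, 0.5), nr, nc)
      if (sum(M) > 0) break
    }
    dimnames(M) <- list(paste0("h", 1:nr), paste0("p", 1:nc))
    expect_equal(barber_modularity(M, seed = i)$Q, oracle_barber_q(M),
                 tolerance = 1e-9)
  }
  expect_true(is.na(barber_modularity(matrix(0, 2, 2))$Q))
})

test_that("NODF follows the overlap and decreasing-fill definition", {
  tri <- matrix(c(1, 1, 1,
                  1, 1, 0,
                  1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nodf(tri), 100)
  expect_equal(nodf(diag(2)), 0)     # equal fills never count
  one_row <- matrix(c(1, 1, 0), 1, 3)
  expect_equal(nodf(one_row), 0)     # only column pairs contribute
  # permutation invariance
  set.seed(15)
  M <- matrix(rbinom(30, 1, 0.5), 5, 6)
  expect_equal(nodf(M), nodf(M[sample(5), sample(6)]))
  # agreement with the community-ecology reference implementation
  skip_if_not_installed("vegan")
  for (i in 1:5) {
    M <- matrix(rbinom(42, 1, 0.4), 6, 7)
    if (sum(M) == 0) next
    ref <- unname(vegan::nestednodf(M)$statistic["NODF"])
    expect_equal(nodf(M), ref, tolerance = 1e-9)
  }
})

test_that("node metrics cover degree, betweenness and closeness", {
  links <- mk_links(rmag = c("H1", "H1", "H1", "H2"),
                    imge = c("P1", "P2", "P3", "P1"),
                    label = "plasmid", spacer = paste0("s", 1:4))
  net <- build_global_network(links, "plasmid")
  met <- node_metrics(net)
  expect_equal(met$degree[met$node == "H1"], 3)
  # path H1 - P1 - H2: P1 lies on shortest paths between the other nodes
  expect_gt(met$betweenness[met$node == "P1"],
            met$betweenness[met$node == "P3"])
  # orphan: present node without partners
  net$hosts <- c(net$hosts, "H9")
  met2 <- node_metrics(net)
  expect_equal(met2$degree[met2$node == "H9"], 0)
  expect_equal(met2$closeness[met2$node == "H9"], 0)
})

test_that("the one-mode projection counts shared elements", {
  links <- mk_links(rmag = c("H1", "H2", "H1", "H2", "H1", "H2", "H3"),
                    imge = c("P1", "P1", "P2", "P2", "P3", "P3", "P9"),
                    label = "plasmid", spacer = paste0("s", 1:7))
  net <- build_global_network(links, "plasmid")
  pr <- one_mode_projection(net)
  expect_equal(pr$weight[pr$host1 == "H1" & pr$host2 == "H2"], 3L)
  expect_false(any(pr$host1 == "H3" | pr$host2 == "H3"))
})

test_that("interaction counts correlate exactly on (anti)proportional series", {
  mk_net <- function(k) {
    links <- mk_links(rmag = paste0("H", seq_len(k)),
                      imge = paste0("P", seq_len(k)), label = "plasmid",
                      spacer = paste0("s", seq_len(k)))
    build_global_network(links, "plasmid")
  }
  nets <- lapply(c(1, 2, 3, 5, 4), mk_net)
  counts <- vapply(nets, function(x) nrow(x$edges), integer(1))
  expect_equal(interaction_counts_and_correlation(nets, counts)$r, 1)
  expect_equal(interaction_counts_and_correlation(nets, -counts + 10)$r, -1)
  expect_true(is.na(interaction_counts_and_correlation(nets[1:2],
                                                       counts[1:2])$r))
})
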