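set.seed(55)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

test_that("the consolidation truth table is exhaustive and exclusive", {
  combos <- expand.grid(plasmid_cbar = c(FALSE, TRUE),
                        plasmid_plasflow = c(FALSE, TRUE),
                        phage_virsorter = c(FALSE, TRUE),
                        phage_virfinder = c(FALSE, TRUE),
                        is_pscc = c(FALSE, TRUE))
  combos$contig <- paste0("c", seq_len(nrow(combos)))
  lab <- consolidate_imge_labels(combos,
                                 combos$contig[combos$is_pscc])
  # independently coded expectation
  pl <- combos$plasmid_cbar | combos$plasmid_plasflow
  ph <- combos$phage_virsorter | combos$phage_virfinder
  want <- rep("none", nrow(combos))
  want[combos$is_pscc & !pl & !ph] <- "unclassified"
  want[pl & !ph] <- "plasmid"
  want[!pl & ph] <- "phage"
  want[pl & ph] <- "ambiguous"
  expect_equal(lab$label, want)
  # exactly one label per contig
  expect_equal(nrow(lab), 32L)
  expect_true(all(lab$label %in% c("plasmid", "phage", "ambiguous",
                                   "unclassified", "none")))
})

test_that("element clustering keeps the representative's label", {
  a <- rand_dna(500)
  b <- substr(a, 1, 480)  # shorter near-copy absorbed by a
  substr(b, 100, 100) <- "A"
  far <- rand_dna(500)
  seqs <- c(pl1 = a, amb1 = b, ph1 = far)
  labels <- data.frame(contig = c("pl1", "amb1", "ph1"),
                       label = c("plasmid", "ambiguous", "phage"))
  rec <- cluster_imges(seqs, labels)
  expect_equal(nrow(rec), 2L)
  merged <- rec[rec$n_members == 2L, ]
  expect_equal(merged$representative_contig, "pl1")
  expect_equal(merged$label, "plasmid")  # representative's annotation wins
  expect_equal(rec$label[rec$representative_contig == "ph1"], "phage")
})

test_that("clustering never merges sequences below 80% identity", {
  d <- small_sim(seed = 61)
  r <- run_pipeline(d, stages = c("cluster", "protospacer", "classify"),
                    seed = 2)
  rec <- r$imge_records[r$imge_records$n_members > 1, ]
  for (i in seq_len(nrow(rec))) {
    members <- strsplit(rec$member_contigs[i], ",")[[1]]
    rep_seq <- d$contigs[[rec$representative_contig[i]]]
    for (m in setdiff(members, rec$representative_contig[i])) {
      a <- local_align(d$contigs[[m]], rep_seq)
      expect_gte(a$identity, 0.80)
    }
  }
})

test_that("the synthetic community carries the configured 16:1 composition", {
  cfg <- simulation_config(n_timepoints = 5, n_hosts = 2, n_extra_mags = 0,
                           n_families = 2, n_imges = 170,
                           n_spacers_per_host = 2, n_twin_plasmids = 0,
                           n_mt_only = 0, n_background = 0, n_slack = 2,
                           seed = 3)
  d <- simulate_community(cfg)
  truth <- table(d$ground_truth$imges$label)
  expect_equal(unname(truth[["plasmid"]]), 160L)
  expect_equal(unname(truth[["phage"]]), 10L)
  # with error-free predictors, consolidation reproduces the truth exactly
  lab <- consolidate_imge_labels(d$flags)
  lab <- lab[match(d$ground_truth$imges$contig, lab$contig), ]
  expect_equal(lab$label, d$ground_truth$imges$label)
})

test_that("MT-only elements are flagged from the depth tables", {
  rec <- data.frame(imge = c("i1", "i2"),
                    representative_contig = c("c1", "c2"),
                    label = "plasmid", is_pscc = TRUE, n_members = 1L,
                    member_contigs = c("c1", "c2"))
  mg <- matrix(c(0, 0, 0, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("c1", "c2"), c("t1", "t2")))
  mt <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("c1", "c2"), c("t1", "t2")))
  out <- flag_mt_only(rec, mg, mt)
  expect_equal(out$mt_only, c(TRUE, FALSE))
})
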