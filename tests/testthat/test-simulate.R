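test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_timepoints = 0), "n_timepoints")
  expect_error(simulation_config(plasmid_phage_ratio = 0),
               "plasmid_phage_ratio")
  expect_error(simulation_config(predictor_error_rate = 1.2),
               "predictor_error_rate")
  expect_error(simulation_config(n_timepoints = 10,
                                 shift_window = c(5, 12)), "shift_window")
})

test_that("simulation is deterministic and fixtures are byte-identical", {
  d1 <- small_sim(seed = 91)
  d2 <- small_sim(seed = 91)
  expect_identical(d1$contigs, d2$contigs)
  expect_identical(d1$depth_mg, d2$depth_mg)
  expect_identical(d1$elements, d2$elements)
  expect_identical(d1$ground_truth$links, d2$ground_truth$links)

  t1 <- file.path(tempdir(), "fix_a"); t2 <- file.path(tempdir(), "fix_b")
  m1 <- write_fixtures(d1, t1)
  m2 <- write_fixtures(d2, t2)
  expect_identical(m1$files, m2$files)  # md5-identical output files
  unlink(c(t1, t2), recursive = TRUE)
})

test_that("planted sequences satisfy the dataset invariants", {
  d <- small_sim(seed = 92)
  gt <- d$ground_truth
  host_seq <- paste(d$contigs[gt$host_contigs], collapse = "NNNN")
  for (i in seq_len(nrow(gt$spacers))) {
    sp <- gt$spacers$sequence[i]
    n_occ <- length(gregexpr(sp, host_seq, fixed = TRUE)[[1]])
    expect_equal(n_occ, 1L)  # verbatim in exactly one CRISPR array
  }
  for (i in seq_len(nrow(gt$links))) {
    sp <- gt$spacers$sequence[gt$spacers$spacer_id == gt$links$spacer_id[i]]
    ct <- d$contigs[[paste0(gt$links$imge_id[i], "_ct")]]
    emb <- if (gt$links$strand[i] == "+") sp else rev_comp(sp)
    expect_equal(substr(ct, gt$links$start[i] + 1,
                        gt$links$start[i] + nchar(sp)), emb)
  }
  expect_true(all(diff(d$dates) >= 1))  # strictly increasing dates
})

test_that("error-free predictor flags equal the planted labels", {
  d <- small_sim(seed = 93, predictor_error_rate = 0)
  lab <- consolidate_imge_labels(d$flags)
  gt <- d$ground_truth$imges
  lab <- lab[match(gt$contig, lab$contig), ]
  expect_equal(lab$label, gt$label)
  # host and background contigs carry no predictor signal
  others <- setdiff(d$flags$contig,
                    c(gt$contig, d$ground_truth$twins$twin_contig))
  fl <- d$flags[d$flags$contig %in% others, -1]
  expect_false(any(unlist(fl)))
})

test_that("fixtures round-trip through write and read", {
  d <- small_sim(seed = 94)
  dir <- file.path(tempdir(), "fix_rt")
  manifest <- write_fixtures(d, dir)
  expect_equal(manifest$n_timepoints, length(d$dates))
  expect_equal(sum(grepl("^contigs_.*fasta$", names(manifest$files))),
               length(d$dates))  # one FASTA per time point
  r <- read_fixtures(dir)
  expect_identical(r$contigs, d$contigs)
  expect_equal(r$elements, d$elements)
  expect_equal(r$depth_mg, d$depth_mg)
  expect_equal(r$depth_mt, d$depth_mt)
  expect_equal(r$contig2mag, d$contig2mag)
  expect_equal(r$mag2rmag, d$mag2rmag)
  expect_equal(r$flags, d$flags)
  expect_identical(r$dates, d$dates)
  expect_equal(r$ground_truth$links, d$ground_truth$links)
  unlink(dir, recursive = TRUE)
})

test_that("a degenerate zero-host community still writes valid fixtures", {
  cfg <- simulation_config(n_timepoints = 4, n_hosts = 0, n_imges = 0,
                           n_background = 2, n_twin_plasmids = 0,
                           n_mt_only = 0, n_slack = 0, seed = 5)
  d <- simulate_community(cfg)
  expect_equal(nrow(d$ground_truth$spacers), 0L)
  dir <- file.path(tempdir(), "fix_empty")
  m <- write_fixtures(d, dir)
  expect_true("elements.tsv" %in% names(m$files))
  r <- read_fixtures(dir)
  expect_equal(nrow(r$elements), 0L)
  unlink(dir, recursive = TRUE)
})
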