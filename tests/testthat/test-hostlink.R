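set.seed(21)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
mutate_k <- function(s, pos) {
  for (p in pos) {
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1)
  }
  s
}
as_clusters <- function(seqs, kind) {
  greedy_cluster(seqs, 0.99, "both_min", 0.975, element_kind = kind)
}

test_that("flank matching applies the length-dependent coverage branches", {
  flank_long <- rand_dna(150)
  # contig carries only 128/150 of the long flank (coverage ~0.85) with 5
  # interior substitutions (identity ~0.96): retained under the >=100 nt rule
  emb_long <- mutate_k(substr(flank_long, 1, 128), c(20, 45, 70, 95, 120))
  flank_short <- rand_dna(80)
  # only 60/80 of the short flank embedded (coverage 0.75 < 0.95): rejected
  emb_short <- substr(flank_short, 1, 60)
  flank_exact <- rand_dna(150)

  contigs <- c(c1 = paste0(rand_dna(100), emb_long, rand_dna(100)),
               c2 = paste0(rand_dna(100), emb_short, rand_dna(100)),
               c3 = paste0(rand_dna(50), flank_exact, rand_dna(50)))
  c2m <- data.frame(contig = c("c1", "c2", "c3"),
                    mag = c("m1", "m2", "m3"))
  fc <- as_clusters(c(f1 = flank_long, f2 = flank_short, f3 = flank_exact),
                    "flank")
  cand <- match_flanks_to_mags(fc, contigs, c2m)
  reps <- cluster_representatives(fc)
  cl_of <- function(seq) names(reps)[reps == seq]

  long_rows <- cand[cand$flank_cluster == cl_of(flank_long), ]
  expect_true("m1" %in% long_rows$mag)
  expect_false(cl_of(flank_short) %in% cand$flank_cluster)
  exact_rows <- cand[cand$flank_cluster == cl_of(flank_exact), ]
  expect_equal(exact_rows$mag, "m3")
  expect_equal(exact_rows$identity, 1)
  expect_equal(exact_rows$flank_coverage, 1)
})

test_that("repeat confirmation enforces 75% identity and 80% coverage", {
  flank <- rand_dna(150)
  rpt <- rand_dna(32)
  ok_emb <- mutate_k(rpt, c(6, 12, 18, 24, 30, 3))   # 26/32 ~ 0.81 identity
  contig_ok <- paste0(rand_dna(60), flank, ok_emb, rand_dna(60))
  contig_bad <- paste0(rand_dna(60), flank,
                       mutate_k(rpt, seq(2, 30, by = 2)), rand_dna(60))
  contigs <- c(g = contig_ok, b = contig_bad)
  c2m <- data.frame(contig = c("g", "b"), mag = c("mg", "mb"))
  fc <- as_clusters(c(f = flank), "flank")
  rc <- greedy_cluster(c(r = rpt), 0.80, "shorter_min", 0.75,
                       element_kind = "repeat")
  locus_map <- data.frame(flank_cluster = fc[[1]]$cluster_id,
                          repeat_cluster = rc[[1]]$cluster_id,
                          spacer_cluster = NA_character_)
  cand <- match_flanks_to_mags(fc, contigs, c2m)
  expect_setequal(cand$mag, c("mg", "mb"))
  links <- confirm_with_repeats(cand, rc, locus_map, contigs, c2m)
  expect_equal(links$mag, "mg")
  expect_gte(links$repeat_identity, 0.75)
  expect_gte(links$repeat_coverage, 0.80)

  # an exactly embedded repeat confirms at identity 1
  contig_id <- paste0(rand_dna(40), flank, rpt, rand_dna(40))
  cand2 <- match_flanks_to_mags(fc, c(x = contig_id),
                                data.frame(contig = "x", mag = "mx"))
  links2 <- confirm_with_repeats(cand2, rc, locus_map, c(x = contig_id),
                                 data.frame(contig = "x", mag = "mx"))
  expect_equal(links2$repeat_identity, 1)

  # candidate with no associated repeat is dropped with a warning
  lm_empty <- data.frame(flank_cluster = "other", repeat_cluster = "r",
                         spacer_cluster = NA_character_)
  expect_warning(
    out <- confirm_with_repeats(cand2, rc, lm_empty, c(x = contig_id),
                                data.frame(contig = "x", mag = "mx")),
    "no associated repeat")
  expect_equal(nrow(out), 0L)
})

test_that("spacer assignment propagates loci to MAGs and rMAGs", {
  links <- data.frame(flank_cluster = c("fA", "fB"), mag = c("m1", "m2"))
  locus_map <- data.frame(
    flank_cluster = c(rep("fA", 10), rep("fB", 3)),
    spacer_cluster = c(paste0("s", 1:10), paste0("t", 1:3)))
  m2r <- data.frame(mag = c("m1", "m2"), rmag = c("R", "R"))
  tab <- assign_spacers(links, locus_map, m2r)
  expect_equal(sum(tab$mag == "m1"), 10L)           # cardinality
  expect_setequal(tab$spacer_cluster[tab$rmag == "R"],
                  c(paste0("s", 1:10), paste0("t", 1:3)))  # rMAG union

  expect_error(assign_spacers(links, locus_map,
                              data.frame(mag = "m1", rmag = "R")),
               "missing from the rMAG map")
})

test_that("no confirmed link falls below the linking thresholds and the
          synthetic assignment matches the planted truth", {
  d <- small_sim(seed = 31)
  r <- run_pipeline(d, stages = c("cluster", "link"), seed = 2)
  expect_true(all(r$host_links$identity >= 0.95))
  expect_true(all(r$host_links$repeat_identity >= 0.75))
  expect_true(all(r$host_links$repeat_coverage >= 0.80))

  mem <- cluster_membership(r$spacer_clusters)
  mem$planted <- sub("_var$", "", mem$member_id)
  sp_map <- tapply(mem$planted, mem$cluster_id, function(x) x[1])
  got <- unique(paste(sp_map[r$assignment$spacer_cluster],
                      r$assignment$rmag))
  truth <- unique(paste(d$ground_truth$spacers$spacer_id,
                        d$ground_truth$spacers$rmag))
  expect_setequal(got, truth)  # precision and recall both 1
})
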