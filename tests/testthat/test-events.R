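# presence matrices for one spacer/element pair over an index axis
pair_presence <- function(s_win, i_win, n = 10) {
  dates <- as.Date("2011-01-01") + (seq_len(n) - 1) * 7
  sp <- matrix(seq_len(n) >= s_win[1] & seq_len(n) <= s_win[2], 1, n,
               dimnames = list("s", as.character(dates)))
  im <- matrix(seq_len(n) >= i_win[1] & seq_len(n) <= i_win[2], 1, n,
               dimnames = list("i", as.character(dates)))
  list(sp = sp, im = im, dates = dates)
}
one_link <- data.frame(spacer = "s", imge = "i", label = "plasmid")

test_that("the six event categories follow the printed first/last rules", {
  cases <- list(
    list(s = c(4, 9), i = c(2, 6), first = "gain", last = "loss"),
    list(s = c(3, 7), i = c(3, 7), first = "probable_gain",
         last = "probable_loss"),
    list(s = c(2, 5), i = c(5, 8), first = "probable_secondary_encounter",
         last = "spacer_loss_before_imge_loss"))
  for (cs in cases) {
    pp <- pair_presence(cs$s, cs$i)
    ev <- classify_events(one_link, pp$sp, pp$im, pp$dates)
    expect_equal(nrow(ev), 2L)
    expect_equal(ev$category[ev$comparison == "first"], cs$first)
    expect_equal(ev$category[ev$comparison == "last"], cs$last)
  }
})

test_that("category assignment is a pure function of the four dates", {
  n <- 6
  for (fs in 1:4) for (fi in 1:4) for (ls in 4:n) for (li in 4:n) {
    if (fs > ls || fi > li) next
    pp <- pair_presence(c(fs, ls), c(fi, li), n)
    ev <- classify_events(one_link, pp$sp, pp$im, pp$dates)
    first <- ev[ev$comparison == "first", ]
    last <- ev[ev$comparison == "last", ]
    expect_equal(first$category,
                 if (fs > fi) "gain" else if (fs == fi) "probable_gain"
                 else "probable_secondary_encounter")
    expect_equal(last$category,
                 if (ls > li) "loss" else if (ls == li) "probable_loss"
                 else "spacer_loss_before_imge_loss")
    expect_equal(first$lag_weeks, as.numeric(pp$dates[fs] - pp$dates[fi]) / 7)
    expect_gte(if (first$category == "gain") first$lag_weeks else 1, 0)
  }
})

test_that("pairs never present are skipped with a message", {
  pp <- pair_presence(c(2, 4), c(3, 5))
  pp$sp[] <- FALSE
  expect_message(ev <- classify_events(one_link, pp$sp, pp$im, pp$dates),
                 "never present")
  expect_equal(nrow(ev), 0L)
})

test_that("active-spacer filtering enforces all three retention conditions", {
  dates <- as.character(as.Date("2011-01-01") + 0:3 * 7)
  spp <- matrix(c(FALSE, FALSE, TRUE, FALSE,   # s1 present t3
                  TRUE, FALSE, FALSE, FALSE,   # s2 present t1 only
                  FALSE, TRUE, FALSE, FALSE),  # s3 present t2
                3, 4, byrow = TRUE, dimnames = list(c("s1", "s2", "s3"),
                                                    dates))
  rmp <- matrix(c(FALSE, FALSE, TRUE, TRUE,    # r1 present t3, t4
                  FALSE, TRUE, TRUE, FALSE),   # r2
                2, 4, byrow = TRUE, dimnames = list(c("r1", "r2"), dates))
  assign <- data.frame(spacer_cluster = c("s1", "s2", "s3"),
                       rmag = c("r1", "r1", "r2"))
  links <- data.frame(spacer = c("s1", "s2"))
  out <- filter_active_spacers(assign, spp, rmp, links)
  # s1: co-occurs at t3 and targets an element -> kept
  # s2: never co-present with r1 -> dropped; s3: no target -> dropped
  expect_equal(out$spacer_cluster, "s1")
})

test_that("lag statistics use fractional weeks and the n-1 denominator", {
  ev <- data.frame(category = "gain", label = c("plasmid", "plasmid",
                                                "phage"),
                   lag_weeks = c(7, 21, 14) / 7)
  st <- lag_statistics(ev, "gain")
  ov <- st[st$group == "overall", ]
  expect_equal(ov$mean_weeks, 2)
  expect_equal(ov$median_weeks, 2)
  expect_equal(ov$sd_weeks, 1)

  one <- lag_statistics(data.frame(category = "gain", label = "plasmid",
                                   lag_weeks = 2), "gain")
  expect_equal(one$mean_weeks[one$group == "overall"], 2)
  expect_true(is.na(one$sd_weeks[one$group == "overall"]))
  expect_true(is.na(one$mean_weeks[one$group == "phage"]))

  none <- lag_statistics(ev[0, ], "gain")
  expect_true(all(is.na(none$mean_weeks)))

  # probable gains (lag 0) enter only on request
  ev2 <- rbind(ev, data.frame(category = "probable_gain", label = "phage",
                              lag_weeks = 0))
  expect_equal(lag_statistics(ev2, "gain")$n[1], 3L)
  expect_equal(lag_statistics(ev2, "gain", include_probable = TRUE)$n[1], 4L)
})

test_that("the gain/loss timeline finds the planted crossover", {
  dates <- as.Date("2011-01-01") + 0:9 * 7
  ev <- data.frame(
    category = c(rep("gain", 5), rep("loss", 4)),
    spacer_date = dates[c(1, 2, 3, 4, 5, 6, 7, 8, 9)])
  tl <- gain_loss_timeline(ev, dates)
  expect_equal(tl$crossover, dates[5])
  expect_equal(sum(tl$timeline$gains), 5L)
  expect_equal(sum(tl$timeline$losses), 4L)

  all_gain <- gain_loss_timeline(ev[ev$category == "gain", ], dates)
  expect_true(is.na(all_gain$crossover))

  none <- gain_loss_timeline(ev[0, ], dates)
  expect_true(all(none$timeline$gains == 0L))
  expect_true(is.na(none$crossover))
})
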