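test_that("primer assignment respects the mismatch budget", {
  panel <- tiny_panel()
  loc <- panel[[1]]
  read <- amplicon_seq(loc)
  exact <- trim_and_assign(read, panel, 0)
  expect_identical(exact$locus_id, loc$locus_id)
  expect_identical(exact$insert,
                   substring(read, nchar(loc$fwd_primer) + 1))

  mm <- read
  substr(mm, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mm, 3, 3))[1]
  expect_identical(trim_and_assign(mm, panel, 1)$locus_id, loc$locus_id)
  expect_true(is.na(trim_and_assign(mm, panel, 0)$locus_id))
  expect_identical(trim_and_assign(mm, panel, 0)$reason, "no_match")
  expect_identical(trim_and_assign("", panel, 2)$reason, "empty")

  # duplicate primers are a panel defect caught at load time
  p2 <- panel
  p2[[2]]$fwd_primer <- p2[[1]]$fwd_primer
  expect_error(trim_and_assign(read, p2, 2), "duplicate")

  # near-duplicate primers make reads ambiguous within a generous budget
  p3 <- panel
  near <- p3[[1]]$fwd_primer
  substr(near, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(near, 1, 1))[1]
  p3[[2]]$fwd_primer <- near
  amb <- trim_and_assign(read, p3, 2)
  expect_true(is.na(amb$locus_id))
  expect_identical(amb$reason, "ambiguous")
})

test_that("assignment of simulated reads matches the simulator truth", {
  panel <- demo_panel()
  truth_locus <- character(0)
  reads <- character(0)
  for (lid in names(panel)) {
    spec <- sample_spec("s", "tumor", depth = 850,
                        subst_error_rate = 0.001,
                        seed = derive_test_seed(77, lid))
    sim <- simulate_reads(panel[[lid]], spec)
    reads <- c(reads, sim$reads)
    truth_locus <- c(truth_locus, rep(lid, length(sim$reads)))
  }
  asg <- trim_and_assign(reads, panel, 2)
  # every assigned read goes to its true locus; (rare) unassigned reads are
  # only those whose primer drew 3+ errors
  assigned <- !is.na(asg$locus_id)
  expect_gt(mean(assigned), 0.999)
  expect_identical(asg$locus_id[assigned], truth_locus[assigned])
})

test_that("repeat-length extraction recovers planted and slipped lengths", {
  panel <- tiny_panel()
  loc <- panel[[1]]   # A x 20
  insert_for <- function(n) substring(amplicon_seq(loc, n),
                                      nchar(loc$fwd_primer) + 1)
  one_less <- extract_repeat_count(insert_for(19), loc)
  expect_true(one_less$usable)
  expect_identical(one_less$observed_repeat_count, 19L)

  wt <- extract_repeat_count(insert_for(loc$wt_repeat_count), loc)
  expect_identical(wt$observed_repeat_count, loc$wt_repeat_count)

  # an interrupted tract is unusable, never an error
  broken <- insert_for(20)
  mid <- nchar(loc$left_flank) + 10
  substr(broken, mid, mid) <- "C"
  expect_false(extract_repeat_count(broken, loc)$usable)
  expect_false(extract_repeat_count("GGGG", loc)$usable)

  # extraction equals the simulator's slip distribution exactly when
  # substitution errors are off
  spec <- sample_spec("s", "tumor", depth = 10000, stutter_rate = 0.05,
                      stutter_decay = 0.4, subst_error_rate = 0, seed = 21)
  sim <- simulate_reads(loc, spec)
  ex <- extract_repeat_count(substring(sim$reads, nchar(loc$fwd_primer) + 1),
                             loc)
  expect_true(all(ex$usable))
  expect_identical(ex$observed_repeat_count, as.integer(sim$counts))
})

test_that("anchors with mismatches are honoured when budgeted", {
  panel <- tiny_panel()
  loc <- panel[[1]]
  insert <- substring(amplicon_seq(loc, 19), nchar(loc$fwd_primer) + 1)
  pos <- nchar(loc$left_flank) - 2   # inside the left anchor
  substr(insert, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(insert, pos, pos))[1]
  expect_false(extract_repeat_count(insert, loc, 6, 0)$usable)
  with_budget <- extract_repeat_count(insert, loc, 6, 1)
  expect_true(with_budget$usable)
  expect_identical(with_budget$observed_repeat_count, 19L)
  expect_error(extract_repeat_count(insert, loc, 3), ">= 4")
})

test_that("tabulation computes VAFs, zero-fills offsets, and conserves reads", {
  panel <- tiny_panel()
  obs <- rbind(
    data.frame(sample_id = "t1", locus_id = "locA",
               observed_repeat_count = c(rep(20L, 980), rep(19L, 20)),
               usable = TRUE),
    data.frame(sample_id = "wt1", locus_id = "locA",
               observed_repeat_count = rep(20L, 500), usable = TRUE))
  tab <- tabulate_indels(obs, panel)
  t1 <- tab[tab$sample_id == "t1" & tab$offset == -1, ]
  expect_equal(t1$vaf, 20 / 1000)
  expect_identical(t1$mutant_reads, 20L)
  expect_identical(t1$total_usable, 1000L)
  # zero-fill: wt1 never showed offset -1 but gets an explicit 0-VAF row
  w1 <- tab[tab$sample_id == "wt1" & tab$offset == -1, ]
  expect_identical(nrow(w1), 1L)
  expect_equal(w1$vaf, 0)
  expect_identical(w1$total_usable, 500L)

  # unusable-only sample excluded with a warning
  obs2 <- rbind(obs, data.frame(sample_id = "t2", locus_id = "locA",
                                observed_repeat_count = NA_integer_,
                                usable = FALSE))
  expect_warning(tab2 <- tabulate_indels(obs2, panel), "no usable")
  expect_false("t2" %in% tab2$sample_id)
})

test_that("cohort tabulation matches a brute-force recount of the truth", {
  panel <- tiny_panel()
  cohort <- make_cohort_specs(panel, seed = 5, n_controls = 2, n_tumors = 3,
                              n_planted = 2, planted_loci = "locA",
                              vaf = 0.3, depth = 400)
  sim <- simulate_cohort(panel, cohort$specs, level = "counts")
  tab <- tabulate_indels(sim$observations, panel)
  # recount from raw observations, independently of tabulate_indels
  for (i in sample(nrow(tab), 25)) {
    row <- tab[i, ]
    wt_n <- panel[[row$locus_id]]$wt_repeat_count
    sub <- sim$observations[sim$observations$sample_id == row$sample_id &
                              sim$observations$locus_id == row$locus_id, ]
    mut <- sum(sub$observed_repeat_count == wt_n + row$offset)
    wtr <- sum(sub$observed_repeat_count == wt_n)
    expect_identical(row$mutant_reads, mut)
    expect_identical(row$wt_reads, wtr)
    expect_identical(row$total_usable, nrow(sub))
    expect_equal(row$vaf, mut / (mut + wtr))
  }
  # conservation: per (sample, locus) the total equals the usable read count
  expect_true(all(tab$mutant_reads <= tab$total_usable))
  expect_true(all(tab$vaf >= 0 & tab$vaf <= 1, na.rm = TRUE))
})
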