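test_that("read classification follows the truth-comparison rules", {
  truth <- make_truth("e1", "endogenous", "c1", 100L, 35L, "+")
  obs <- make_obs("e1", TRUE, "c1", 100L, "+", 37L)
  expect_identical(classify_reads(obs, truth), "ENDO_CORRECT")

  # contig mismatch
  obs2 <- make_obs("e1", TRUE, "c2", 100L, "+", 37L)
  expect_identical(classify_reads(obs2, truth), "ENDO_INCORRECT")

  # strand mismatch
  obs3 <- make_obs("e1", TRUE, "c1", 100L, "-", 37L)
  expect_identical(classify_reads(obs3, truth), "ENDO_INCORRECT")

  # position off by one: incorrect at tolerance 0, correct at tolerance 1
  obs4 <- make_obs("e1", TRUE, "c1", 101L, "+", 37L)
  expect_identical(classify_reads(obs4, truth), "ENDO_INCORRECT")
  expect_identical(classify_reads(obs4, truth, tolerance = 1L), "ENDO_CORRECT")

  expect_identical(classify_reads(make_obs("e1", FALSE), truth),
                   "ENDO_UNMAPPED")

  # a contaminant is a false positive wherever it maps
  ctruth <- make_truth("x1", "contaminant", "c9", 5L, 40L, "-")
  expect_identical(classify_reads(make_obs("x1", TRUE, "c1", 0L, "+", 60L),
                                  ctruth), "CONT_MAPPED")
  expect_identical(classify_reads(make_obs("x1", FALSE), ctruth),
                   "CONT_UNMAPPED")

  expect_error(classify_reads(make_obs("other", TRUE, "c1", 0L, "+", 1L),
                              truth), "same read ids")
})

# hand-countable run: 8 endogenous (5 correct, 1 incorrect, 2 unmapped)
# and 4 contaminants (1 mapped) -> sensitivity 5/8, specificity 3/4,
# FPR 1/7
toy_run <- function(mapq = 60L) {
  truth <- rbind(
    make_truth(sprintf("e%d", 1:8), "endogenous", "c1",
               start = seq(0L, 700L, by = 100L), length = 35L),
    make_truth(sprintf("x%d", 1:4), "contaminant", "c1", start = 0L,
               length = 35L)
  )
  obs <- rbind(
    make_obs(sprintf("e%d", 1:5), TRUE, "c1",
             leftmost_pos = seq(0L, 400L, by = 100L), strand = "+",
             mapq = mapq),
    make_obs("e6", TRUE, "c1", 9999L, "+", mapq),
    make_obs(c("e7", "e8"), FALSE),
    make_obs("x1", TRUE, "c1", 50L, "-", mapq),
    make_obs(sprintf("x%d", 2:4), FALSE)
  )
  list(truth = truth, obs = obs)
}

test_that("evaluate_run reproduces the metric definitions on a toy run", {
  tr <- toy_run()
  m <- evaluate_run(tr$obs, tr$truth, mapq_threshold = 30L)
  unf <- m[m$mapq_filter == "none", ]
  expect_equal(unf$sensitivity, 0.625)
  expect_equal(unf$specificity, 0.75)
  expect_equal(unf$fpr, 1 / 7)
  expect_identical(unf$endo_correct, 5L)
  expect_identical(unf$endo_incorrect, 1L)
  expect_identical(unf$endo_unmapped, 2L)
  expect_identical(unf$cont_mapped, 1L)
  expect_identical(unf$cont_unmapped, 3L)
  expect_identical(unf$total_mapped, 7L)
  # integer identity: fpr * total_mapped = contaminants mapped
  expect_equal(unf$fpr * unf$total_mapped, unf$cont_mapped)
})

test_that("degenerate runs report sensitivity 0, specificity 1, FPR NA", {
  truth <- rbind(make_truth(c("e1", "e2"), "endogenous"),
                 make_truth("x1", "contaminant"))
  obs <- make_obs(c("e1", "e2", "x1"), FALSE)
  m <- evaluate_run(obs, truth)
  expect_equal(m$sensitivity, c(0, 0))
  expect_equal(m$specificity, c(1, 1))
  expect_true(all(is.na(m$fpr)))
  expect_identical(m$total_mapped, c(0L, 0L))
})

test_that("the MapQ filter treats low-quality mapped reads as unmapped", {
  truth <- make_truth("e1", "endogenous", "c1", 10L, 35L, "+")
  obs <- make_obs("e1", TRUE, "c1", 10L, "+", mapq = 10L)
  m <- evaluate_run(obs, truth, mapq_threshold = 30L)
  expect_equal(m$sensitivity[m$mapq_filter == "none"], 1)
  expect_equal(m$sensitivity[m$mapq_filter == ">=30"], 0)
  # boundary: mapq >= threshold is kept
  obs30 <- make_obs("e1", TRUE, "c1", 10L, "+", mapq = 30L)
  m30 <- evaluate_run(obs30, truth, mapq_threshold = 30L)
  expect_equal(m30$sensitivity, c(1, 1))
})

test_that("class counts are conserved across randomized runs", {
  set.seed(2024)
  for (rep in 1:1000) {
    n_e <- sample(0:30, 1)
    n_c <- sample(0:30, 1)
    if (n_e + n_c == 0) next
    truth <- rbind(
      if (n_e > 0) make_truth(sprintf("e%d", seq_len(n_e)), "endogenous",
                              start = sample(0:50, n_e, TRUE)),
      if (n_c > 0) make_truth(sprintf("x%d", seq_len(n_c)), "contaminant",
                              start = sample(0:50, n_c, TRUE))
    )
    n <- n_e + n_c
    mapped <- stats::runif(n) < 0.6
    obs <- data.frame(
      read_id = truth$read_id, is_mapped = mapped,
      contig = ifelse(mapped, sample(c("c1", "c2"), n, TRUE), NA),
      leftmost_pos = ifelse(mapped, sample(0:60, n, TRUE), NA_integer_),
      strand = ifelse(mapped, sample(c("+", "-"), n, TRUE), NA),
      mapq = ifelse(mapped, sample(0:60, n, TRUE), NA_integer_),
      stringsAsFactors = FALSE)
    m <- evaluate_run(obs, truth, mapq_threshold = 30L)
    for (r in 1:2) {
      expect_identical(m$endo_correct[r] + m$endo_incorrect[r] +
                         m$endo_unmapped[r], n_e)
      expect_identical(m$cont_mapped[r] + m$cont_unmapped[r], n_c)
      expect_identical(m$total_mapped[r],
                       m$endo_correct[r] + m$endo_incorrect[r] +
                         m$cont_mapped[r])
      if (m$total_mapped[r] > 0) {
        expect_equal(m$fpr[r] * m$total_mapped[r], m$cont_mapped[r])
      }
    }
    # filtering never increases mapped counts
    expect_lte(m$total_mapped[2], m$total_mapped[1])
    expect_lte(m$endo_correct[2], m$endo_correct[1])
    expect_lte(m$cont_mapped[2], m$cont_mapped[1])
  }
})

test_that("raising the MapQ threshold is monotone in mapped counts", {
  set.seed(11)
  tr <- toy_run()
  tr$obs$mapq[tr$obs$is_mapped] <- sample(0:60, sum(tr$obs$is_mapped))
  prev <- NULL
  for (thr in c(0L, 10L, 20L, 30L, 40L, 50L, 61L)) {
    m <- evaluate_run(tr$obs, tr$truth, mapq_threshold = thr)
    cur <- m[m$mapq_filter != "none", ]
    if (!is.null(prev)) {
      expect_lte(cur$total_mapped, prev$total_mapped)
      expect_lte(cur$endo_correct, prev$endo_correct)
      expect_lte(cur$cont_mapped, prev$cont_mapped)
    }
    prev <- cur
  }
})

test_that("summarize_runs joins runs and metrics with fold changes", {
  runs <- data.frame(
    run_id = c("run001", "run002"), n = c("0.04", "0.004"),
    command = c("x", "y"), exit_status = c(0L, 0L),
    wall_time_s = c(1, 2), cpu_time_s = c(1, 2),
    sam_path = c("a.sam", "b.sam"), stringsAsFactors = FALSE)
  # mapped-read counts as in the published simulated comparison:
  # baseline 117,379 vs optimized 171,099 -> fold change ~1.46 (prints 1.5)
  mk <- function(total) {
    truth <- make_truth(sprintf("e%d", seq_len(total + 10)), "endogenous",
                        start = 0L)
    obs <- rbind(
      make_obs(truth$read_id[seq_len(total)], TRUE, "c1", 0L, "+", 60L),
      make_obs(truth$read_id[(total + 1):(total + 10)], FALSE))
    evaluate_run(obs, truth)
  }
  # scale by 1/1000 to keep the toy fast; the ratio is what matters
  metrics <- list(run001 = mk(117L), run002 = mk(171L))
  metrics$run001$total_mapped <- c(117379L, 117379L)
  metrics$run002$total_mapped <- c(171099L, 171099L)
  rep_df <- summarize_runs(runs, metrics, baseline_run_id = "run001")
  expect_identical(nrow(rep_df), 4L)  # 2 runs x 2 filter states
  fold <- rep_df$fold_total_mapped[rep_df$run_id == "run002" &
                                     rep_df$mapq_filter == "none"]
  expect_equal(fold, 171099 / 117379, tolerance = 1e-12)
  expect_equal(round(fold, 1), 1.5)
  expect_equal(rep_df$fold_total_mapped[rep_df$run_id == "run001"], c(1, 1))
})

test_that("summarize_runs flags failed runs and validates the baseline", {
  runs <- data.frame(
    run_id = c("run001", "run002"), n = c("a", "b"), command = "c",
    exit_status = c(0L, 1L), wall_time_s = 1, cpu_time_s = 1,
    sam_path = "s.sam", stringsAsFactors = FALSE)
  tr <- toy_run()
  metrics <- list(run001 = evaluate_run(tr$obs, tr$truth))
  rep_df <- summarize_runs(runs, metrics)
  expect_identical(nrow(rep_df), 4L)
  expect_true(all(rep_df$failed[rep_df$run_id == "run002"]))
  expect_true(all(is.na(rep_df$sensitivity[rep_df$run_id == "run002"])))
  expect_false(any(rep_df$failed[rep_df$run_id == "run001"]))
  # no fold columns without a baseline
  expect_false(any(grepl("^fold_", names(rep_df))))
  expect_error(summarize_runs(runs, metrics, baseline_run_id = "nope"),
               "unknown baseline")
})
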