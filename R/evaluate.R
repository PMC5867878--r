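#' Classify reads against their recorded origins
#'
#' Endogenous reads are correct when the primary alignment hits the true
#' contig and strand and its leftmost 0-based coordinate is within
#' `tolerance` bases of the true fragment start; otherwise incorrect, or
#' unmapped. A contaminant read is a false positive whenever it maps at all,
#' anywhere. Minus-strand truth is still compared by leftmost coordinate,
#' since both truth start and SAM POS are leftmost by construction.
#'
#' @param observations Data frame from [parse_alignments()].
#' @param truth Truth-table data frame ([read_truth_table()]); read ids must
#'   match `observations` row for row.
#' @param tolerance Allowed |reported - true| start offset in bases.
#'   Default 0 (exact match); a small positive value (>= 5) is advisable
#'   when the mapper may soft-clip damaged read ends, which shifts POS.
#' @return Character vector with one of `ENDO_CORRECT`, `ENDO_INCORRECT`,
#'   `ENDO_UNMAPPED`, `CONT_MAPPED`, `CONT_UNMAPPED` per read.
#' @export
classify_reads <- function(observations, truth, tolerance = 0L) {
  if (nrow(observations) != nrow(truth) ||
      !identical(as.character(observations$read_id),
                 as.character(truth$read_id))) {
    stop("observations and truth must cover the same read ids in the same order")
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  endo <- truth$role == "endogenous"
  mapped <- observations$is_mapped
  cls <- character(nrow(truth))
  cls[!endo] <- ifelse(mapped[!endo], "CONT_MAPPED", "CONT_UNMAPPED")
  correct <- mapped & endo &
    !is.na(observations$contig) & observations$contig == truth$contig &
    observations$strand == truth$strand &
    abs(observations$leftmost_pos - truth$start) <= tolerance
  correct[is.na(correct)] <- FALSE
  cls[endo] <- ifelse(!mapped[endo], "ENDO_UNMAPPED",
                      ifelse(correct[endo], "ENDO_CORRECT", "ENDO_INCORRECT"))
  cls
}

.metrics_from_classes <- function(cls, truth, mapq_filter) {
  endo_correct <- sum(cls == "ENDO_CORRECT")
  endo_incorrect <- sum(cls == "ENDO_INCORRECT")
  endo_unmapped <- sum(cls == "ENDO_UNMAPPED")
  cont_mapped <- sum(cls == "CONT_MAPPED")
  cont_unmapped <- sum(cls == "CONT_UNMAPPED")
  n_endo <- endo_correct + endo_incorrect + endo_unmapped
  n_cont <- cont_mapped + cont_unmapped
  total_mapped <- endo_correct + endo_incorrect + cont_mapped
  mapped_bases <- sum(truth$length[cls %in%
                                     c("ENDO_CORRECT", "ENDO_INCORRECT", "CONT_MAPPED")])
  data.frame(
    mapq_filter = mapq_filter,
    endo_correct = endo_correct, endo_incorrect = endo_incorrect,
    endo_unmapped = endo_unmapped, cont_mapped = cont_mapped,
    cont_unmapped = cont_unmapped, total_mapped = total_mapped,
    mapped_bases = mapped_bases,
    sensitivity = if (n_endo > 0) endo_correct / n_endo else NA_real_,
    specificity = if (n_cont > 0) cont_unmapped / n_cont else NA_real_,
    fpr = if (total_mapped > 0) cont_mapped / total_mapped else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Compute sensitivity, specificity and false-positive rate for one run
#'
#' Definitions: sensitivity = fraction of all endogenous reads that map to
#' their true coordinates; specificity = fraction of all contaminant reads
#' that fail to map; false-positive rate = mapped contaminant reads over all
#' mapped reads (`NA` when nothing maps). Metrics are reported twice: over
#' all reads, and after treating mapped reads with mapping quality below
#' `mapq_threshold` as unmapped (reads with `mapq >= mapq_threshold` are
#' kept).
#'
#' @param observations Data frame from [parse_alignments()].
#' @param truth Matching truth table (same ids; reordered internally).
#' @param mapq_threshold Minimum MapQ kept by the filtered view (default 30).
#' @param tolerance Position tolerance passed to [classify_reads()].
#' @return Object of class `run_metrics`: a two-row data frame (rows
#'   `mapq_filter = "none"` and `mapq_filter = ">=<threshold>"`) with class
#'   counts, `total_mapped`, `mapped_bases` (sum of read lengths of mapped
#'   reads, a coverage proxy), `sensitivity`, `specificity` and `fpr`.
#' @examples
#' # 8 endogenous reads: 5 correct, 1 incorrect, 2 unmapped;
#' # 4 contaminants: 1 mapped -> sensitivity 0.625, specificity 0.75, fpr 1/7
#' @export
evaluate_run <- function(observations, truth, mapq_threshold = 30L,
                         tolerance = 0L) {
  i <- match(observations$read_id, truth$read_id)
  if (anyNA(i) || nrow(observations) != nrow(truth)) {
    stop("observations must cover exactly the truth-table reads")
  }
  truth <- truth[i, , drop = FALSE]
  cls <- classify_reads(observations, truth, tolerance)
  unfiltered <- .metrics_from_classes(cls, truth, "none")

  filt <- observations
  drop <- filt$is_mapped & !is.na(filt$mapq) & filt$mapq < mapq_threshold
  filt$is_mapped[drop] <- FALSE
  filt$contig[drop] <- NA_character_
  filt$leftmost_pos[drop] <- NA_integer_
  filt$strand[drop] <- NA_character_
  filt$mapq[drop] <- NA_integer_
  cls_f <- classify_reads(filt, truth, tolerance)
  filtered <- .metrics_from_classes(cls_f, truth,
                                    paste0(">=", mapq_threshold))
  out <- rbind(unfiltered, filtered)
  class(out) <- c("run_metrics", class(out))
  out
}

#' @export
print.run_metrics <- function(x, ...) {
  cat("Mapping-run metrics:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Build the cross-run comparison report
#'
#' One row per (run, MapQ-filter state), joining the sweep manifest's
#' parameter columns and runtimes with the evaluated metrics. When a
#' baseline run is named, fold-change columns relative to the baseline (at
#' the same filter state) are added for `total_mapped`, `sensitivity` and
#' `mapped_bases`. Failed runs (non-zero exit status) appear with `NA`
#' metrics and `failed = TRUE` rather than being dropped.
#'
#' @param runs Sweep manifest data frame (from [run_sweep()] or
#'   [read_manifest()]): columns `run_id`, parameter columns, `exit_status`,
#'   `wall_time_s`, `cpu_time_s`.
#' @param metrics Named list of `run_metrics`, one per successful run, names
#'   = run ids.
#' @param baseline_run_id Optional run id to compare against.
#' @return Data frame of class `sweep_report`.
#' @export
summarize_runs <- function(runs, metrics, baseline_run_id = NULL) {
  if (!is.null(baseline_run_id) && !(baseline_run_id %in% runs$run_id)) {
    stop("unknown baseline run id: ", baseline_run_id)
  }
  par_cols <- setdiff(names(runs), c("run_id", "command", "exit_status",
                                     "wall_time_s", "cpu_time_s", "sam_path"))
  rows <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    run <- runs[r, , drop = FALSE]
    failed <- is.na(run$exit_status) || run$exit_status != 0L ||
      is.null(metrics[[run$run_id]])
    if (failed) {
      m <- .metrics_from_classes(character(0),
                                 data.frame(length = integer(0)), "none")
      m <- m[c(1L, 1L), ]
      for (col in setdiff(names(m), "mapq_filter")) m[[col]] <- NA
      m$mapq_filter <- c("none", "filtered")
      rownames(m) <- NULL
    } else {
      m <- as.data.frame(metrics[[run$run_id]])
    }
    base <- run[rep(1L, nrow(m)),
                c("run_id", par_cols, "wall_time_s", "cpu_time_s"),
                drop = FALSE]
    rows[[r]] <- cbind(base, m, failed = failed, row.names = NULL)
  }
  rep_df <- do.call(rbind, rows)
  if (!is.null(baseline_run_id)) {
    for (col in c("total_mapped", "sensitivity", "mapped_bases")) {
      bl <- rep_df[rep_df$run_id == baseline_run_id, ]
      idx <- match(rep_df$mapq_filter, bl$mapq_filter)
      denom <- bl[[col]][idx]
      rep_df[[paste0("fold_", col)]] <- ifelse(
        !is.na(denom) & denom > 0, rep_df[[col]] / denom, NA_real_)
    }
  }
  rownames(rep_df) <- NULL
  class(rep_df) <- c("sweep_report", class(rep_df))
  rep_df
}

#' Write / read a sweep report TSV
#' @param report A `sweep_report` data frame.
#' @param path TSV path.
#' @return `path` invisibly / the report data frame.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
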