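#' Construct a deamination damage profile
#'
#' Post-mortem cytosine deamination is read as C-to-T substitutions that are
#' most frequent at the 5' end of a fragment and decay inwards; on
#' double-stranded libraries the complementary G-to-A signal appears at the
#' 3' end. A profile holds, per position, the probability that an eligible
#' base is mis-read.
#'
#' @param ct5 Numeric vector; `ct5[i]` is the probability that a C at read
#'   position `i` (counted from the 5' end, first position = 1) is read as T.
#' @param ga3 Numeric vector; `ga3[j]` is the probability that a G at
#'   position `j` counted from the 3' end is read as A. Defaults to none.
#' @return Object of class `damage_profile`. Positions beyond the vector
#'   lengths have probability 0; empty vectors mean no damage.
#' @export
damage_profile <- function(ct5 = numeric(0), ga3 = numeric(0)) {
  ct5 <- as.numeric(ct5); ga3 <- as.numeric(ga3)
  if (any(ct5 < 0 | ct5 > 1) || any(ga3 < 0 | ga3 > 1)) {
    stop("damage probabilities must lie in [0, 1]")
  }
  structure(list(ct5 = ct5, ga3 = ga3), class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("Damage profile: 5' C>T over", length(x$ct5), "position(s)",
      if (length(x$ct5)) sprintf("(terminal %.3f)", x$ct5[1L]) else "",
      "; 3' G>A over", length(x$ga3), "position(s)\n")
  invisible(x)
}

#' Parse mapDamage per-position mis-incorporation frequency tables
#'
#' mapDamage writes per-position substitution frequencies as two-column
#' text (position, frequency), positions 1-based and ascending from the
#' respective read end (5pCtoT_freq.txt / 3pGtoA_freq.txt). Header lines
#' whose first token is not numeric are skipped.
#'
#' @param path_5p_ct Path to the 5' C-to-T frequency table.
#' @param path_3p_ga Optional path to the 3' G-to-A table; when absent the
#'   3' model is off.
#' @return A [damage_profile()].
#' @export
parse_mapdamage_profile <- function(path_5p_ct, path_3p_ga = NULL) {
  ct5 <- .read_freq_table(path_5p_ct)
  ga3 <- if (is.null(path_3p_ga)) numeric(0) else .read_freq_table(path_3p_ga)
  damage_profile(ct5 = ct5, ga3 = ga3)
}

.read_freq_table <- function(path) {
  if (!file.exists(path)) stop("frequency table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[\t ]+")
  first <- vapply(fields, `[`, "", 1L)
  numeric_row <- suppressWarnings(!is.na(as.numeric(first)))
  fields <- fields[numeric_row]
  if (length(fields) == 0L) stop("no data rows in frequency table '", path, "'")
  pos <- as.integer(vapply(fields, `[`, "", 1L))
  freq <- as.numeric(vapply(fields, `[`, "", 2L))
  if (anyNA(freq)) stop("non-numeric frequency in '", path, "'")
  if (any(freq < 0 | freq > 1)) {
    stop("frequency outside [0, 1] in '", path, "' at position ",
         pos[which(freq < 0 | freq > 1)[1L]])
  }
  if (!identical(pos, seq_along(pos))) {
    expected <- seq_along(pos)
    bad <- which(pos != expected)[1L]
    stop("non-contiguous positions in '", path, "': expected position ",
         expected[bad], ", found ", pos[bad])
  }
  freq
}

#' Geometric-decay parametric damage profile
#'
#' A convenient stand-in for a measured profile: the terminal substitution
#' probability `p0` falls off geometrically inwards, mirroring the
#' exponential decay of deamination frequency away from fragment ends.
#' Position i (1-based from the end) gets probability `p0 * decay^(i-1)`.
#'
#' @param p0 Terminal substitution probability, in \[0, 1\].
#' @param decay Per-position decay factor, in \[0, 1\].
#' @param n_positions Number of positions the profile covers (beyond it the
#'   probability is 0).
#' @param both_ends If `TRUE`, the same decay curve is used for the 3' G-to-A
#'   model; by default only 5' C-to-T damage is generated.
#' @return A [damage_profile()].
#' @examples
#' geometric_profile(0.3, 0.5, 3)$ct5  # 0.300 0.150 0.075
#' @export
geometric_profile <- function(p0, decay, n_positions, both_ends = FALSE) {
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (decay < 0 || decay > 1) stop("decay must lie in [0, 1]")
  if (n_positions < 0) stop("n_positions must be >= 0")
  v <- if (n_positions == 0L) numeric(0) else p0 * decay^(seq_len(n_positions) - 1)
  damage_profile(ct5 = v, ga3 = if (both_ends) v else numeric(0))
}

#' Apply deamination damage to read sequences
#'
#' For each read (already in sequencing orientation), every C at 5' position
#' i is independently replaced by T with probability `profile$ct5[i]`, and
#' every G at 3' position j by A with probability `profile$ga3[j]`. All other
#' bases are untouched and length is preserved. The 5' rule is evaluated
#' first; since it only turns C into T, the two rules never compete for a
#' base.
#'
#' @param sequence Character vector of read sequences.
#' @param profile A [damage_profile()].
#' @return Character vector of damaged sequences, same length and widths.
#' @export
apply_damage <- function(sequence, profile) {
  stopifnot(inherits(profile, "damage_profile"))
  if (length(sequence) == 0L) return(sequence)
  if (length(profile$ct5) == 0L && length(profile$ga3) == 0L) return(sequence)
  lens <- nchar(sequence)
  nonzero <- lens > 0L
  if (!any(nonzero)) return(sequence)
  ch <- strsplit(sequence[nonzero], "", fixed = TRUE)
  v <- unlist(ch, use.names = FALSE)
  n <- lens[nonzero]
  p5 <- base::sequence(n)                  # 1-based position from 5'
  p3 <- rep.int(n, n) - p5 + 1L            # 1-based position from 3'
  if (length(profile$ct5) > 0L) {
    pr <- ifelse(p5 <= length(profile$ct5), profile$ct5[pmin(p5, length(profile$ct5))], 0)
    hit <- v == "C" & pr > 0 & stats::runif(length(v)) < pr
    v[hit] <- "T"
  }
  if (length(profile$ga3) > 0L) {
    pr <- ifelse(p3 <= length(profile$ga3), profile$ga3[pmin(p3, length(profile$ga3))], 0)
    hit <- v == "G" & pr > 0 & stats::runif(length(v)) < pr
    v[hit] <- "A"
  }
  out <- sequence
  grp <- rep.int(seq_along(n), n)
  out[nonzero] <- vapply(split(v, grp), paste, "", collapse = "")
  out
}
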