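#' Declare a read source for simulation
#'
#' A source is one genome contributing reads to the simulated mixture:
#' either the endogenous target (reads from it should map to the reference)
#' or a contaminant (reads from it should not).
#'
#' @param source_id Short label, unique across sources.
#' @param fasta_path Path to the source genome (multi-FASTA).
#' @param role `"endogenous"` or `"contaminant"`.
#' @param fraction Proportion of the read set drawn from this source.
#' @param divergence Per-base substitution probability applied to fragments
#'   from this source, modelling evolutionary distance to the mapping
#'   reference (e.g. 0.05 for a reference ~28 My diverged).
#' @param damage A [damage_profile()] or `NULL` for no damage. Contaminants
#'   default to undamaged.
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(source_id, fasta_path, role, fraction,
                        divergence = 0, damage = NULL) {
  role <- match.arg(role, c("endogenous", "contaminant"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (divergence < 0 || divergence > 1) stop("divergence must lie in [0, 1]")
  if (!is.null(damage) && !inherits(damage, "damage_profile")) {
    stop("damage must be a damage_profile or NULL")
  }
  structure(list(source_id = source_id, fasta_path = fasta_path, role = role,
                 fraction = fraction, divergence = divergence,
                 damage = damage),
            class = "source_spec")
}

#' Simulation configuration
#'
#' Fragment lengths follow a shifted exponential: `min_length` plus the
#' floor of an exponential variate with mean `decay_length`, the classic
#' model for degraded-DNA fragment-size decay.
#'
#' @param sources List of [source_spec()] objects; fractions must sum to 1.
#' @param n_reads Total number of reads to simulate.
#' @param min_length Minimum fragment length in bp.
#' @param decay_length Mean of the exponential length tail in bp; 0 gives
#'   constant-length fragments.
#' @param seed Integer seed; the whole read set is reproducible from it.
#' @param quality_char Constant FASTQ base quality (Phred+33).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(sources, n_reads, min_length = 30, decay_length = 15,
                       seed = 1L, quality_char = "I") {
  if (!length(sources) || !all(vapply(sources, inherits, TRUE, "source_spec"))) {
    stop("sources must be a non-empty list of source_spec objects")
  }
  ids <- vapply(sources, `[[`, "", "source_id")
  if (anyDuplicated(ids)) stop("duplicate source_id: ", ids[duplicated(ids)][1L])
  fr <- vapply(sources, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("source fractions must sum to 1 (got ", format(sum(fr)), ")")
  }
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (min_length < 1) stop("min_length must be >= 1")
  if (decay_length < 0) stop("decay_length must be >= 0")
  structure(list(sources = sources, n_reads = as.integer(n_reads),
                 min_length = as.integer(min_length),
                 decay_length = decay_length, seed = as.integer(seed),
                 quality_char = quality_char),
            class = "sim_config")
}

#' Allocate exact per-source read counts
#'
#' Composition is exact, not multinomial: each source gets
#' `floor(n_reads * fraction)` reads and the shortfall is distributed by
#' largest remainder (ties broken by source order), so the realized mixture
#' matches the declared one to the read.
#'
#' @param n_reads Total reads.
#' @param fractions Numeric vector of proportions summing to 1.
#' @return Integer vector of counts summing to `n_reads`.
#' @examples
#' allocate_composition(1e6, c(0.26, 0.01, 0.03, 0.70))
#' @export
allocate_composition <- function(n_reads, fractions) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  exact <- n_reads * fractions
  counts <- floor(exact)
  short <- round(n_reads - sum(counts))
  if (short > 0) {
    rem <- exact - counts
    # largest remainder; order() breaks ties by position = source order
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Draw fragment lengths from the shifted exponential decay model
#'
#' Returns `min_length + floor(X)` with `X ~ Exponential(mean = decay_length)`.
#' With `decay_length = 0` every fragment has length `min_length`.
#'
#' @param n Number of draws.
#' @param min_length Minimum fragment length.
#' @param decay_length Mean of the exponential tail.
#' @return Integer vector of lengths.
#' @export
sample_fragment_length <- function(n, min_length, decay_length) {
  if (decay_length == 0) return(rep.int(as.integer(min_length), n))
  as.integer(min_length + floor(stats::rexp(n, rate = 1 / decay_length)))
}

#' Sample uniform genomic origins for fragments
#'
#' Placement is uniform over all valid (contig, start) pairs genome-wide:
#' a contig of length L can host a fragment of length len at L - len + 1
#' starts, and contigs are weighted accordingly. Strand is +/- with equal
#' probability.
#'
#' @param genome A `reference_genome`.
#' @param length Integer vector of fragment lengths.
#' @param role `"endogenous"` or `"contaminant"`.
#' @param source_id Source label recorded in the origins.
#' @param read_id Optional read names (defaults to a serial per call).
#' @return Data frame of read origins (truth-table columns).
#' @export
sample_origin <- function(genome, length, role, source_id,
                          read_id = NULL) {
  stopifnot(inherits(genome, "reference_genome"))
  n <- base::length(length)
  if (is.null(read_id)) read_id <- sprintf("r%d", seq_len(n))
  clens <- genome$lengths
  # per-read valid start counts per contig: max(clen - len + 1, 0)
  # vectorized cumulative inversion over contigs
  k <- base::length(clens)
  W <- outer(clens, length, function(L, l) pmax(L - l + 1, 0))  # k x n
  tot <- colSums(W)
  if (any(tot == 0)) {
    stop("no contig long enough for fragment length ",
         length[which(tot == 0)[1L]], " in genome '", genome$source_id, "'")
  }
  u <- stats::runif(n) * tot
  cw <- matrix(apply(W, 2L, cumsum), nrow = k)     # k x n cumulative
  ci <- max.col(t(cw >= rep(u, each = k)), ties.method = "first")
  # start uniform over 0 .. (clen - len)
  navail <- W[cbind(ci, seq_len(n))]
  start <- as.integer(floor(stats::runif(n) * navail))
  start <- pmin(start, as.integer(navail) - 1L)    # guard runif()==1 edge
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  data.frame(read_id = read_id, source_id = source_id, role = role,
             contig = names(clens)[ci], start = start,
             end = start + as.integer(length), strand = strand,
             length = as.integer(length), stringsAsFactors = FALSE)
}

#' Extract fragment sequences for read origins
#'
#' Returns the contig substring over `[start, end)`, reverse-complemented
#' when the origin is on the minus strand. IUPAC ambiguity codes are
#' preserved.
#'
#' @param genome A `reference_genome`.
#' @param origins Truth-table data frame (as from [sample_origin()]).
#' @return Character vector of fragment sequences in read orientation.
#' @export
extract_fragment <- function(genome, origins) {
  stopifnot(inherits(genome, "reference_genome"))
  ci <- match(origins$contig, names(genome$contigs))
  if (anyNA(ci)) {
    stop("unknown contig '", origins$contig[is.na(ci)][1L], "' in origins")
  }
  bad <- origins$start < 0 | origins$end > genome$lengths[ci] |
    origins$start >= origins$end
  if (any(bad)) {
    stop("origin coordinates out of range for read '",
         origins$read_id[bad][1L], "'")
  }
  seqs <- substring(genome$contigs[ci], origins$start + 1L, origins$end)
  minus <- origins$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  unname(seqs)
}

#' Apply divergence substitutions
#'
#' Each A/C/G/T base is independently replaced, with probability `rate`, by
#' a base drawn uniformly from the other three (no transition/transversion
#' bias). Ambiguity codes are untouched; length is preserved. This models
#' the genetic distance between the simulated target and the mapping
#' reference.
#'
#' @param sequence Character vector of sequences.
#' @param rate Per-base substitution probability in \[0, 1\].
#' @return Character vector of mutated sequences.
#' @export
apply_divergence <- function(sequence, rate) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0 || length(sequence) == 0L) return(sequence)
  lens <- nchar(sequence)
  nonzero <- lens > 0L
  if (!any(nonzero)) return(sequence)
  v <- unlist(strsplit(sequence[nonzero], "", fixed = TRUE), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  bi <- match(v, bases)
  hit <- which(!is.na(bi) & stats::runif(length(v)) < rate)
  if (length(hit) > 0L) {
    # row i of alt = the three alternatives to bases[i]
    alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                 c("A", "C", "T"), c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- alt[cbind(bi[hit], pick)]
  }
  out <- sequence
  grp <- rep.int(seq_len(sum(nonzero)), lens[nonzero])
  out[nonzero] <- vapply(split(v, grp), paste, "", collapse = "")
  out
}

#' Simulate a complete degraded-DNA read set with its truth table
#'
#' Per read the pipeline is: draw a fragment length, place it uniformly on
#' its source genome, extract the sequence, apply divergence substitutions
#' (in fragment orientation), reverse-complement minus-strand fragments,
#' then apply deamination damage (in read orientation, where damage
#' profiles are defined). Reads are generated source by source in
#' configuration order and the whole set is reproducible from the seed.
#' Fragment lengths with no valid placement (longer than every contig) are
#' redrawn up to `max_retries` times, then the simulation errors.
#'
#' @param config A [sim_config()].
#' @param out_fastq Output FASTQ path.
#' @param out_truth Output truth-table TSV path.
#' @param max_retries Bound on per-read length redraws.
#' @return Invisibly, a summary list: `n_reads`, per-source `counts`,
#'   `mean_length`, output paths.
#' @export
simulate_readset <- function(config, out_fastq, out_truth,
                             max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fr <- vapply(config$sources, `[[`, 0, "fraction")
  counts <- allocate_composition(config$n_reads, fr)
  pad <- max(1L, nchar(as.character(config$n_reads)))
  serial <- 0L
  all_ids <- character(0)
  all_seqs <- character(0)
  truth <- vector("list", length(config$sources))

  for (s in seq_along(config$sources)) {
    src <- config$sources[[s]]
    nk <- counts[s]
    if (nk == 0L) next
    genome <- read_fasta(src$fasta_path, source_id = src$source_id)
    maxlen <- max(genome$lengths)
    lens <- sample_fragment_length(nk, config$min_length, config$decay_length)
    tries <- 0L
    while (any(lens > maxlen)) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("could not place a fragment on '", src$source_id,
             "' after ", max_retries, " length redraws (min_length ",
             config$min_length, " vs longest contig ", maxlen, " bp)")
      }
      redo <- lens > maxlen
      lens[redo] <- sample_fragment_length(sum(redo), config$min_length,
                                           config$decay_length)
    }
    ids <- sprintf(paste0("sim%0", pad, "d"), serial + seq_len(nk))
    serial <- serial + nk
    org <- sample_origin(genome, lens, src$role, src$source_id, read_id = ids)
    # divergence in fragment (plus-strand) orientation, then orient, then damage
    frag <- substring(genome$contigs[match(org$contig, names(genome$contigs))],
                      org$start + 1L, org$end)
    frag <- apply_divergence(unname(frag), src$divergence)
    minus <- org$strand == "-"
    if (any(minus)) {
      frag[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frag[minus])))
    }
    if (!is.null(src$damage)) frag <- apply_damage(frag, src$damage)
    all_ids <- c(all_ids, ids)
    all_seqs <- c(all_seqs, frag)
    truth[[s]] <- org
  }

  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(read_id = character(0), source_id = character(0),
                        role = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), length = integer(0),
                        stringsAsFactors = FALSE)
  }
  write_fastq(all_ids, all_seqs, out_fastq, config$quality_char)
  write_truth_table(truth, out_truth)
  summary <- list(
    n_reads = config$n_reads,
    counts = stats::setNames(counts,
                             vapply(config$sources, `[[`, "", "source_id")),
    mean_length = if (nrow(truth)) mean(truth$length) else NA_real_,
    fastq = out_fastq, truth = out_truth
  )
  invisible(summary)
}
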