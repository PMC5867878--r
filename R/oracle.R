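#' Generate a deterministic random reference genome
#'
#' Contigs of i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2, reproducible from the seed. Random genomes of 100 kb or more
#' make 30-mers effectively unique, which is what the exhaustive-aligner
#' tests rely on.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param gc GC content in \[0, 1\].
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @param source_id Genome label (default "synth").
#' @return A `reference_genome`; written to `path` as FASTA when given.
#' @export
generate_genome <- function(n_contigs, contig_length, gc = 0.5, seed = 1L,
                            path = NULL, source_id = "synth") {
  if (n_contigs < 1L || contig_length < 1L) stop("lengths must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(names(probs), contig_length, replace = TRUE, prob = probs),
          collapse = "")
  }, "")
  names(contigs) <- sprintf("ctg%d", seq_len(n_contigs))
  genome <- new_reference_genome(source_id, contigs)
  if (!is.null(path)) write_genome_fasta(genome, path)
  genome
}

#' Write a reference genome as FASTA
#' @param genome A `reference_genome`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "reference_genome"))
  set <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Exhaustive gapless aligner emitting SAM
#'
#' A reference mapper for testing: every read is compared against every
#' position of every contig on both strands, keeping gapless full-length
#' hits with at most `max_mismatch` mismatches. A unique best hit (strictly
#' fewest mismatches) is reported as a primary record with MapQ 60; tied
#' best hits are reported at the first tied position in scan order (contig
#' order, then position, then + before -) with MapQ 0, mimicking how real
#' mappers flag ambiguous placements; no hit yields an unmapped record.
#' Reads longer than every contig are unmapped, not an error. Deliberately
#' O(genome x reads); intended for fixture-scale data, not real mapping.
#'
#' @param reads_fastq Path to the reads (FASTQ).
#' @param genome A `reference_genome` or path to a FASTA file.
#' @param max_mismatch Maximum number of mismatches allowed per hit.
#' @param out_sam Output SAM path.
#' @return `out_sam` invisibly.
#' @export
oracle_align <- function(reads_fastq, genome, max_mismatch = 0L, out_sam) {
  if (is.character(genome)) genome <- read_fasta(genome)
  stopifnot(inherits(genome, "reference_genome"))
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  reads <- Biostrings::readDNAStringSet(reads_fastq, format = "fastq")
  ids <- sub("\\s.*$", "", names(reads))
  subjects <- lapply(genome$contigs, Biostrings::DNAString)
  cnames <- names(genome$contigs)
  clens <- unname(genome$lengths)

  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", cnames, clens),
    "@PG\tID:mapsweep-oracle\tPN:mapsweep-oracle"
  )
  n <- length(reads)
  lines <- character(n)
  rc_reads <- Biostrings::reverseComplement(reads)
  for (i in seq_len(n)) {
    fwd <- reads[[i]]
    rev <- rc_reads[[i]]
    hits_contig <- integer(0); hits_pos <- integer(0)
    hits_strand <- character(0); hits_mm <- integer(0)
    for (ci in seq_along(subjects)) {
      if (length(fwd) > clens[ci]) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") fwd else rev
        m <- Biostrings::matchPattern(pat, subjects[[ci]],
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        st <- BiocGenerics::start(m)
        if (length(st) == 0L) next
        mm <- Biostrings::neditStartingAt(pat, subjects[[ci]], starting.at = st,
                                          with.indels = FALSE)
        hits_contig <- c(hits_contig, rep.int(ci, length(st)))
        hits_pos <- c(hits_pos, st)
        hits_strand <- c(hits_strand, rep.int(strand, length(st)))
        hits_mm <- c(hits_mm, mm)
      }
    }
    seq_fwd <- as.character(fwd)
    if (length(hits_pos) == 0L) {
      lines[i] <- paste(ids[i], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                        seq_fwd, "*", sep = "\t")
      next
    }
    best <- min(hits_mm)
    cand <- which(hits_mm == best)
    # scan order: contig, then position, then + before -
    ord <- order(hits_contig[cand], hits_pos[cand], hits_strand[cand])
    pick <- cand[ord[1L]]
    mapq <- if (length(cand) == 1L) 60L else 0L
    flag <- if (hits_strand[pick] == "-") 16L else 0L
    seq_out <- if (flag == 16L) as.character(rev) else seq_fwd
    lines[i] <- paste(ids[i], flag, cnames[hits_contig[pick]],
                      hits_pos[pick], mapq,
                      paste0(length(fwd), "M"), "*", 0L, 0L,
                      seq_out, "*",
                      paste0("NM:i:", hits_mm[pick]), sep = "\t")
  }
  writeLines(c(header, lines), out_sam)
  invisible(out_sam)
}
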