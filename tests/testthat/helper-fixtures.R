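# Shared fixture builders and an independent reference implementation of
# gapless alignment used to cross-check the package's exhaustive aligner.

write_tmp_fasta <- function(lines, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal valid SAM file: header for the given contigs plus raw record lines.
write_tmp_sam <- function(records, contigs = c(c1 = 100L)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, rname = "*", pos = 0L, mapq = 0L,
                       cigar = "*", seq = "ACGT") {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

make_truth <- function(read_id, role, contig = "c1", start = 0L,
                       length = 4L, strand = "+", source_id = "src") {
  n <- base::length(read_id)
  data.frame(read_id = read_id, source_id = rep_len(source_id, n),
             role = rep_len(role, n), contig = rep_len(contig, n),
             start = rep_len(as.integer(start), n),
             end = rep_len(as.integer(start), n) + rep_len(as.integer(length), n),
             strand = rep_len(strand, n),
             length = rep_len(as.integer(length), n),
             stringsAsFactors = FALSE)
}

make_obs <- function(read_id, is_mapped, contig = NA_character_,
                     leftmost_pos = NA_integer_, strand = NA_character_,
                     mapq = NA_integer_) {
  n <- base::length(read_id)
  data.frame(read_id = read_id, is_mapped = rep_len(is_mapped, n),
             contig = rep_len(contig, n),
             leftmost_pos = rep_len(as.integer(leftmost_pos), n),
             strand = rep_len(strand, n), mapq = rep_len(as.integer(mapq), n),
             stringsAsFactors = FALSE)
}

# Independent quadratic-time gapless scanner: character-by-character
# comparison at every offset of every contig, both strands. Returns the
# best hit the same way the oracle defines it, or NULL if none.
quadratic_scan <- function(read, contigs, max_mismatch) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  best <- NULL
  for (ci in seq_along(contigs)) {
    cs <- strsplit(contigs[[ci]], "")[[1]]
    L <- length(cs)
    w <- nchar(read)
    if (w > L) next
    for (strand in c("+", "-")) {
      rs <- strsplit(if (strand == "+") read else rc(read), "")[[1]]
      for (p in seq_len(L - w + 1L)) {
        mm <- sum(rs != cs[p:(p + w - 1L)])
        if (mm <= max_mismatch) {
          hit <- list(contig = names(contigs)[ci], pos = p, strand = strand,
                      mm = mm)
          if (is.null(best) || mm < best$mm) {
            best <- hit
            best$tied <- FALSE
          } else if (mm == best$mm) {
            best$tied <- TRUE  # first hit in scan order is kept
          }
        }
      }
    }
  }
  best
}

# Read a FASTQ written by the package back into ids + sequences.
read_tmp_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(list(id = character(0), seq = character(0)))
  }
  list(id = sub("^@", "", lines[seq(1L, length(lines), 4L)]),
       seq = lines[seq(2L, length(lines), 4L)])
}
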