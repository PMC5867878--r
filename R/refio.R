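#' Read a (multi-)FASTA reference genome
#'
#' Loads all contigs of a FASTA file in file order, uppercasing soft-masked
#' (lowercase) bases. Any assembly can be used, including draft assemblies
#' made of many scaffolds.
#'
#' @param path Path to a FASTA file.
#' @param source_id Short label for the genome (defaults to the file name
#'   without extension). Used in truth tables to tag read provenance.
#' @return An object of class `reference_genome`: a list with elements
#'   `source_id`, `contigs` (named character vector of uppercase sequences,
#'   names are contig names), `lengths` (named integer vector) and
#'   `total_length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", ">c2", "NNN"), fa)
#' g <- read_fasta(fa)
#' g$total_length  # 7
#' @export
read_fasta <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  # header line up to first whitespace is the contig name
  nms <- sub("\\s.*$", "", names(set))
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    stop("duplicate contig name(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for contig '", nms[!nzchar(seqs)][1L], "' in '",
         path, "'")
  }
  names(seqs) <- nms
  if (is.null(source_id)) {
    source_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  new_reference_genome(source_id, seqs)
}

new_reference_genome <- function(source_id, contigs) {
  lens <- nchar(contigs)
  structure(
    list(source_id = source_id, contigs = contigs, lengths = lens,
         total_length = sum(as.numeric(lens))),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("Reference genome '", x$source_id, "': ", length(x$contigs),
      " contig(s), ", format(x$total_length, big.mark = ","), " bp\n",
      sep = "")
  invisible(x)
}

#' Write reads as FASTQ with a constant base quality
#'
#' Simulated reads carry no per-base quality model; every base gets the same
#' Phred+33 quality character (default 'I' = Q40).
#'
#' @param read_id Character vector of read names.
#' @param sequence Character vector of read sequences (same length).
#' @param path Output path.
#' @param quality_char Single printable Phred+33 character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(read_id, sequence, path, quality_char = "I") {
  stopifnot(length(read_id) == length(sequence))
  if (nchar(quality_char) != 1L || !grepl("[!-~]", quality_char)) {
    stop("quality_char must be a single printable Phred+33 character")
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for read '", read_id[!nzchar(sequence)][1L], "'")
  }
  if (length(read_id) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep(quality_char, nchar(sequence))
  lines <- as.vector(rbind(paste0("@", read_id), sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

.truth_cols <- c("read_id", "source_id", "role", "contig", "start", "end",
                 "strand", "length")

#' Write / read the simulation truth table
#'
#' The truth table is the authoritative record of every simulated read's
#' origin: source genome, role (endogenous or contaminant), contig,
#' 0-based half-open coordinates and strand. Read names are opaque serials;
#' classification of mapping results always goes through this table.
#'
#' @param origins Data frame with columns `read_id`, `source_id`, `role`,
#'   `contig`, `start`, `end`, `strand`, `length`. Coordinates 0-based,
#'   half-open; `strand` is "+" or "-"; `role` is "endogenous" or
#'   "contaminant".
#' @param path TSV path.
#' @return `write_truth_table`: `path` invisibly. `read_truth_table`: the
#'   truth data frame keyed by `read_id` (row order preserved).
#' @export
write_truth_table <- function(origins, path) {
  origins <- as.data.frame(origins)
  missing <- setdiff(.truth_cols, names(origins))
  if (length(missing) > 0L) {
    stop("truth table missing column(s): ", paste(missing, collapse = ", "))
  }
  origins <- origins[, .truth_cols]
  if (anyDuplicated(origins$read_id)) {
    stop("duplicate read_id in truth table: ",
         origins$read_id[duplicated(origins$read_id)][1L])
  }
  utils::write.table(origins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- if (length(first)) strsplit(first, "\t", fixed = TRUE)[[1L]]
            else character(0)
  missing <- setdiff(.truth_cols, header)
  if (length(missing) > 0L) {
    stop("truth table '", path, "' missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tt <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(read_id = "character",
                                         source_id = "character",
                                         role = "character",
                                         contig = "character",
                                         start = "integer",
                                         end = "integer",
                                         strand = "character",
                                         length = "integer"),
                          check.names = FALSE)
  if (anyDuplicated(tt$read_id)) {
    stop("duplicate read_id in truth table '", path, "': ",
         tt$read_id[duplicated(tt$read_id)][1L])
  }
  tt
}

#' Extract one alignment observation per simulated read from a SAM file
#'
#' Only primary alignment records are considered (secondary 0x100 and
#' supplementary 0x800 records are ignored); if a mapper emits more than one
#' primary-looking record for a read, the first wins. A truth read with no
#' record in the file is reported as unmapped, because many mappers omit
#' unmapped reads. Records for reads not in `truth_ids` are skipped with a
#' warning. SAM's 1-based leftmost position is converted to the package's
#' 0-based convention at this boundary.
#'
#' @param path SAM (or BAM) file with a header.
#' @param truth_ids Character vector of expected read ids.
#' @return Data frame with one row per element of `truth_ids` (same order):
#'   `read_id`, `is_mapped`, and for mapped reads `contig`, `leftmost_pos`
#'   (0-based), `strand` ("+"/"-"), `mapq`; `NA` otherwise.
#' @export
parse_alignments <- function(path, truth_ids) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (anyDuplicated(truth_ids)) stop("truth_ids must be unique")
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("SAM format error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]

  keep <- bitwAnd(rec$flag, bitwOr(0x100L, 0x800L)) == 0L
  qname <- rec$qname[keep]
  flag <- rec$flag[keep]
  rname <- as.character(rec$rname)[keep]
  pos <- rec$pos[keep]
  mapq <- rec$mapq[keep]

  unknown <- !(qname %in% truth_ids)
  if (any(unknown)) {
    warning(sum(unknown), " alignment record(s) with read ids absent from ",
            "the truth set were skipped (e.g. '", qname[unknown][1L], "')")
    qname <- qname[!unknown]; flag <- flag[!unknown]
    rname <- rname[!unknown]; pos <- pos[!unknown]; mapq <- mapq[!unknown]
  }

  # first primary record per read wins
  idx <- match(truth_ids, qname)
  found <- !is.na(idx)
  out <- data.frame(
    read_id = truth_ids,
    is_mapped = FALSE,
    contig = NA_character_,
    leftmost_pos = NA_integer_,
    strand = NA_character_,
    mapq = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(found)) {
    i <- idx[found]
    mapped <- bitwAnd(flag[i], 0x4L) == 0L
    out$is_mapped[found] <- mapped
    sel <- which(found)[mapped]
    im <- i[mapped]
    out$contig[sel] <- rname[im]
    out$leftmost_pos[sel] <- pos[im] - 1L
    out$strand[sel] <- ifelse(bitwAnd(flag[im], 0x10L) != 0L, "-", "+")
    out$mapq[sel] <- mapq[im]
  }
  out
}
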