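DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. background sequence; uses the current RNG state.
#'
#' @param n Length in nucleotides.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains non-ACGT symbols: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

#' Construct a read set
#'
#' Lightweight container for a sequencing library (or a sample of one):
#' parallel vectors of identifiers, sequences and quality strings, plus a
#' library label (`"female"`, `"male"`, or `"mixed"`). An optional `origin`
#' data frame (one row per read: `seq_index`, `start`, `end`, 0-based
#' half-open on the source genome, `strand`) carries simulation ground truth
#' through the pipeline for truth-aware evaluation.
#'
#' @param id,seq,qual Character vectors of equal length.
#' @param library_label One of `"female"`, `"male"`, `"mixed"`.
#' @param origin Optional data frame of read origin coordinates.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual = NULL, library_label = "mixed",
                     origin = NULL) {
  if (is.null(qual)) qual <- strrep("?", nchar(seq))
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(seq) && any(!nzchar(seq))) stop("empty read sequences")
  if (!is.null(origin)) stopifnot(nrow(origin) == length(seq))
  structure(
    list(id = as.character(id), seq = as.character(seq),
         qual = as.character(qual),
         library_label = library_label, origin = origin),
    class = "read_set")
}

#' @exportS3Method base::length
length.read_set <- function(x) length(x$seq)

#' @exportS3Method base::print
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads (%s library)\n", length(x), x$library_label))
  if (length(x)) {
    cat(sprintf("  read length: %d-%d nt\n",
                min(nchar(x$seq)), max(nchar(x$seq))))
  }
  invisible(x)
}

#' Subset a read set
#'
#' @param rs A `read_set`.
#' @param i Index vector.
#' @return The subsetted `read_set`.
#' @export
subset_reads <- function(rs, i) {
  read_set(rs$id[i], rs$seq[i], rs$qual[i], rs$library_label,
           if (!is.null(rs$origin)) rs$origin[i, , drop = FALSE])
}

#' Concatenate read sets
#'
#' Joins several libraries into one pool; per-read provenance is preserved
#' in the `source_library` attribute column of `origin` when present, and in
#' a `library` element of the result.
#'
#' @param ... `read_set` objects.
#' @return A pooled `read_set` with `library_label = "mixed"` and an extra
#'   `library` character vector recording each read's source library.
#' @export
join_reads <- function(...) {
  sets <- list(...)
  lib <- unlist(lapply(sets, function(s) rep(s$library_label, length(s))))
  origin <- NULL
  if (all(vapply(sets, function(s) !is.null(s$origin), logical(1)))) {
    origin <- do.call(rbind, lapply(sets, function(s) s$origin))
  }
  out <- read_set(unlist(lapply(sets, `[[`, "id")),
                  unlist(lapply(sets, `[[`, "seq")),
                  unlist(lapply(sets, `[[`, "qual")),
                  "mixed", origin)
  out$library <- lib
  out
}

.read_library <- function(rs) {
  if (!is.null(rs$library)) rs$library else rep(rs$library_label, length(rs))
}

#' Write a read set to FASTQ
#'
#' Plain 4-line records. Paired sets can be written as two files by
#' subsetting on the `/1` / `/2` id suffix beforehand.
#'
#' @param rs A `read_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(rs)) {
    rec <- paste0("@", rs$id, "\n", rs$seq, "\n+\n", rs$qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file path.
#' @param library_label Library label to attach.
#' @return A `read_set`.
#' @export
read_fastq <- function(path, library_label = "mixed") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  if (is.null(qual)) qual <- strrep("?", Biostrings::width(x))
  read_set(names(x), as.character(x), qual, library_label)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# Derive a 32-bit-safe stage seed from a master seed and a stage counter.
# Documented scheme so individual stages can be re-run independently.
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) + 7919 * as.numeric(stage)) %% 2147483647)
}
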