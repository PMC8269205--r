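## Low-level sequence utilities shared across modules. All sequences are plain
## uppercase A/C/G/T character strings; FASTA I/O goes through Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA string
#'
#' Uniform base composition over A/C/G/T, using the current RNG stream.
#'
#' @param n Length in bp.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAACCC")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("revcomp: non-ACGT characters in sequence(s): ",
         paste(head(which(bad), 3L), collapse = ", "))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming distance between two equal-length strings (byte comparison).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming: unequal lengths")
  sum(ra != rb)
}

## Substitute exactly k positions of a DNA string with different bases.
mutate_bases <- function(seq, k) {
  if (k == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

## Set of distinct k-mers of a sequence (character vector).
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

## TRUE when two sequences share at least one exact k-mer on the forward
## strand; cheap prefilter that avoids O(mn) alignments of unrelated pairs.
shares_kmer <- function(a, b, k = 16L) {
  sa <- kmer_set(a, k)
  if (length(sa) == 0) return(FALSE)
  any(sa %in% kmer_set(b, k))
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## TSV helpers with the conventions used throughout (no quoting, no rownames).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Used to compare recovered vOTU membership with planted lineage labels.
#'
#' @param x,y Vectors of cluster labels over the same items.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must cover the same items")
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- length(x)
  expected <- b * c / choose(n, 2)
  maxidx <- (b + c) / 2
  if (maxidx == expected) return(1)
  (a - expected) / (maxidx - expected)
}
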