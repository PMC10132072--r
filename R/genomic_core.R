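#' Sequence containers and coordinate conventions
#'
#' Nucleotide records are plain tibbles with columns `id`, `description` and
#' `seq` (upper-case DNA over `A`, `C`, `G`, `T`, `N`). All genomic
#' coordinates in this package are 0-based, half-open (`[start, end)`) and
#' expressed on the forward strand; minus-strand features carry forward-strand
#' coordinates plus a strand flag, so interval arithmetic is identical on both
#' strands and conversion to 1-based conventions happens only at I/O
#' boundaries.
#'
#' @name genomic-coordinates
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# default start codon set used throughout ORF calling (bacterial practice:
# ATG plus the alternative initiators the pipeline tolerates)
DEFAULT_START_CODONS <- c("ATG", "CTG", "GTG", "TTG", "ATT", "ATC")
DEFAULT_STOP_CODONS <- c("TAA", "TAG", "TGA")

assert_dna <- function(seq, arg = "seq") {
  if (!is.character(seq)) {
    abort(sprintf("`%s` must be a character vector of DNA sequences.", arg))
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains characters outside the {A,C,G,T,N} alphabet (first offender: element %d).",
      arg, which(bad)[1]
    ))
  }
  invisible(seq)
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of upper-case DNA sequences over
#'   `A`, `C`, `G`, `T`, `N`. `N` complements to `N`.
#' @return Character vector of reverse complements, same length as `seq`.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  if (length(seq) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

# codon -> amino acid lookup, bacterial/archaeal code (translation table 11)
codon_table_11 <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::getGeneticCode("11")
    gc
  }
})

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

translate_codons <- function(codons, start_as_met = FALSE,
                             start_codons = DEFAULT_START_CODONS) {
  gc <- codon_table_11()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  if (start_as_met && length(codons) >= 1 && codons[1] %in% start_codons) {
    aa[1] <- "M"
  }
  aa
}

#' Translate DNA with the bacterial/archaeal genetic code
#'
#' Translation uses NCBI translation table 11. Stop codons render `*`. A codon
#' containing `N` renders `X`. With `start_as_met = TRUE` the first codon is
#' rendered `M` when it belongs to the accepted start-codon set, matching
#' prokaryotic annotation practice for alternative initiators.
#'
#' @param seq Single DNA string; length must be a multiple of 3.
#' @param start_as_met Render an initial start codon as methionine?
#' @param start_codons Codons accepted as initiators (used only when
#'   `start_as_met = TRUE`).
#' @return Single amino-acid string (may contain `*` and `X`).
#' @examples
#' translate_dna("ATGGCA", start_as_met = TRUE)
#' translate_dna("CTGGCA", start_as_met = TRUE) # alternative start -> "MA"
#' @export
translate_dna <- function(seq, start_as_met = FALSE,
                          start_codons = DEFAULT_START_CODONS) {
  stopifnot(length(seq) == 1)
  assert_dna(seq)
  if (nchar(seq) %% 3 != 0) {
    abort(sprintf("Sequence length %d is not divisible by 3.", nchar(seq)))
  }
  paste(translate_codons(split_codons(seq), start_as_met, start_codons),
        collapse = "")
}

#' Read and write FASTA nucleotide records
#'
#' `read_fasta()` returns a tibble with columns `id`, `description`, `seq`;
#' sequences are upper-cased on read and must use only `A`, `C`, `G`, `T`,
#' `N`. Duplicate ids are rejected. `write_fasta()` accepts the same tibble
#' shape (the `description` column is optional) and wraps sequence lines.
#'
#' @param path File path.
#' @param records Tibble with columns `id`, `seq` and optionally
#'   `description`.
#' @param width Line width for sequence wrapping on output.
#' @return `read_fasta()`: a tibble; `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(tibble(id = character(), description = character(),
                  seq = character()))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tibble(id = character(), description = character(), seq = character()))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(id == "")) abort("FASTA record with empty id.")
  if (anyDuplicated(id)) {
    abort(sprintf("Duplicate FASTA id: '%s'.", id[duplicated(id)][1]))
  }
  seq <- toupper(as.character(set))
  assert_dna(seq, arg = "FASTA sequence")
  if (any(nchar(seq) == 0)) abort("FASTA record with empty sequence.")
  tibble(id = id, description = description, seq = unname(seq))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(desc == "" | is.na(desc), records$id,
                   paste(records$id, desc))
  lines <- unlist(map2(header, records$seq, function(h, s) {
    n <- nchar(s)
    starts <- seq(1, max(n, 1), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, n)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# length of a 0-based half-open interval
interval_length <- function(start, end) end - start

# gap between two half-open intervals on the same record: 0 when they
# overlap or abut, else the number of bases strictly between them
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1, start2) - pmin(end1, end2))
}
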