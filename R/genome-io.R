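#' Read genome sequences from a FASTA file
#'
#' Parses a (possibly multi-record, line-wrapped) FASTA file into a tibble
#' with one row per record. Lowercase bases are upcased; the alphabet is
#' restricted to `A`, `C`, `G`, `T` and `N` (ambiguous `N` bases are allowed
#' but counted, since downstream AT-run analysis treats them as non-AT).
#'
#' @param path Path to a FASTA file.
#'
#' @return A tibble with columns `id` (record identifier, the word after
#'   `>`), `bases` (the upcased sequence as one string), `length` (bp) and
#'   `n_ambiguous` (number of `N` bases).
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">rec1", "AATG", ">rec2", "GGCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort(paste0("empty FASTA file: ", path))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0(
      "not FASTA: line ", first, " should start with '>' but is: ",
      substr(trimws(lines[first]), 1, 40)
    ))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(set) == 0)) {
    bad <- names(set)[Biostrings::width(set) == 0][1]
    abort(paste0("FASTA record has a header but no sequence: ", bad))
  }
  bases <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(bases))
  allowed <- c("A", "C", "G", "T", "N")
  extra <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(extra > 0)) {
    abort(paste0(
      "record '", ids[which(extra > 0)[1]],
      "' contains bases outside the {A,C,G,T,N} alphabet"
    ))
  }
  tibble(
    id = ids,
    bases = unname(bases),
    length = unname(nchar(bases)),
    n_ambiguous = unname(freq[, "N"])
  )
}

#' Write genome sequences to a FASTA file
#'
#' @param genome A tibble as returned by [read_fasta()] or
#'   [generate_genome()], with columns `id` and `bases`.
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.data.frame(genome), all(c("id", "bases") %in% names(genome)))
  set <- Biostrings::DNAStringSet(genome$bases)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
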