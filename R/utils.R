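# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a protein string into a character vector of residues.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

# Cached BLOSUM62 from Biostrings (loaded lazily once per session).
.ap2erf_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.ap2erf_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ap2erf_env$BLOSUM62 <- e$BLOSUM62
  }
  .ap2erf_env$BLOSUM62
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 0) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector, the representation used throughout this package.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write proteins to a FASTA file
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(!is.null(names(proteins)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}
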