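#' Target sequence
#'
#' A target sequence is the full-length amino-acid sequence of the protein
#' being modelled.  All per-residue scores are indexed by 1-based target
#' position `1..L`; models may cover any subset of those positions.
#'
#' @param id character label for the target.
#' @param residues character vector of one-letter codes, or a single string.
#' @return An object of class `target_sequence` with fields `id` and
#'   `residues` (character vector of length `L`).
#' @examples
#' target_sequence("toy", "MKVLA")
#' @export
target_sequence <- function(id, residues) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) {
    stop("target sequence must contain at least one residue")
  }
  bad <- setdiff(unique(residues), c(AA_ONE, "X"))
  if (length(bad) > 0L) {
    stop("invalid amino-acid code(s) in target sequence: ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = as.character(id), residues = residues),
            class = "target_sequence")
}

#' @export
length.target_sequence <- function(x) length(x$residues)

#' @export
print.target_sequence <- function(x, ...) {
  cat(sprintf("<target_sequence> %s  L = %d\n", x$id, length(x)))
  cat(" ", paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Read a target sequence from a FASTA file
#'
#' The first record of the file is taken as the target.
#'
#' @param path path to a FASTA file.
#' @return A [target_sequence()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1L) stop("no sequences found in ", path)
  id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  target_sequence(id, as.character(set[[1]]))
}

#' Write a target sequence to a FASTA file
#'
#' @param target a [target_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(target, path) {
  seq <- Biostrings::AAStringSet(paste(target$residues, collapse = ""))
  names(seq) <- target$id
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

# the 20 standard one-letter codes
AA_ONE <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

# three-letter -> one-letter, including common modified residues mapped to
# their parent; anything else becomes X (matches any target letter)
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", MLY = "K", CSO = "C", KCX = "K",
  LLP = "K", CME = "C", MLE = "L", FME = "M"
)

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

aa3to1 <- function(x) {
  out <- AA_THREE_TO_ONE[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

# X is a wildcard on either side
aa_match <- function(a, b) a == b | a == "X" | b == "X"
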