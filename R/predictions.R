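#' Read PSIPRED ss2 secondary-structure probabilities
#'
#' Parses the PSIPRED VFORMAT dialect: one line per residue holding the
#' position index, residue letter, predicted state and the three state
#' probabilities in coil/helix/strand order.  Comment lines (`#`) and blank
#' lines are ignored.  Per-position probabilities are renormalized to sum to 1
#' when the raw sum lies in `[0.9, 1.1]`; anything further off is an error.
#'
#' @param text path or text of a `.ss2` file.
#' @return A numeric matrix with one row per position and columns
#'   `C`, `H`, `E`; `rownames` are positions `1..L_file`.
#' @export
read_ss2 <- function(text) {
  tok <- prediction_tokens(text, min_fields = 6)
  pos <- as.integer(vapply(tok, `[`, "", 1))
  check_contiguous(pos, "ss2")
  p <- t(vapply(tok, function(f) as.numeric(f[4:6]), numeric(3)))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("malformed probability in ss2 file (outside [0,1])")
  }
  s <- rowSums(p)
  if (any(s < 0.9 | s > 1.1)) {
    stop("malformed probability in ss2 file: row sum ",
         format(s[which(s < 0.9 | s > 1.1)[1]]), " outside [0.9, 1.1]")
  }
  p <- p / s
  dimnames(p) <- list(pos, c("C", "H", "E"))
  p
}

#' Read DISOPRED-style per-residue disorder probabilities
#'
#' Lines hold position, residue letter, an order/disorder mark and the
#' disorder probability `Pd`.
#'
#' @param text path or text of a disorder prediction file.
#' @return Named numeric vector of `Pd` per position (contiguous from 1).
#' @export
read_disorder <- function(text) {
  tok <- prediction_tokens(text, min_fields = 4)
  pos <- as.integer(vapply(tok, `[`, "", 1))
  check_contiguous(pos, "disorder")
  pd <- as.numeric(vapply(tok, `[`, "", 4))
  if (any(!is.finite(pd)) || any(pd < 0 | pd > 1)) {
    stop("malformed probability in disorder file (outside [0,1])")
  }
  names(pd) <- pos
  pd
}

#' Read CASP RR residue-residue contact predictions
#'
#' Parses `i j d1 d2 p` lines.  Pairs closer than `min_separation` in sequence
#' are dropped (short-range pairs are trivially in contact and would swamp the
#' contact agreement score); duplicate pairs keep the maximum probability.
#'
#' @param text path or text of an RR file.
#' @param L target length; positions beyond `L` are an error.
#' @param min_separation minimum `|i - j|` retained (default 5).
#' @return A data.frame with columns `i`, `j` (`i < j`) and `p`.
#' @export
read_contacts <- function(text, L, min_separation = 5L) {
  tok <- prediction_tokens(text, min_fields = 3, allow_sequence_row = TRUE)
  ij <- t(vapply(tok, function(f) as.numeric(f[1:2]), numeric(2)))
  p <- vapply(tok, function(f) as.numeric(f[length(f)]), numeric(1))
  if (any(!is.finite(ij)) || any(ij != round(ij))) {
    stop("malformed contact line: non-integer residue index")
  }
  i <- pmin(ij[, 1], ij[, 2])
  j <- pmax(ij[, 1], ij[, 2])
  if (any(i < 1 | j > L)) {
    stop("contact position out of range 1..", L)
  }
  if (any(i == j)) stop("contact pair with i == j")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("malformed contact probability (outside [0,1])")
  }
  keep <- (j - i) >= min_separation
  i <- i[keep]; j <- j[keep]; p <- p[keep]
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    p <- tapply(p, key, max)
    ij2 <- do.call(rbind, strsplit(names(p), " "))
    i <- as.integer(ij2[, 1]); j <- as.integer(ij2[, 2]); p <- unname(p)
  }
  ord <- order(i, j)
  data.frame(i = as.integer(i[ord]), j = as.integer(j[ord]), p = p[ord])
}

#' Read external per-residue local quality scores
#'
#' Two-column `position score` text, the stand-in channel for a third-party
#' local score such as ProQ2.  Scores are clipped to `[0, 1]`.
#'
#' @param text path or text.
#' @param L target length.
#' @return Named numeric vector of similarities per listed position.
#' @export
read_local_scores <- function(text, L) {
  tok <- prediction_tokens(text, min_fields = 2)
  pos <- as.integer(vapply(tok, `[`, "", 1))
  s <- as.numeric(vapply(tok, `[`, "", 2))
  if (any(pos < 1 | pos > L)) stop("local score position out of range 1..", L)
  if (any(!is.finite(s))) stop("malformed local score")
  s <- pmin(pmax(s, 0), 1)
  names(s) <- pos
  s
}

#' Bundle per-residue upstream predictions for one target
#'
#' @param target a [target_sequence()].
#' @param ss_probs matrix from [read_ss2()].
#' @param disorder_pd vector from [read_disorder()].
#' @param contact_probs data.frame from [read_contacts()].
#' @param external_local optional vector from [read_local_scores()]; when
#'   absent the corresponding score channel runs at the neutral constant 0.5.
#' @return An object of class `prediction_bundle`.
#' @export
prediction_bundle <- function(target, ss_probs, disorder_pd, contact_probs,
                              external_local = NULL) {
  L <- length(target)
  if (nrow(ss_probs) != L) {
    stop("ss_probs covers ", nrow(ss_probs), " positions but target has ", L)
  }
  if (length(disorder_pd) != L) {
    stop("disorder_pd covers ", length(disorder_pd),
         " positions but target has ", L)
  }
  if (nrow(contact_probs) > 0 && max(contact_probs$j) > L) {
    stop("contact positions exceed target length ", L)
  }
  if (!is.null(external_local) &&
      any(as.integer(names(external_local)) > L)) {
    stop("external local score positions exceed target length ", L)
  }
  structure(list(target_id = target$id, L = L,
                 ss_probs = ss_probs, disorder_pd = disorder_pd,
                 contact_probs = contact_probs,
                 external_local = external_local),
            class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("<prediction_bundle> %s: L = %d, %d contact pairs, %s\n",
              x$target_id, x$L, nrow(x$contact_probs),
              if (is.null(x$external_local)) "no external local scores"
              else "with external local scores"))
  invisible(x)
}

# tokenize a prediction file: drop comments, headers and blanks
prediction_tokens <- function(text, min_fields, allow_sequence_row = FALSE) {
  lines <- read_text_lines(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # header keywords of the CASP RR dialect and friends
  kw <- c("PFRMAT", "TARGET", "AUTHOR", "METHOD", "REMARK", "MODEL", "END",
          "RMODE", "CONF", "VFORMAT")
  lines <- lines[!toupper(sub("[ :].*$", "", lines)) %in% kw]
  tok <- strsplit(lines, "\\s+")
  if (allow_sequence_row) {  # RR files may carry the raw sequence
    tok <- Filter(function(f) !is.na(suppressWarnings(as.numeric(f[1]))), tok)
  }
  if (length(tok) == 0L) stop("no data lines found in prediction file")
  short <- which(lengths(tok) < min_fields)
  if (length(short) > 0L) {
    stop("parse error: line with fewer than ", min_fields,
         " fields: '", paste(tok[[short[1]]], collapse = " "), "'")
  }
  tok
}

check_contiguous <- function(pos, what) {
  if (any(is.na(pos))) stop("parse error in ", what, " file: bad position index")
  expect <- seq(pos[1], length.out = length(pos))
  if (pos[1] != 1L || !identical(as.integer(pos), as.integer(expect))) {
    bad <- which(as.integer(pos) != as.integer(seq_along(pos)))[1]
    stop("parse error in ", what, " file: positions not contiguous from 1 ",
         "(line ", bad, " has index ", pos[bad], ")")
  }
}
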