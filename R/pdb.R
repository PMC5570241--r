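#' Read a protein model from PDB-format text
#'
#' Parses ATOM (and recognized modified-residue HETATM) records of the first
#' chain of the first MODEL and maps each model residue to a 1-based position
#' of the target sequence.  Mapping trusts the PDB residue numbers when at
#' least 90% of them index cleanly into `1..L` with matching letters;
#' otherwise an exhaustive ungapped offset scan of the model letters against
#' the target is used, and a tie between two equally good offsets is an error
#' (the offsets are named), never a guess.
#'
#' Alternate locations are resolved to the highest occupancy (first seen on a
#' tie).  Non-standard residues are mapped to their parent one-letter code via
#' a fixed table; unknown residues become `X`, which matches any target
#' letter.  For non-glycine residues lacking a CB atom, a virtual CB is
#' synthesized from ideal N/CA/C geometry when the backbone is present;
#' otherwise CB-based scores fall back to CA for that residue.
#'
#' @param pdb path to a PDB file, or PDB-format text (character vector of
#'   lines or a single string with newlines).
#' @param target a [target_sequence()].
#' @param model_id label for the model; defaults to the file name or "model".
#' @return An object of class `protein_model`: a list with `model_id`,
#'   `target_positions` (strictly increasing integer vector), `res_codes`,
#'   coordinate matrices `ca`, `cb`, `n`, `c`, `o` (rows aligned to residues,
#'   `NA` where absent; `cb` holds the virtual or fallback-CA coordinate, with
#'   `cb_real` flagging residues that had an actual or synthesized CB),
#'   `lines` (the raw input lines) and `atom_line_res` (for each input line,
#'   the residue index it belongs to, or `NA`).
#' @export
read_model <- function(pdb, target, model_id = NULL) {
  lines <- read_text_lines(pdb)
  if (is.null(model_id)) {
    model_id <- if (length(pdb) == 1L && file.exists(pdb)) {
      sub("\\.(pdb|ent)$", "", basename(pdb))
    } else "model"
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " |
    (rec == "HETATM" & toupper(substr(lines, 18, 20)) %in% names(AA_THREE_TO_ONE))

  # first MODEL only (NMR-style multi-model files)
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0L) is_atom[seq_along(lines) > endmdl[1]] <- FALSE
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("unreadable model: no ATOM records found")

  at <- data.frame(
    line    = idx,
    name    = trimws(substr(lines[idx], 13, 16)),
    altloc  = substr(lines[idx], 17, 17),
    resname = toupper(substr(lines[idx], 18, 20)),
    chain   = substr(lines[idx], 22, 22),
    resseq  = suppressWarnings(as.integer(substr(lines[idx], 23, 26))),
    icode   = substr(lines[idx], 27, 27),
    x = as.numeric(substr(lines[idx], 31, 38)),
    y = as.numeric(substr(lines[idx], 39, 46)),
    z = as.numeric(substr(lines[idx], 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines[idx], 55, 60))),
    stringsAsFactors = FALSE
  )
  at$occ[is.na(at$occ)] <- 1.0
  at <- at[at$chain == at$chain[1], , drop = FALSE]
  if (any(is.na(at$resseq))) stop("unreadable model: unparseable residue number")

  # residue grouping in order of first appearance
  rkey <- paste(at$resseq, at$icode)
  ukey <- unique(rkey)
  nres <- length(ukey)
  res_of <- match(rkey, ukey)

  getxyz <- function(r, nm) {
    sel <- which(res_of == r & at$name == nm)
    if (length(sel) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    if (length(sel) > 1L) sel <- sel[order(-at$occ[sel])][1]  # altloc rule
    c(at$x[sel], at$y[sel], at$z[sel])
  }
  ca <- t(vapply(seq_len(nres), getxyz, numeric(3), nm = "CA"))
  has_ca <- !is.na(ca[, 1])
  if (!any(has_ca)) stop("unreadable model: no CA atoms found")
  # residues without CA cannot be scored
  keep <- which(has_ca)
  remap <- match(res_of, keep)

  ca <- ca[keep, , drop = FALSE]
  nres <- length(keep)
  cb <- t(vapply(seq_len(nres), function(r) getxyz(keep[r], "CB"), numeric(3)))
  nn <- t(vapply(seq_len(nres), function(r) getxyz(keep[r], "N"),  numeric(3)))
  cc <- t(vapply(seq_len(nres), function(r) getxyz(keep[r], "C"),  numeric(3)))
  oo <- t(vapply(seq_len(nres), function(r) getxyz(keep[r], "O"),  numeric(3)))
  if (!all(is.finite(ca))) stop("unreadable model: non-finite CA coordinate")

  res_codes <- aa3to1(at$resname[match(keep, res_of)])
  resseq    <- at$resseq[match(keep, res_of)]

  tpos <- map_to_target(resseq, res_codes, target)

  # keep residues in strictly increasing target order, drop unmappable
  ok <- !is.na(tpos)
  ord <- order(tpos[ok])
  sel <- which(ok)[ord]

  cb_real <- !is.na(cb[, 1])
  # synthesize virtual CB from ideal backbone geometry where possible
  for (r in seq_len(nres)) {
    if (!cb_real[r] && res_codes[r] != "G" &&
        all(is.finite(c(nn[r, ], cc[r, ])))) {
      cb[r, ] <- virtual_cb(nn[r, ], ca[r, ], cc[r, ])
      cb_real[r] <- TRUE
    }
  }
  cb_fallback <- is.na(cb[, 1])
  cb[cb_fallback, ] <- ca[cb_fallback, , drop = FALSE]

  atom_line_res <- rep(NA_integer_, length(lines))
  res_sel_pos <- match(seq_len(nres), sel)  # residue -> output index
  src_res <- remap[seq_len(nrow(at))]
  out_res <- res_sel_pos[src_res]
  atom_line_res[at$line] <- out_res

  structure(list(
    model_id = model_id,
    target_id = target$id,
    target_positions = as.integer(tpos[sel]),
    res_codes = res_codes[sel],
    ca = ca[sel, , drop = FALSE],
    cb = cb[sel, , drop = FALSE],
    cb_real = cb_real[sel],
    n = nn[sel, , drop = FALSE],
    c = cc[sel, , drop = FALSE],
    o = oo[sel, , drop = FALSE],
    lines = lines,
    atom_line_res = atom_line_res,
    source_path = if (length(pdb) == 1L && file.exists(pdb)) pdb else NA_character_
  ), class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d residues, target positions %d..%d\n",
              x$model_id, length(x$target_positions),
              min(x$target_positions), max(x$target_positions)))
  invisible(x)
}

# Decide target positions for model residues.  resseq/res_codes per model
# residue (CA-bearing, file order).  Returns vector of target positions or NA.
map_to_target <- function(resseq, res_codes, target) {
  L <- length(target)
  tl <- target$residues
  in_range <- resseq >= 1L & resseq <= L
  direct_match <- in_range & aa_match(res_codes, ifelse(in_range, tl[pmax(resseq, 1L)], ""))
  if (mean(direct_match) >= 0.9) {
    tpos <- ifelse(direct_match, resseq, NA_integer_)
    # two residues must never claim one position: keep first
    tpos[duplicated(tpos, incomparables = NA)] <- NA_integer_
    return(tpos)
  }
  # ungapped best-offset scan
  offs <- seq(1L - min(resseq), L - max(resseq))
  if (length(offs) == 0L) {
    stop("mapping error: model numbering span exceeds target length")
  }
  score <- vapply(offs, function(off) {
    p <- resseq + off
    sum(aa_match(res_codes, tl[p]))
  }, numeric(1))
  best <- max(score)
  winners <- offs[score == best]
  if (length(winners) > 1L) {
    stop("mapping error: ambiguous residue mapping; offsets ",
         paste(winners, collapse = " and "),
         " match equally well (", best, " residues)")
  }
  tpos <- resseq + winners
  tpos[!aa_match(res_codes, tl[tpos])] <- NA_integer_
  tpos[duplicated(tpos, incomparables = NA)] <- NA_integer_
  tpos
}

# virtual CB from ideal tetrahedral geometry about CA (standard constants)
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Write a model with per-residue errors in the B-factor column
#'
#' Replaces columns 61-66 of every ATOM record of each scored residue with the
#' residue's predicted error in Angstroms (`%6.2f`).  All other columns are
#' passed through byte-identically from the input.  Errors of 1000 A or more
#' are clamped to 999.99 with a warning.
#'
#' @param model a `protein_model` from [read_model()].
#' @param per_residue_error named numeric vector of errors in Angstroms; names
#'   are target positions.  Every residue of the model must have a value.
#' @param path optional output path; when `NULL` the text is returned.
#' @return The annotated PDB lines (invisibly when `path` is given).
#' @export
write_annotated_model <- function(model, per_residue_error, path = NULL) {
  pos <- model$target_positions
  err <- per_residue_error[as.character(pos)]
  if (any(is.na(err))) {
    stop("missing error value for target position(s) ",
         paste(pos[is.na(err)], collapse = ", "))
  }
  if (any(err >= 1000)) {
    warning(sum(err >= 1000), " error value(s) >= 1000 A clamped to 999.99")
    err <- pmin(err, 999.99)
  }
  lines <- model$lines
  li <- which(!is.na(model$atom_line_res))
  for (i in li) {
    r <- model$atom_line_res[i]
    ln <- lines[i]
    if (nchar(ln) < 66) ln <- formatC(ln, width = -66)
    substr(ln, 61, 66) <- sprintf("%6.2f", err[r])
    lines[i] <- ln
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write a protein model as minimal PDB text
#'
#' Serializes the stored backbone/CB coordinates as fresh ATOM records
#' numbered by target position.  Used by the fixture generator; for annotating
#' user-supplied files see [write_annotated_model()], which preserves the
#' original records.
#'
#' @param model a `protein_model` or bare coordinate list from the fixture
#'   generator.
#' @param path optional output path.
#' @param bfactor per-residue B-factor values (recycled); default 0.
#' @return PDB lines (invisibly when `path` is given).
#' @export
write_pdb <- function(model, path = NULL, bfactor = 0) {
  pos <- model$target_positions
  nres <- length(pos)
  bf <- rep_len(bfactor, nres)
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(nres)) {
    res3 <- AA_ONE_TO_THREE[model$res_codes[r]]
    if (is.na(res3)) res3 <- "UNK"
    emit <- function(nm, xyz, el) {
      if (any(!is.finite(xyz))) return(invisible(NULL))
      serial <<- serial + 1L
      lines <<- c(lines, sprintf(
        "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", formatC(nm, width = -3)), res3, pos[r],
        xyz[1], xyz[2], xyz[3], 1.00, bf[r], el))
      invisible(NULL)
    }
    if (!is.null(model$n)) emit("N", model$n[r, ], "N")
    emit("CA", model$ca[r, ], "C")
    if (!is.null(model$c)) emit("C", model$c[r, ], "C")
    if (!is.null(model$o)) emit("O", model$o[r, ], "O")
    if (!is.null(model$cb) && isTRUE(model$cb_real[r]) &&
        model$res_codes[r] != "G") emit("CB", model$cb[r, ], "C")
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# accept a path, a single string with newlines, or a vector of lines
read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  as.character(x)
}
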