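#' Write a CASP QA (QMODE 2) record for one model
#'
#' Emits the standard machine-readable QA block: `PFRMAT QA`, target and
#' method headers, `QMODE 2`, then the model name, its global score and the
#' predicted per-residue error in Angstroms for positions `1..L` (`X` where
#' the model leaves a position unpredicted), wrapped 20 values per line, and
#' `END`.  Errors are printed with two decimals, matching the B-factor field
#' of the annotated PDB.
#'
#' @param result a `qa_result`.
#' @param path output path.
#' @param author free-text AUTHOR field.
#' @return `path`, invisibly.
#' @export
write_casp_qa <- function(result, path, author = "modqa6") {
  L <- result$L
  err <- rep("X", L)
  pos <- as.integer(names(result$per_residue_error))
  err[pos] <- sprintf("%.2f", result$per_residue_error)
  vals <- c(sprintf("%.4f", result$variants[[result$variant]]), err)
  rows <- split(vals, ceiling(seq_along(vals) / 20))
  body <- vapply(rows, paste, "", collapse = " ")
  body[1] <- paste(result$model_id, body[1])
  lines <- c("PFRMAT QA",
             paste("TARGET", result$target_id),
             paste("AUTHOR", author),
             "METHOD modqa6 hybrid pure/quasi-single model quality assessment",
             "QMODE 2",
             unname(body),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP QA (QMODE 2) record written by [write_casp_qa()]
#'
#' @param path path to a `.qa` file.
#' @param L target length.
#' @return List with `model_id`, `global` and `errors` (length `L`, `NA`
#'   where the record holds `X`).
#' @export
read_casp_qa <- function(path, L) {
  lines <- readLines(path, warn = FALSE)
  kw <- c("PFRMAT", "TARGET", "AUTHOR", "METHOD", "QMODE", "END", "REMARK")
  body <- lines[!sub(" .*$", "", lines) %in% kw & nzchar(trimws(lines))]
  tok <- unlist(strsplit(trimws(body), "\\s+"))
  model_id <- tok[1]
  global <- as.numeric(tok[2])
  err <- tok[-(1:2)]
  if (length(err) != L) {
    stop("QA record holds ", length(err), " per-residue values, expected ", L)
  }
  errors <- suppressWarnings(as.numeric(err))
  list(model_id = model_id, global = global, errors = errors)
}

#' Write the per-residue score TSV for one model
#'
#' Full-precision table: target position, residue coverage, the six component
#' scores, the consensus similarity and the predicted error in Angstroms.
#'
#' @param result a `qa_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_local_tsv <- function(result, path) {
  L <- result$L
  tab <- result$local_scores
  cov <- seq_len(L) %in% attr(tab, "covered")
  sim <- err <- rep(NA_real_, L)
  pos <- as.integer(names(result$per_residue_similarity))
  sim[pos] <- result$per_residue_similarity
  err[pos] <- result$per_residue_error
  df <- data.frame(position = seq_len(L), covered = as.integer(cov),
                   tab, consensus = sim, error_A = err, check.names = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE, nsmall = 0),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the run summary TSV
#'
#' One row per scored model with the ten global scores, the three variants
#' and the P-value, in the order produced by [run_qa()] (chosen variant,
#' descending).
#'
#' @param summary data.frame from [run_qa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  out <- summary
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
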