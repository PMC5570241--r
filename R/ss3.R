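#' Three-state secondary structure from model coordinates
#'
#' Assigns H (helix), E (strand) or C (everything else) per model residue
#' using the Kabsch-Sander hydrogen-bond energy model.  The amide hydrogen is
#' placed 1 A from N opposite the preceding carbonyl, the electrostatic bond
#' energy is
#' `E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol, and a
#' bond exists when `E < -0.5` kcal/mol.  Two consecutive `i -> i+4` turns
#' make residues `i+1..i+4` helical; ladders of at least two consecutive
#' parallel or antiparallel bridges make their residues strand.  The
#' remaining eight-state detail (3/10 and pi helices, isolated bridges, turns,
#' bends) all reduces to C, matching the standard 8-to-3 reduction in which
#' only H and E are preserved.  Residues in stretches lacking full backbone
#' N/CA/C/O coordinates are assigned C.
#'
#' @param model a `protein_model`.
#' @return Named character vector (H/E/C) over the model's target positions,
#'   class `ss3_string`.
#' @export
assign_ss3 <- function(model) {
  pos <- model$target_positions
  n <- length(pos)
  ss <- rep("C", n)
  names(ss) <- pos
  if (is.null(model$n) || is.null(model$c) || is.null(model$o) || n < 5L) {
    return(structure(ss, class = c("ss3_string", class(ss))))
  }
  complete <- rowSums(!is.finite(model$n)) == 0 &
    rowSums(!is.finite(model$c)) == 0 &
    rowSums(!is.finite(model$o)) == 0 &
    rowSums(!is.finite(model$ca)) == 0
  # chain continuity: residue i-1 immediately precedes i in target numbering
  prev_ok <- c(FALSE, diff(pos) == 1L)

  # amide H on N, 1 A along the previous C=O direction (DSSP convention);
  # proline has no amide hydrogen and cannot donate
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (complete[i] && prev_ok[i] && complete[i - 1L] &&
        model$res_codes[i] != "P") {
      co <- model$c[i - 1L, ] - model$o[i - 1L, ]
      H[i, ] <- model$n[i, ] + co / sqrt(sum(co^2))
    }
  }

  # hb[i, j]: N-H of residue i donates to C=O of residue j
  hb <- matrix(FALSE, n, n)
  q1q2f <- 0.084 * 332
  for (i in seq_len(n)) {
    if (any(!is.finite(H[i, ]))) next
    for (j in seq_len(n)) {
      if (j == i || j == i - 1L || !complete[j]) next
      if (sum((model$ca[i, ] - model$ca[j, ])^2) > 81) next  # 9 A speed gate
      dON <- sqrt(sum((model$o[j, ] - model$n[i, ])^2))
      dCH <- sqrt(sum((model$c[j, ] - H[i, ])^2))
      dOH <- sqrt(sum((model$o[j, ] - H[i, ])^2))
      dCN <- sqrt(sum((model$c[j, ] - model$n[i, ])^2))
      if (min(dON, dCH, dOH, dCN) < 0.5) { hb[i, j] <- TRUE; next }
      e <- q1q2f * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      if (e < -0.5) hb[i, j] <- TRUE
    }
  }

  # bonds must respect chain continuity in index space vs sequence space:
  # work in sequence positions to honour gaps
  turn4 <- rep(FALSE, n)  # turn4[i]: hb from i+4 to i with contiguous span
  for (i in seq_len(n - 4L)) {
    if (pos[i + 4L] - pos[i] == 4L && hb[i + 4L, i]) turn4[i] <- TRUE
  }
  for (i in seq_len(max(0L, n - 5L))) {
    if (turn4[i] && turn4[i + 1L]) ss[(i + 1L):(i + 4L)] <- "H"
  }

  # bridges (Kabsch-Sander): parallel and antiparallel patterns
  bridge <- matrix(0L, n, n)  # 1 parallel, 2 antiparallel
  inner <- function(i) i >= 2L && i <= n - 1L && prev_ok[i] &&
    (pos[i + 1L] - pos[i] == 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) < 3L) next
      if (inner(i) && inner(j)) {
        par <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
               (hb[j - 1L, i] && hb[i, j + 1L])
        anti <- (hb[i, j] && hb[j, i]) ||
                (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
        if (par) bridge[i, j] <- 1L
        else if (anti) bridge[i, j] <- 2L
      }
    }
  }
  # ladders: two or more consecutive bridges of the same type
  strand <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(n)) {
      b <- bridge[i, j]
      if (b == 0L) next
      nxt <- if (b == 1L) j + 1L else j - 1L
      if (nxt >= 1L && nxt <= n && bridge[i + 1L, nxt] == b) {
        strand[c(i, i + 1L, j, nxt)] <- TRUE
      }
    }
  }
  ss[strand & ss != "H"] <- "E"
  structure(ss, class = c("ss3_string", class(ss)))
}

#' @export
print.ss3_string <- function(x, ...) {
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}
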