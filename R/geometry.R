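#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares fits `P` onto `Q` over paired points, enforcing a proper
#' rotation (determinant +1) via the usual sign correction of the smallest
#' singular vector.
#'
#' @param P,Q `n x 3` coordinate matrices of paired points, `n >= 3`.
#' @return A list with `rotation` (3x3), `translation` (length 3) such that
#'   `P %*% t(rotation) + translation` best matches `Q`, and `rmsd` in
#'   Angstroms.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets must be paired")
  if (nrow(P) < 3L) stop("insufficient points: Kabsch needs n >= 3")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)         # rotation applied as P %*% t(R)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

apply_transform <- function(X, rotation, translation) {
  sweep(X %*% t(rotation), 2, translation, "+")
}

# TM-score distance scale; floor of 0.5 A covers short targets where the
# Zhang-Skolnick formula goes non-positive
tm_d0 <- function(L_norm) {
  if (L_norm <= 15) return(0.5)
  max(0.5, 1.24 * (L_norm - 15)^(1/3) - 1.8)
}

#' TM-score superposition of two models
#'
#' Runs the iterative-extension TM-score search over the target positions the
#' two models share: seed fragments of decreasing length are superposed by
#' [kabsch()], then pairs closer than a `d0`-derived cutoff are kept and
#' re-superposed until the kept set repeats (at most 20 iterations).  The
#' returned frame is the one maximizing
#' `TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = max(0.5, 1.24 (L_norm - 15)^(1/3) - 1.8)`.
#'
#' @param model_a,model_b `protein_model` objects for the same target.
#' @param L_norm normalizing length, conventionally the full target length.
#' @return An object of class `superposition`: `rotation`, `translation`
#'   (mapping `model_a` CA onto `model_b`'s frame), `per_residue_d` (named by
#'   common target position, Angstroms), `tm_score`, `aligned_count`, `d0`.
#' @export
tm_superpose <- function(model_a, model_b, L_norm) {
  common <- intersect(model_a$target_positions, model_b$target_positions)
  n <- length(common)
  if (n < 5L) stop("no-overlap error: models share only ", n,
                   " target positions (need >= 5)")
  common <- sort(common)
  A <- model_a$ca[match(common, model_a$target_positions), , drop = FALSE]
  B <- model_b$ca[match(common, model_b$target_positions), , drop = FALSE]
  d0 <- tm_d0(L_norm)

  tm_of <- function(d) sum(1 / (1 + (d / d0)^2)) / L_norm
  best <- NULL
  consider <- function(R, t) {
    d <- sqrt(rowSums((apply_transform(A, R, t) - B)^2))
    tm <- tm_of(d)
    if (is.null(best) || tm > best$tm) {
      best <<- list(tm = tm, d = d, rotation = R, translation = t)
    }
  }

  frag_lengths <- unique(pmax(4L, c(n, n %/% 2L, n %/% 4L)))
  for (f in frag_lengths) {
    starts <- seed_starts(n, f)
    for (s in starts) {
      sel <- s:(s + f - 1L)
      prev_sel <- integer(0)
      for (iter in 1:20) {
        if (length(sel) < 3L) break
        k <- kabsch(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
        d <- sqrt(rowSums((apply_transform(A, k$rotation, k$translation) - B)^2))
        consider(k$rotation, k$translation)
        cutoff <- d0
        repeat {
          new_sel <- which(d < cutoff)
          if (length(new_sel) >= 3L) break
          cutoff <- cutoff + 0.5
        }
        if (identical(new_sel, sel) || identical(new_sel, prev_sel)) break
        prev_sel <- sel
        sel <- new_sel
      }
    }
  }
  names(best$d) <- common
  structure(list(rotation = best$rotation, translation = best$translation,
                 per_residue_d = best$d, tm_score = best$tm,
                 aligned_count = n, d0 = d0, L_norm = L_norm),
            class = "superposition")
}

# evenly spaced seed start positions, capped so the search stays fast
seed_starts <- function(n, f) {
  last <- n - f + 1L
  if (last <= 1L) return(1L)
  k <- min(last, 10L)
  unique(as.integer(round(seq(1L, last, length.out = k))))
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> TM-score %.4f over %d residues (d0 = %.2f A)\n",
              x$tm_score, x$aligned_count, x$d0))
  invisible(x)
}

# side-chain proxy coordinates: CB, CA for glycine (or when CB missing)
contact_coords <- function(model) {
  xyz <- model$cb
  gly <- model$res_codes == "G"
  xyz[gly, ] <- model$ca[gly, , drop = FALSE]
  xyz
}

#' Residue contacts realized in a model
#'
#' All unordered residue pairs at sequence separation `|i - j| >=
#' min_separation` whose CB-CB distance (CA for glycine) is at most
#' `threshold` Angstroms.
#'
#' @param model a `protein_model`.
#' @param threshold contact distance cutoff in Angstroms (default 8.0).
#' @param min_separation minimum sequence separation (default 5).
#' @return data.frame with columns `i`, `j` (target positions, `i < j`) and
#'   `d` (distance in Angstroms).
#' @export
model_contacts <- function(model, threshold = 8.0, min_separation = 5L) {
  pos <- model$target_positions
  if (length(pos) < 2L) stop("model has fewer than 2 residues")
  xyz <- contact_coords(model)
  D <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(pos, pos, "-"))
  hit <- which(upper.tri(D) & D <= threshold & sep >= min_separation,
               arr.ind = TRUE)
  data.frame(i = pos[hit[, 1]], j = pos[hit[, 2]],
             d = D[hit])
}

#' Superposition-free local Q-score between two models
#'
#' For each target position `i` shared by both models, the mean over shared
#' partner positions `j != i` of `exp(-(d_ij^a - d_ij^b)^2 / width^2)`, where
#' `d_ij` are intramolecular CB-CB distances (CA for glycine) in Angstroms.
#' With the default unit width this is the Levitt-Gerstein-family similarity
#' used by Q-score based model comparison; no superposition is involved, so
#' the score is invariant under rigid motion of either model.
#'
#' @param model_a,model_b `protein_model` objects for the same target.
#' @param width Gaussian width in Angstroms (default 1).
#' @param min_separation minimum `|i - j|` for partner pairs (default 1, i.e.
#'   all partners).
#' @return Named numeric vector over shared target positions; positions with
#'   no eligible partner are `NA`.
#' @export
local_qscore <- function(model_a, model_b, width = 1, min_separation = 1L) {
  common <- sort(intersect(model_a$target_positions, model_b$target_positions))
  if (length(common) < 1L) stop("models share no target positions")
  Xa <- contact_coords(model_a)[match(common, model_a$target_positions), , drop = FALSE]
  Xb <- contact_coords(model_b)[match(common, model_b$target_positions), , drop = FALSE]
  Da <- as.matrix(stats::dist(Xa))
  Db <- as.matrix(stats::dist(Xb))
  S <- exp(-((Da - Db) / width)^2)
  sep <- abs(outer(common, common, "-"))
  S[sep < min_separation] <- NA
  diag(S) <- NA
  q <- rowMeans(S, na.rm = TRUE)
  q[!is.finite(q)] <- NA
  names(q) <- common
  q
}
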