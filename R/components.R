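#' Contact Distance Agreement (CDA)
#'
#' Pure-single per-residue score: for each residue, the mean predicted contact
#' probability over the contacts that residue realizes in the model (CB-CB
#' distance at most 8 A by default) and for which a prediction exists, i.e.
#' `CDA = (sum p) / c` with `c` the number of model contacts of the residue
#' covered by the predictions.  Residues with `c = 0` are absent (`NA`).
#'
#' @param model a `protein_model`.
#' @param contact_probs data.frame from [read_contacts()].
#' @param threshold contact cutoff in Angstroms.
#' @param min_separation minimum sequence separation.
#' @return Named numeric vector over the model's target positions.
#' @export
cda <- function(model, contact_probs, threshold = 8.0, min_separation = 5L) {
  mc <- model_contacts(model, threshold = threshold,
                       min_separation = min_separation)
  pos <- model$target_positions
  out <- rep(NA_real_, length(pos))
  names(out) <- pos
  if (nrow(mc) == 0L || nrow(contact_probs) == 0L) return(out)
  key <- paste(mc$i, mc$j)
  pkey <- paste(contact_probs$i, contact_probs$j)
  p <- contact_probs$p[match(key, pkey)]
  hit <- !is.na(p)
  if (!any(hit)) return(out)
  ends <- c(mc$i[hit], mc$j[hit])
  pp <- c(p[hit], p[hit])
  m <- tapply(pp, ends, mean)
  out[names(out) %in% names(m)] <- m[names(out)[names(out) %in% names(m)]]
  out
}

#' Secondary Structure Agreement (SSA)
#'
#' Pure-single per-residue score: the predicted probability (PSIPRED-style
#' `pC`/`pH`/`pE`) of the three-state secondary-structure class the residue
#' actually adopts in the model according to [assign_ss3()].
#'
#' @param model a `protein_model`.
#' @param ss_probs matrix from [read_ss2()] covering the full target.
#' @return Named numeric vector over the model's target positions.
#' @export
ssa <- function(model, ss_probs) {
  ss <- assign_ss3(model)
  pos <- model$target_positions
  out <- ss_probs[cbind(pos, match(unclass(ss), c("C", "H", "E")))]
  names(out) <- pos
  out
}

#' Quasi-single distance similarity (ModFOLD5_single-style local score)
#'
#' The model is superposed against every reference model with
#' [tm_superpose()]; the per-residue distances are averaged over references
#' (weighted, default uniform) and the mean distance `dbar` converts to a
#' similarity via `S_r = 1 / (1 + (dbar / 3.9)^2)`.
#'
#' @param model a `protein_model`.
#' @param ensemble a [reference_ensemble()] or list of `protein_model`.
#' @param L target length used for TM-score normalization.
#' @param profile optional precomputed [quasi_profile()].
#' @return List with `score` and `dbar`, both named by target position.
#' @export
mf5s_local <- function(model, ensemble, L, profile = NULL) {
  if (is.null(profile)) profile <- quasi_profile(model, ensemble, L)
  list(score = distance_to_similarity(profile$dbar), dbar = profile$dbar)
}

#' Quasi-single local Q-score (ModFOLDclustQ_single-style local score)
#'
#' Per-residue mean over the reference ensemble of the superposition-free
#' local Q-score ([local_qscore()]) between the model and each reference.
#'
#' @inheritParams mf5s_local
#' @return Named numeric vector over the model's target positions.
#' @export
mfcqs_local <- function(model, ensemble, L, profile = NULL) {
  if (is.null(profile)) profile <- quasi_profile(model, ensemble, L)
  profile$qbar
}

#' Disorder B-factor Agreement (DBA)
#'
#' Quasi-single per-residue score relating predicted disorder to the
#' quasi-single predicted accuracy: `DBA = 1 - |S_r - (1 - P_d)|`, where `S_r`
#' is the distance-similarity score of [mf5s_local()] and `P_d` the predicted
#' probability of disorder.  A residue predicted disordered should not be
#' confidently placed, and vice versa.
#'
#' @param mf5s_scores named numeric vector (`score` element of
#'   [mf5s_local()]).
#' @param disorder_pd vector from [read_disorder()] over the full target.
#' @return Named numeric vector over the same positions as `mf5s_scores`;
#'   absent `S_r` propagates as `NA`.
#' @export
dba <- function(mf5s_scores, disorder_pd) {
  pd <- disorder_pd[as.integer(names(mf5s_scores))]
  out <- 1 - abs(mf5s_scores - (1 - pd))
  names(out) <- names(mf5s_scores)
  out
}

#' Global score of one per-residue track
#'
#' The sum of the per-residue similarity scores divided by the full target
#' length: positions not covered by the model (or with an undefined score)
#' contribute zero, so incomplete models are penalized proportionally.
#'
#' @param scores named numeric vector of per-residue similarities (`NA`
#'   allowed).
#' @param L target length.
#' @return A value in `[0, 1]`.
#' @export
component_global <- function(scores, L) {
  if (length(scores) == 0L) return(0)
  sum(pmin(pmax(scores, 0), 1), na.rm = TRUE) / L
}

#' Reference ensemble of models for quasi-single scoring
#'
#' @param models list of `protein_model` objects for the same target.
#' @param weights optional per-model weights (default uniform).
#' @return Object of class `reference_ensemble`.
#' @export
reference_ensemble <- function(models, weights = NULL) {
  if (length(models) < 2L) {
    stop("reference ensemble needs at least 2 models")
  }
  tid <- unique(vapply(models, function(m) m$target_id, ""))
  if (length(tid) > 1L) stop("ensemble models map to different targets")
  if (is.null(weights)) weights <- rep(1, length(models))
  if (length(weights) != length(models) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("invalid ensemble weights")
  }
  structure(list(models = models, weights = weights / sum(weights)),
            class = "reference_ensemble")
}

#' @export
print.reference_ensemble <- function(x, ...) {
  cat(sprintf("<reference_ensemble> %d models\n", length(x$models)))
  invisible(x)
}

as_ensemble <- function(x) {
  if (inherits(x, "reference_ensemble")) x else reference_ensemble(x)
}

#' Precompute all model-vs-ensemble comparisons
#'
#' Superposes the model on every usable reference and computes per-residue
#' distance and local Q-score profiles plus the per-reference TM and global
#' Q-scores.  Shared by the quasi-single component scores and the clustering
#' style global scores so each reference is visited once.
#'
#' @inheritParams mf5s_local
#' @return List with `dbar`, `qbar` (named by model target position),
#'   `tm_scores`, `global_q` (per usable reference) and `weights`.
#' @export
quasi_profile <- function(model, ensemble, L) {
  ensemble <- as_ensemble(ensemble)
  pos <- model$target_positions
  npos <- length(pos)
  dsum <- qsum <- dw <- qw <- rep(0, npos)
  tms <- gq <- wts <- numeric(0)
  for (k in seq_along(ensemble$models)) {
    ref <- ensemble$models[[k]]
    w <- ensemble$weights[k]
    sup <- tryCatch(tm_superpose(model, ref, L), error = function(e) NULL)
    if (is.null(sup)) next
    q <- local_qscore(model, ref)
    idx <- match(as.integer(names(sup$per_residue_d)), pos)
    dsum[idx] <- dsum[idx] + w * sup$per_residue_d
    dw[idx] <- dw[idx] + w
    qidx <- match(as.integer(names(q)), pos)
    ok <- !is.na(q)
    qsum[qidx[ok]] <- qsum[qidx[ok]] + w * q[ok]
    qw[qidx[ok]] <- qw[qidx[ok]] + w
    tms <- c(tms, sup$tm_score)
    gq <- c(gq, sum(q, na.rm = TRUE) / L)
    wts <- c(wts, w)
  }
  if (length(tms) == 0L) {
    warning("no reference model overlaps the model; quasi-single scores absent")
    na <- rep(NA_real_, npos)
    names(na) <- pos
    return(list(dbar = na, qbar = na, tm_scores = numeric(0),
                global_q = numeric(0), weights = numeric(0)))
  }
  dbar <- ifelse(dw > 0, dsum / dw, NA_real_)
  qbar <- ifelse(qw > 0, qsum / qw, NA_real_)
  names(dbar) <- names(qbar) <- pos
  list(dbar = dbar, qbar = qbar, tm_scores = tms, global_q = gq,
       weights = wts / sum(wts))
}

#' Per-residue component score table for one model
#'
#' Assembles the six score tracks (CDA, SSA, ProQ2, DBA, MF5s, MFcQs) into an
#' `L x 6` matrix aligned to target positions; positions not covered by the
#' model are `NA` for every method, as are undefined scores.
#'
#' @param model a `protein_model`.
#' @param bundle a [prediction_bundle()].
#' @param ensemble a [reference_ensemble()].
#' @param external_local optional per-model external local scores (overrides
#'   the bundle channel); `NULL` leaves the ProQ2 column absent where no data
#'   exists.
#' @param profile optional precomputed [quasi_profile()].
#' @param threshold,min_separation contact definition passed to [cda()].
#' @return Numeric matrix of class `local_score_table`, rows `1..L`, columns
#'   `CDA`, `SSA`, `ProQ2`, `DBA`, `MF5s`, `MFcQs`.
#' @export
local_score_table <- function(model, bundle, ensemble,
                              external_local = bundle$external_local,
                              profile = NULL,
                              threshold = 8.0, min_separation = 5L) {
  L <- bundle$L
  methods <- c("CDA", "SSA", "ProQ2", "DBA", "MF5s", "MFcQs")
  tab <- matrix(NA_real_, nrow = L, ncol = length(methods),
                dimnames = list(seq_len(L), methods))
  pos <- model$target_positions
  if (is.null(profile)) profile <- quasi_profile(model, ensemble, L)
  m5 <- mf5s_local(model, ensemble, L, profile = profile)
  tab[pos, "CDA"] <- cda(model, bundle$contact_probs, threshold = threshold,
                         min_separation = min_separation)
  tab[pos, "SSA"] <- ssa(model, bundle$ss_probs)
  if (!is.null(external_local)) {
    ppos <- intersect(as.integer(names(external_local)), pos)
    tab[ppos, "ProQ2"] <- pmin(pmax(external_local[as.character(ppos)], 0), 1)
  }
  tab[pos, "MF5s"] <- m5$score
  tab[pos, "MFcQs"] <- mfcqs_local(model, ensemble, L, profile = profile)
  tab[pos, "DBA"] <- dba(m5$score, bundle$disorder_pd)
  structure(tab, class = c("local_score_table", class(tab)),
            covered = pos)
}
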