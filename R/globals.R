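QA_GLOBAL_NAMES <- c("CDA", "SSA", "ProQ2", "DBA", "MF5s", "MFcQs",
                     "MFclust_s", "MFclustQ_s", "MFclust2_s", "ModFOLD6")
QA_VARIANT_NAMES <- c("ModFOLD6", "ModFOLD6_cor", "ModFOLD6_rank")

#' Quasi-single clustering-style global scores
#'
#' Three global scores in the style of the ModFOLDclust family, computed
#' against the reference ensemble instead of a pool of submitted models:
#' `MFclust_s` is the mean TM-score of the model against each reference,
#' `MFclustQ_s` the mean over references of the model's global Q-score
#' (summed local Q divided by the full target length), and `MFclust2_s`
#' their midpoint.
#'
#' @inheritParams mf5s_local
#' @return Named numeric vector `c(MFclust_s, MFclustQ_s, MFclust2_s)`, all
#'   `NA` when no reference overlaps the model.
#' @export
clust_singles <- function(model, ensemble, L, profile = NULL) {
  if (is.null(profile)) profile <- quasi_profile(model, ensemble, L)
  if (length(profile$tm_scores) == 0L) {
    return(c(MFclust_s = NA_real_, MFclustQ_s = NA_real_,
             MFclust2_s = NA_real_))
  }
  w <- profile$weights
  cl <- sum(w * profile$tm_scores)
  cq <- sum(w * profile$global_q)
  c(MFclust_s = cl, MFclustQ_s = cq, MFclust2_s = (cl + cq) / 2)
}

# mean over named members; when some are missing, fall back to the mean of
# the available ones and flag the result degraded
combine_globals <- function(globals, members, label) {
  have <- members[members %in% names(globals) & !is.na(globals[members])]
  if (length(have) < length(members)) {
    warning(label, ": missing global score(s) ",
            paste(setdiff(members, have), collapse = ", "),
            "; using the mean of the available components (degraded)")
  }
  if (length(have) == 0L) return(structure(NA_real_, degraded = TRUE))
  out <- mean(globals[have])
  if (length(have) < length(members)) attr(out, "degraded") <- TRUE
  out
}

#' Correlation-optimized global score combination
#'
#' `(MFclustQ_s + DBA + ModFOLD6) / 3`: the three-way mean found to give
#' global scores closest to linear in the observed quality.
#'
#' @param globals named numeric vector containing at least `MFclustQ_s`,
#'   `DBA` and `ModFOLD6`.
#' @return The mean (with attribute `degraded` if members were missing).
#' @export
modfold6_cor <- function(globals) {
  combine_globals(globals, c("MFclustQ_s", "DBA", "ModFOLD6"), "ModFOLD6_cor")
}

#' Ranking-optimized global score combination
#'
#' `(MFclustQ_s + ProQ2 + CDA + DBA + SSA + ModFOLD6) / 6`: the six-way mean
#' found to put the most accurate model at the top of the ranking.  When the
#' external ProQ2 channel is unavailable its global is absent and the mean of
#' the remaining members is used (flagged degraded).
#'
#' @param globals named numeric vector of global scores.
#' @return The mean (with attribute `degraded` if members were missing).
#' @export
modfold6_rank <- function(globals) {
  combine_globals(globals,
                  c("MFclustQ_s", "ProQ2", "CDA", "DBA", "SSA", "ModFOLD6"),
                  "ModFOLD6_rank")
}
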