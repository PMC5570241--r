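#' Score a single model
#'
#' Runs the full per-model pipeline: the six component score tracks, the
#' sliding-window combiner, the similarity-to-Angstrom conversion, the ten
#' global scores, the three optimized variants and (when a calibration is
#' supplied) the P-value that the model's similarity to the native is random.
#'
#' @param model a `protein_model`.
#' @param target the [target_sequence()].
#' @param bundle a [prediction_bundle()].
#' @param ensemble a [reference_ensemble()].
#' @param network a [combiner_network()].
#' @param calibration optional named list of `calibration_curve`s (per
#'   variant); when absent the P-value is omitted, never fabricated.
#' @param external_local optional per-model external local scores.
#' @param variant variant whose calibration curve supplies the P-value.
#' @return Object of class `qa_result`: `model_id`, `local_scores` (the
#'   component table), `per_residue_similarity`, `per_residue_error`
#'   (Angstroms), `globals` (10 scores), `variants` (3 scores), `p_value`.
#' @export
score_model <- function(model, target, bundle, ensemble, network,
                        calibration = NULL,
                        external_local = bundle$external_local,
                        variant = "ModFOLD6") {
  L <- length(target)
  profile <- quasi_profile(model, ensemble, L)
  tab <- local_score_table(model, bundle, ensemble,
                           external_local = external_local,
                           profile = profile)
  consensus <- predict_local(network, tab)
  errors <- similarity_to_distance(consensus)
  names(errors) <- names(consensus)

  globals <- c(
    CDA = component_global(tab[, "CDA"], L),
    SSA = component_global(tab[, "SSA"], L),
    ProQ2 = if (all(is.na(tab[, "ProQ2"]))) NA_real_
            else component_global(tab[, "ProQ2"], L),
    DBA = component_global(tab[, "DBA"], L),
    MF5s = component_global(tab[, "MF5s"], L),
    MFcQs = component_global(tab[, "MFcQs"], L),
    clust_singles(model, ensemble, L, profile = profile),
    ModFOLD6 = component_global(consensus, L)
  )
  variants <- c(ModFOLD6 = unname(globals["ModFOLD6"]),
                ModFOLD6_cor = as.numeric(modfold6_cor(globals)),
                ModFOLD6_rank = as.numeric(modfold6_rank(globals)))
  pv <- NA_real_
  if (!is.null(calibration) && variant %in% names(calibration) &&
      !is.na(variants[variant])) {
    pv <- p_value(variants[[variant]], calibration[[variant]])
  }
  structure(list(model_id = model$model_id, target_id = target$id, L = L,
                 local_scores = tab,
                 per_residue_similarity = consensus,
                 per_residue_error = errors,
                 globals = globals, variants = variants,
                 p_value = pv, variant = variant),
            class = "qa_result")
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf("<qa_result> %s (target %s)\n", x$model_id, x$target_id))
  g <- sprintf("%s=%.3f", names(x$globals), x$globals)
  cat("  globals:", paste(g, collapse = " "), "\n")
  v <- sprintf("%s=%.3f", names(x$variants), x$variants)
  cat("  variants:", paste(v, collapse = " "))
  if (!is.na(x$p_value)) cat(sprintf("  P=%.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Validate and resolve a run configuration
#'
#' Accepts a list or the path of a simple `key = value` text file (`#`
#' comments allowed), checks every key against the known set, fills defaults
#' and range-checks thresholds.
#'
#' @param config list or path.  Recognized keys: `sequence`, `models`
#'   (file, comma-separated files or a directory), `refs` (directory),
#'   `ss2`, `diso`, `rr`, `proq2` (file or directory; optional), `weights`,
#'   `calibration` (optional), `out`, `variant`
#'   (`ModFOLD6`/`ModFOLD6_cor`/`ModFOLD6_rank`/`all`), `contact_threshold`,
#'   `min_separation`, `similarity_floor`, `seed`.
#' @return A validated list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    lines <- readLines(config, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", lines))
    if (any(lengths(kv) != 3L)) {
      stop("cannot parse config line: '", lines[which(lengths(kv) != 3L)[1]], "'")
    }
    config <- stats::setNames(lapply(kv, function(m) trimws(m[3])),
                              vapply(kv, function(m) m[2], ""))
  }
  known <- c("sequence", "models", "refs", "ss2", "diso", "rr", "proq2",
             "weights", "calibration", "out", "variant",
             "contact_threshold", "min_separation", "similarity_floor",
             "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(variant = "ModFOLD6", contact_threshold = 8.0,
                   min_separation = 5L, similarity_floor = 0.01,
                   seed = 1L, proq2 = NULL, calibration = NULL,
                   weights = NULL, out = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  }
  for (nm in c("sequence", "models", "refs", "ss2", "diso", "rr")) {
    if (is.null(config[[nm]])) {
      stop("missing required config field '", nm, "'")
    }
    paths <- strsplit(as.character(config[[nm]]), ",", fixed = TRUE)[[1]]
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("config field '", nm, "': path does not exist: ",
           paste(missing, collapse = ", "))
    }
  }
  for (nm in c("contact_threshold", "min_separation", "similarity_floor")) {
    config[[nm]] <- as.numeric(config[[nm]])
    if (!is.finite(config[[nm]]) || config[[nm]] <= 0) {
      stop("config field '", nm, "' must be positive")
    }
  }
  config$seed <- as.integer(config$seed)
  if (!config$variant %in% c(QA_VARIANT_NAMES, "all")) {
    stop("config field 'variant' must be one of ",
         paste(c(QA_VARIANT_NAMES, "all"), collapse = ", "))
  }
  structure(config, class = "run_config")
}

expand_model_paths <- function(models) {
  paths <- strsplit(as.character(models), ",", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      out <- c(out, sort(list.files(p, pattern = "\\.(pdb|ent)$",
                                    full.names = TRUE)))
    } else {
      out <- c(out, p)
    }
  }
  out
}

#' Run quality assessment end to end
#'
#' Reads the target, models, reference ensemble, prediction files and
#' combiner weights named by the configuration; scores every model
#' (quasi-single: each model is compared only against the reference ensemble,
#' never against co-submitted models); and writes, per model, a B-factor
#' annotated PDB, a CASP QA (QMODE 2) record and a per-residue TSV, plus a
#' summary TSV over all models sorted by the chosen variant, descending.
#' Unreadable models are recorded as failures and the run continues.
#'
#' @param config a [validate_config()] input.
#' @return List with `results` (list of `qa_result`), `summary` (data.frame),
#'   `failures` (named character vector of error messages) and `out_dir`.
#' @export
run_qa <- function(config) {
  config <- validate_config(config)
  target <- read_fasta(config$sequence)
  L <- length(target)
  sort_variant <- if (config$variant == "all") "ModFOLD6_rank" else config$variant

  bundle <- prediction_bundle(
    target,
    ss_probs = read_ss2(config$ss2),
    disorder_pd = read_disorder(config$diso),
    contact_probs = read_contacts(config$rr, L,
                                  min_separation = config$min_separation))

  ref_paths <- sort(list.files(config$refs, pattern = "\\.(pdb|ent)$",
                               full.names = TRUE))
  refs <- lapply(ref_paths, read_model, target = target)
  names(refs) <- vapply(refs, function(m) m$model_id, "")
  ensemble <- reference_ensemble(refs)

  network <- read_weights(config$weights %||% default_weights_path())
  calibration <- if (!is.null(config$calibration)) {
    read_calibration(config$calibration)
  } else if (file.exists(default_calibration_path())) {
    read_calibration(default_calibration_path())
  }

  model_paths <- expand_model_paths(config$models)
  if (length(model_paths) == 0L) stop("no models to score")
  out_dir <- config$out
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  results <- list()
  failures <- character(0)
  for (mp in model_paths) {
    id <- sub("\\.(pdb|ent)$", "", basename(mp))
    res <- tryCatch({
      model <- read_model(mp, target)
      ext <- NULL
      if (!is.null(config$proq2)) {
        pq <- config$proq2
        if (dir.exists(pq)) pq <- file.path(pq, paste0(id, ".local"))
        if (file.exists(pq)) ext <- read_local_scores(pq, L)
      }
      score_model(model, target, bundle, ensemble, network,
                  calibration = calibration, external_local = ext,
                  variant = sort_variant)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      message("model ", id, " failed: ", conditionMessage(res))
      next
    }
    results[[res$model_id]] <- res
    if (!is.null(out_dir)) {
      model <- read_model(mp, target)
      write_annotated_model(model, res$per_residue_error,
                            file.path(out_dir, paste0(id, "_annotated.pdb")))
      write_casp_qa(res, file.path(out_dir, paste0(id, ".qa")))
      write_local_tsv(res, file.path(out_dir, paste0(id, "_local.tsv")))
    }
  }
  if (length(results) == 0L) stop("all models failed to score")

  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = r$model_id, t(r$globals),
               ModFOLD6_cor = r$variants[["ModFOLD6_cor"]],
               ModFOLD6_rank = r$variants[["ModFOLD6_rank"]],
               p_value = r$p_value, check.names = FALSE)
  }))
  summary <- summary[order(-summary[[sort_variant]], summary$model), ]
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    write_summary_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  list(results = results, summary = summary, failures = failures,
       out_dir = out_dir, config = config)
}
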