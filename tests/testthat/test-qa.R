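ws_config <- function(ws, out, models = ws$model_dir) {
  list(sequence = ws$fasta, models = models, refs = ws$ref_dir,
       ss2 = unname(ws$prediction_paths["ss2"]),
       diso = unname(ws$prediction_paths["diso"]),
       rr = unname(ws$prediction_paths["rr"]),
       proq2 = ws$proq2_dir, variant = "ModFOLD6_rank", out = out)
}

test_that("config validation fills defaults and rejects bad input", {
  ws <- ws_small()
  cfg <- validate_config(ws_config(ws, out = NULL))
  expect_equal(cfg$contact_threshold, 8.0)
  expect_equal(cfg$min_separation, 5)
  expect_equal(cfg$similarity_floor, 0.01)
  bad <- ws_config(ws, out = NULL)
  bad$contact_threshold <- -1
  expect_error(validate_config(bad), "positive")
  bad2 <- ws_config(ws, out = NULL)
  bad2$nonsense <- 1
  expect_error(validate_config(bad2), "unknown config key.*nonsense")
  bad3 <- ws_config(ws, out = NULL)
  bad3$ss2 <- NULL
  expect_error(validate_config(bad3), "missing required.*ss2")
  bad4 <- ws_config(ws, out = NULL)
  bad4$ss2 <- "/no/such/file.ss2"
  expect_error(validate_config(bad4), "does not exist")
})

test_that("config files in key = value form parse", {
  ws <- ws_small()
  cfgfile <- tempfile(fileext = ".cfg")
  writeLines(c(
    "# run configuration",
    paste("sequence =", ws$fasta),
    paste("models =", ws$model_dir),
    paste("refs =", ws$ref_dir),
    paste("ss2 =", ws$prediction_paths["ss2"]),
    paste("diso =", ws$prediction_paths["diso"]),
    paste("rr =", ws$prediction_paths["rr"]),
    "variant = ModFOLD6_cor"), cfgfile)
  cfg <- validate_config(cfgfile)
  expect_equal(cfg$variant, "ModFOLD6_cor")
  expect_equal(cfg$seed, 1L)
})

test_that("run_qa scores a workspace end to end and ranks by observed quality", {
  ws <- ws_small()
  out <- file.path(tempdir(), "modqa6_run1")
  unlink(out, recursive = TRUE)
  res <- suppressWarnings(run_qa(ws_config(ws, out)))
  expect_length(res$results, length(ws$models))
  expect_length(res$failures, 0)
  expect_identical(sort(res$summary$model), sort(names(ws$models)))
  # summary is sorted by the chosen variant, descending
  expect_true(all(diff(res$summary$ModFOLD6_rank) <= 1e-12))
  # the unperturbed copy of the native ranks first
  expect_identical(res$summary$model[1], "decoy_r0_01")
  # per-model outputs exist
  expect_true(file.exists(file.path(out, "decoy_r3_01.qa")))
  expect_true(file.exists(file.path(out, "decoy_r3_01_annotated.pdb")))
  expect_true(file.exists(file.path(out, "decoy_r3_01_local.tsv")))
  expect_true(file.exists(file.path(out, "summary.tsv")))
  # P-values come from the shipped calibration and decrease with quality
  pv <- res$summary$p_value
  expect_true(all(pv >= 1e-6 & pv <= 1))
  expect_lte(pv[1], pv[nrow(res$summary)])
})

test_that("QA records match the annotated B-factors at 2-decimal precision", {
  ws <- ws_small()
  out <- file.path(tempdir(), "modqa6_run1")   # reuse previous run
  if (!file.exists(file.path(out, "summary.tsv"))) {
    suppressWarnings(run_qa(ws_config(ws, out)))
  }
  L <- length(ws$target)
  qa <- read_casp_qa(file.path(out, "decoy_r5_02.qa"), L)
  pdb_lines <- readLines(file.path(out, "decoy_r5_02_annotated.pdb"))
  atom <- pdb_lines[startsWith(pdb_lines, "ATOM")]
  pos <- as.integer(substr(atom, 23, 26))
  bf <- as.numeric(substr(atom, 61, 66))
  per_res <- tapply(bf, pos, unique)
  expect_true(all(vapply(per_res, length, 1L) == 1L))
  covered <- sort(unique(pos))
  expect_equal(as.numeric(per_res[as.character(covered)]), qa$errors[covered],
               tolerance = 1e-9)
  expect_true(all(is.na(qa$errors[setdiff(seq_len(L), covered)])))
})

test_that("re-running with the same inputs is byte-identical", {
  ws <- ws_small()
  out1 <- file.path(tempdir(), "modqa6_rerun1")
  out2 <- file.path(tempdir(), "modqa6_rerun2")
  unlink(c(out1, out2), recursive = TRUE)
  sub <- file.path(ws$model_dir, c("decoy_r1_01.pdb", "decoy_r6_01.pdb"))
  sub <- paste(sub, collapse = ",")
  suppressWarnings(run_qa(ws_config(ws, out1, models = sub)))
  suppressWarnings(run_qa(ws_config(ws, out2, models = sub)))
  for (f in sort(list.files(out1))) {
    expect_identical(readLines(file.path(out1, f), warn = FALSE),
                     readLines(file.path(out2, f), warn = FALSE), info = f)
  }
})

test_that("unreadable models are recorded as failures without halting", {
  ws <- ws_small()
  bad <- tempfile(fileext = ".pdb")
  writeLines("REMARK not really a model", bad)
  models <- paste(c(file.path(ws$model_dir, "decoy_r2_01.pdb"), bad),
                  collapse = ",")
  res <- suppressWarnings(run_qa(ws_config(ws, out = NULL, models = models)))
  expect_length(res$results, 1)
  expect_length(res$failures, 1)
  expect_match(unname(res$failures[1]), "no ATOM|unreadable")
})

test_that("scoring is quasi-single: one model alone gets the same scores", {
  ws <- ws_small()
  one <- file.path(ws$model_dir, "decoy_r4_01.pdb")
  res1 <- suppressWarnings(run_qa(ws_config(ws, out = NULL, models = one)))
  resall <- suppressWarnings(run_qa(ws_config(ws, out = NULL)))
  expect_length(res1$results, 1)
  expect_equal(res1$results[["decoy_r4_01"]]$globals,
               resall$results[["decoy_r4_01"]]$globals, tolerance = 1e-12)
})
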