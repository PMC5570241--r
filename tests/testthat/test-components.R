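test_that("CDA is the mean predicted probability over realized contacts", {
  target <- target_sequence("t", strrep("A", 30))
  # residue 1 contacts residues 10 and 20; 10 and 20 are far apart
  co <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  m <- read_model(toy_pdb(rep("ALA", 3), c(1, 10, 20), co), target)
  cp <- read_contacts(c("1 10 0 8 0.8", "1 20 0 8 0.6"), L = 30)
  s <- cda(m, cp)
  expect_equal(unname(s["1"]), 0.7)
  expect_equal(unname(s["10"]), 0.8)
  expect_equal(unname(s["20"]), 0.6)
})

test_that("residues whose contacts lack predictions are absent", {
  target <- target_sequence("t", strrep("A", 30))
  co <- rbind(c(0, 0, 0), c(6, 0, 0), c(100, 0, 0))
  m <- read_model(toy_pdb(rep("ALA", 3), c(1, 10, 20), co), target)
  cp <- read_contacts("2 9 0 8 0.5", L = 30)   # no overlap with model contacts
  s <- cda(m, cp)
  expect_true(all(is.na(s)))
  # isolated residue 20 has no model contacts at all -> absent even with p = 1
  cp2 <- read_contacts("1 10 0 8 1.0", L = 30)
  s2 <- cda(m, cp2)
  expect_equal(unname(s2[c("1", "10")]), c(1, 1))
  expect_true(is.na(s2["20"]))
})

test_that("SSA selects the predicted probability of the model's own state", {
  ws <- ws_small()
  m <- ws$native
  probs <- ws$bundle$ss_probs
  s <- ssa(m, probs)
  ss <- unclass(assign_ss3(m))
  i <- which(ss == "H")[1]
  pos <- m$target_positions[i]
  expect_equal(unname(s[as.character(pos)]), unname(probs[pos, "H"]))
  # a model contradicting a confident prediction scores low
  probs2 <- probs
  probs2[pos, ] <- c(0.98, 0.01, 0.01)
  expect_equal(unname(ssa(m, probs2)[as.character(pos)]), 0.01)
})

test_that("distance similarity scores follow S_r = 1/(1+(d/3.9)^2)", {
  ws <- ws_small()
  L <- length(ws$target)
  ens1 <- reference_ensemble(list(ws$native, ws$native))
  m5 <- mf5s_local(ws$native, ens1, L)
  expect_true(all(abs(m5$score - 1) < 1e-9))
  expect_true(all(m5$dbar < 1e-9))
  # hand-check one model against the ensemble: dbar converts by the formula
  m <- ws$models[[6]]
  prof <- quasi_profile(m, ws$ensemble, L)
  m5b <- mf5s_local(m, ws$ensemble, L, profile = prof)
  expect_equal(unname(m5b$score), unname(1 / (1 + (prof$dbar / 3.9)^2)))
  expect_equal(unname(m5b$score[prof$dbar == 3.9]), rep(0.5, sum(prof$dbar == 3.9)))
})

test_that("mean distances average per-reference superposition distances", {
  ws <- ws_small()
  L <- length(ws$target)
  refs <- ws$ensemble$models[1:2]
  prof <- quasi_profile(ws$models[[4]], reference_ensemble(refs), L)
  d1 <- tm_superpose(ws$models[[4]], refs[[1]], L)$per_residue_d
  d2 <- tm_superpose(ws$models[[4]], refs[[2]], L)$per_residue_d
  expect_equal(unname(prof$dbar), unname((d1 + d2) / 2), tolerance = 1e-9)
})

test_that("local Q consensus is the ensemble mean and order-invariant", {
  ws <- ws_small()
  L <- length(ws$target)
  m <- ws$models[[7]]
  refs <- ws$ensemble$models
  q <- mfcqs_local(m, ws$ensemble, L)
  qs <- sapply(refs, function(r) local_qscore(m, r))
  expect_equal(unname(q), unname(rowMeans(qs)), tolerance = 1e-9)
  perm <- reference_ensemble(refs[sample(length(refs))])
  expect_equal(mfcqs_local(m, perm, L), q, tolerance = 1e-9)
})

test_that("DBA follows 1 - |S_r - (1 - P_d)|", {
  s <- c(`1` = 1, `2` = 1, `3` = 0.7, `4` = NA)
  pd <- c(0, 1, 0.2, 0.5)
  d <- dba(s, pd)
  expect_equal(unname(d[1:3]), c(1, 0, 0.9))
  expect_true(is.na(d[4]))
  # symmetric under exchanging S_r and 1 - P_d
  expect_equal(unname(dba(c(`1` = 0.3), c(0.4))),
               unname(dba(c(`1` = 0.6), c(0.7))))
})

test_that("global scores divide by the full target length", {
  expect_equal(component_global(rep(1, 100), 100), 1)
  expect_equal(component_global(stats::setNames(rep(1, 50), 1:50), 100), 0.5)
  expect_equal(component_global(numeric(0), 100), 0)
  expect_equal(component_global(c(0.5, NA, 0.5), 10), 0.1)
})

test_that("component scores stay in [0,1] and respect model coverage", {
  ws <- ws_small()
  m <- ws$models[[10]]
  tab <- local_score_table(m, ws$bundle, ws$ensemble)
  vals <- tab[!is.na(tab)]
  expect_true(all(vals >= 0 & vals <= 1))
  uncovered <- setdiff(seq_len(nrow(tab)), m$target_positions)
  if (length(uncovered) > 0) {
    expect_true(all(is.na(tab[uncovered, ])))
  }
  expect_true(all(is.na(tab[, "ProQ2"])))   # no external channel supplied
})

test_that("quasi-single scores are invariant under rigid motion of inputs", {
  ws <- ws_small()
  L <- length(ws$target)
  m <- ws$models[[12]]
  base <- mf5s_local(m, ws$ensemble, L)$score
  m2 <- rigid_transform_model(m, 21)
  refs2 <- lapply(ws$ensemble$models, rigid_transform_model, seed = 22)
  moved <- reference_ensemble(refs2)
  expect_equal(mf5s_local(m2, moved, L)$score, base, tolerance = 1e-5)
})
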