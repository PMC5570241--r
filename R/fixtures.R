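# Ideal backbone geometry (Engh-Huber-style bond lengths/angles, degrees)
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega = 180
)

deg2rad <- function(x) x * pi / 180

# next-atom placement from three predecessors (NeRF chain extension)
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- deg2rad(angle); torsion <- deg2rad(torsion)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * cos(torsion) * sin(angle),
          bond * sin(torsion) * sin(angle))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# canonical phi/psi per segment type; coil is drawn per residue
SEGMENT_DIHEDRALS <- list(
  H = c(phi = -57, psi = -47),
  E = c(phi = -119, psi = 113),
  C = NULL
)

# base dihedrals of a coil segment of length m: an extended entry residue, a
# left-handed middle and a tight exit turn, so linkers reverse the chain and
# the fold stays compact enough to realize tertiary contacts; the generator
# jitters these per residue
coil_base_dihedrals <- function(m) {
  if (m == 1L) return(list(c(-90, 0)))
  out <- vector("list", m)
  out[[1L]] <- c(-75, 160)
  out[[m]] <- c(-90, 0)
  if (m > 2L) for (k in 2:(m - 1L)) out[[k]] <- c(55, 45)
  out
}

parse_grammar <- function(grammar) {
  parts <- strsplit(grammar, "-", fixed = TRUE)[[1]]
  if (length(parts) == 0L || !all(grepl("^[HEC][0-9]+$", parts))) {
    stop("bad segment grammar '", grammar,
         "': expected e.g. 'H15-C5-E8-C3-E8'")
  }
  type <- substr(parts, 1, 1)
  len <- as.integer(substring(parts, 2))
  if (sum(len) < 1L) stop("zero-length segment grammar")
  rep(type, len)
}

# build full-backbone coordinates from per-residue (phi, psi), omega = 180
build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(GEOM$b_n_ca, 0, 0)
  ang <- deg2rad(GEOM$a_n_ca_c)
  C[1, ] <- CA[1, ] + GEOM$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           GEOM$b_c_n, GEOM$a_ca_c_n, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           GEOM$b_ca_c, GEOM$a_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         GEOM$b_c_o, GEOM$a_ca_c_o, psi[i] + 180)
    CB[i, ] <- virtual_cb(N[i, ], CA[i, ], C[i, ])
  }
  list(n = N, ca = CA, c = C, o = O, cb = CB)
}

# assemble a protein_model in-memory, then round-trip through the PDB writer
# so fixture models carry the same line-level state as user-loaded models
model_from_coords <- function(coords, res_codes, target_positions, target,
                              model_id) {
  m <- list(model_id = model_id, target_positions = target_positions,
            res_codes = res_codes, ca = coords$ca, cb = coords$cb,
            cb_real = res_codes != "G", n = coords$n, c = coords$c,
            o = coords$o)
  read_model(write_pdb(m), target, model_id = model_id)
}

#' Generate an ideal-geometry native structure from a segment grammar
#'
#' Builds a full-backbone (N/CA/C/O plus CB) chain with ideal bond geometry
#' and canonical dihedrals per segment type: helix `H` (phi -57, psi -47),
#' strand `E` (phi -119, psi +113), coil `C` (turn-prone base dihedrals per
#' linker position with seeded jitter, so the fold stays compact and realizes
#' tertiary contacts).  The residue letters are drawn seeded
#' from the 20 standard amino acids excluding proline and glycine, so every
#' residue can both donate backbone hydrogen bonds and carry a CB.
#'
#' @param grammar segment grammar such as `"H15-C5-E8-C3-E8"`.
#' @param seed RNG seed; the same grammar and seed give identical coordinates.
#' @param id target identifier.
#' @return List with `target` (a [target_sequence()]), `native` (a
#'   `protein_model`) and `ss_types` (the grammar's per-residue H/E/C types).
#' @export
make_native <- function(grammar, seed = 1L, id = "synthetic_target") {
  types <- parse_grammar(grammar)
  n <- length(types)
  set.seed(seed)
  letters20 <- setdiff(AA_ONE, c("P", "G"))
  res <- sample(letters20, n, replace = TRUE)
  phi <- psi <- numeric(n)
  i <- 1L
  while (i <= n) {
    if (types[i] == "C") {
      j <- i
      while (j <= n && types[j] == "C") j <- j + 1L
      base <- coil_base_dihedrals(j - i)
      for (k in seq_along(base)) {
        phi[i + k - 1L] <- base[[k]][1] + stats::runif(1, -8, 8)
        psi[i + k - 1L] <- base[[k]][2] + stats::runif(1, -8, 8)
      }
      i <- j
    } else {
      phi[i] <- SEGMENT_DIHEDRALS[[types[i]]]["phi"]
      psi[i] <- SEGMENT_DIHEDRALS[[types[i]]]["psi"]
      i <- i + 1L
    }
  }
  coords <- build_backbone(phi, psi)
  target <- target_sequence(id, res)
  native <- model_from_coords(coords, res, seq_len(n), target, "native")
  list(target = target, native = native, ss_types = types)
}

#' Generate an ideal two-strand antiparallel sheet model
#'
#' Two ideal-geometry strands (antiparallel-sheet dihedrals phi -139,
#' psi +135) are paired antiparallel: the partner strand is rotated 180
#' degrees about the in-plane axis perpendicular to the strand direction
#' (reversing its chain direction in space) and placed at the
#' hydrogen-bonding register found by a one-time grid search maximizing
#' Kabsch-Sander backbone hydrogen bonds (offsets frozen below, tuned at the
#' default strand length and extrapolated by the ideal 3.36 A per-residue
#' rise for other lengths).  The strands occupy target positions
#' `1..strand_len` and `strand_len+gap+1 ...`; the loop between them is left
#' unmodelled.
#'
#' @param strand_len residues per strand (default 8).
#' @param gap unmodelled loop length between the strands (default 3).
#' @param seed seed for the residue letters.
#' @return List with `target`, `model` and `core` (the target positions of
#'   the sheet core, i.e. both strands minus their terminal residues).
#' @export
make_sheet_model <- function(strand_len = 8L, gap = 3L, seed = 1L) {
  set.seed(seed)
  letters20 <- setdiff(AA_ONE, c("P", "G"))
  n <- 2L * strand_len + gap
  res <- sample(letters20, n, replace = TRUE)
  phi <- rep(-139, strand_len)
  psi <- rep(135, strand_len)
  s1 <- build_backbone(phi, psi)
  u <- s1$ca[strand_len, ] - s1$ca[1, ]
  u <- u / sqrt(sum(u^2))                      # strand direction
  ax <- c(-u[2], u[1], 0)
  ax <- ax / sqrt(sum(ax^2))                   # in-plane perpendicular
  R <- rotation_about(ax, 180)
  t_par <- 24.5 + 3.36 * (strand_len - 8L)     # frozen H-bond register
  off <- t_par * u - 2.5 * ax
  s2 <- lapply(s1, function(X) sweep(X %*% t(R), 2, off, "+"))
  coords <- Map(rbind, s1, s2)
  pos <- c(seq_len(strand_len), strand_len + gap + seq_len(strand_len))
  target <- target_sequence("synthetic_sheet", res)
  model <- model_from_coords(coords, res[pos], pos, target, "sheet")
  list(target = target, model = model,
       core = c(2:(strand_len - 1L),
                strand_len + gap + 2:(strand_len - 1L)))
}

# Rodrigues rotation matrix: `ang` degrees about unit axis
rotation_about <- function(axis, ang) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg2rad(ang)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a ladder of perturbed decoys from a native structure
#'
#' Each rung applies one rigid Gaussian offset per residue (standard
#' deviation = the rung's perturbation scale, in Angstroms, per coordinate)
#' to all atoms of the residue, so local geometry degrades smoothly with the
#' scale; rung 0 is an exact copy of the native.  Optional segment shifts
#' translate a residue range by a fixed vector on top of the noise.
#'
#' @param native a `protein_model` (e.g. from [make_native()]).
#' @param target the matching [target_sequence()].
#' @param perturbations numeric vector of per-rung noise scales in Angstroms.
#' @param per_rung decoys generated per rung.
#' @param seed RNG seed; decoys are reproducible per spec + seed.
#' @param segment_shifts optional list of `list(range =, shift =, rungs =)`
#'   entries applied to the named rungs (1-based).
#' @return List of `protein_model`s with ids `decoy_r<rung>_<k>` and
#'   attribute `rung` giving each decoy's rung index (1-based).
#' @export
make_decoys <- function(native, target, perturbations, per_rung = 1L,
                        seed = 1L, segment_shifts = NULL) {
  set.seed(seed)
  out <- list()
  rung_of <- integer(0)
  nres <- length(native$target_positions)
  for (r in seq_along(perturbations)) {
    for (k in seq_len(per_rung)) {
      sc <- perturbations[r]
      noise <- matrix(stats::rnorm(nres * 3, 0, sc), nres, 3)
      coords <- list(n = native$n + noise, ca = native$ca + noise,
                     c = native$c + noise, o = native$o + noise,
                     cb = native$cb + noise)
      if (!is.null(segment_shifts)) {
        for (ssh in segment_shifts) {
          if (!is.null(ssh$rungs) && !(r %in% ssh$rungs)) next
          rows <- which(native$target_positions %in% ssh$range)
          for (nm in names(coords)) {
            coords[[nm]][rows, ] <- sweep(coords[[nm]][rows, , drop = FALSE],
                                          2, ssh$shift, "+")
          }
        }
      }
      id <- sprintf("decoy_r%d_%02d", r - 1L, k)
      out[[id]] <- model_from_coords(coords, native$res_codes,
                                     native$target_positions, target, id)
      rung_of <- c(rung_of, r)
    }
  }
  attr(out, "rung") <- rung_of
  out
}

#' Generate synthetic upstream prediction files for a native structure
#'
#' Emulates the upstream predictors the component scores consume, blending
#' ground truth computed from the native with noise by `fidelity`
#' (1 = oracle-quality predictions, 0 = pure noise):
#' secondary-structure probabilities are the one-hot [assign_ss3()] string of
#' the native blended with uniform 1/3; disorder probability is high (0.9) in
#' terminal coil tails and low (0.05) elsewhere, blended with uniform noise;
#' contact probabilities are high for native contacts and low for an equal
#' number of sampled non-contacts.  Files are written in the exact dialects
#' [read_ss2()], [read_disorder()] and [read_contacts()] parse.
#'
#' @param native a `protein_model` covering the full target.
#' @param target the [target_sequence()].
#' @param dir output directory (created if needed).
#' @param fidelity blend factor in `[0, 1]` (default 0.85).
#' @param seed RNG seed.
#' @return A [prediction_bundle()] (invisibly the file paths as attribute
#'   `paths`).
#' @export
make_predictions <- function(native, target, dir, fidelity = 0.85, seed = 1L) {
  stopifnot(fidelity >= 0, fidelity <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  L <- length(target)
  ss <- unclass(assign_ss3(native))
  states <- c("C", "H", "E")
  onehot <- matrix(0, L, 3, dimnames = list(NULL, states))
  onehot[cbind(seq_len(L), match(ss, states))] <- 1
  probs <- fidelity * onehot + (1 - fidelity) / 3

  ss2_path <- file.path(dir, paste0(target$id, ".ss2"))
  writeLines(c("# PSIPRED VFORMAT (synthetic)", "",
               sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                       seq_len(L), target$residues, ss,
                       probs[, "C"], probs[, "H"], probs[, "E"])),
             ss2_path)

  # disorder: high in terminal coil tails
  base <- rep(0.05, L)
  lead <- which(cumsum(ss != "C") == 0)
  trail <- which(rev(cumsum(rev(ss != "C"))) == 0)
  base[c(lead, trail)] <- 0.9
  pd <- pmin(pmax(fidelity * base + (1 - fidelity) * stats::runif(L), 0), 1)
  diso_path <- file.path(dir, paste0(target$id, ".diso"))
  writeLines(c("# synthetic disorder prediction",
               sprintf("%5d %s %s %5.2f", seq_len(L), target$residues,
                       ifelse(base > 0.5, "*", "."), pd)),
             diso_path)

  # contacts: native map blended with noise, plus low-probability negatives
  mc <- model_contacts(native)
  p_hit <- pmin(pmax(fidelity * 0.95 + (1 - fidelity) * stats::runif(nrow(mc)),
                     0), 1)
  pairs <- expand.grid(i = seq_len(L), j = seq_len(L))
  pairs <- pairs[pairs$j - pairs$i >= 5L, ]
  key <- paste(pairs$i, pairs$j)
  neg <- pairs[!(key %in% paste(mc$i, mc$j)), ]
  nneg <- min(nrow(neg), nrow(mc))
  neg <- neg[sample.int(nrow(neg), nneg), , drop = FALSE]
  p_neg <- (1 - fidelity) * stats::runif(nneg) * 0.5
  rr <- rbind(data.frame(i = mc$i, j = mc$j, p = p_hit),
              data.frame(i = neg$i, j = neg$j, p = p_neg))
  rr <- rr[order(rr$i, rr$j), ]
  rr_path <- file.path(dir, paste0(target$id, ".rr"))
  writeLines(c("PFRMAT RR",
               paste("TARGET", target$id),
               sprintf("%d %d 0 8 %.4f", rr$i, rr$j, rr$p),
               "END"),
             rr_path)

  bundle <- prediction_bundle(target,
                              ss_probs = read_ss2(ss2_path),
                              disorder_pd = read_disorder(diso_path),
                              contact_probs = read_contacts(rr_path, L))
  attr(bundle, "paths") <- c(ss2 = ss2_path, diso = diso_path, rr = rr_path)
  bundle
}

#' Observed per-residue similarity of a model against its native structure
#'
#' Superposes the model on the native with [tm_superpose()] and converts the
#' observed per-residue distances to similarities via
#' `S_r = 1 / (1 + (d/3.9)^2)`.  These are the training targets for the
#' combiner and the ground truth for P-value calibration.
#'
#' @param model,native `protein_model`s for the same target.
#' @param L target length (TM normalization).
#' @return List with `similarity` (named by position), `d` (Angstroms) and
#'   `tm` (the observed TM-score).
#' @export
observed_local_similarity <- function(model, native, L) {
  sup <- tm_superpose(model, native, L)
  list(similarity = distance_to_similarity(sup$per_residue_d),
       d = sup$per_residue_d, tm = sup$tm_score)
}

#' Generate a complete, ready-to-score fixture workspace
#'
#' Writes a target FASTA, the native structure, a decoy ladder under
#' `models/`, a reference ensemble of mid-ladder-quality decoys under
#' `refs/` (imperfect references, the realistic quasi-single regime),
#' synthetic prediction files and per-model external local scores (a
#' fidelity-blend of the observed similarity, standing in for a third-party
#' local scorer) under `proq2/`.
#'
#' @param dir workspace directory (created).
#' @param grammar segment grammar for the native fold.
#' @param seed master seed; every random draw derives from it.
#' @param perturbations decoy-ladder noise scales in Angstroms.
#' @param per_rung decoys per rung.
#' @param ensemble_size reference models generated (default 20; the method's
#'   production setting is 130).
#' @param ensemble_noise range of reference perturbation scales in Angstroms.
#' @param fidelity prediction quality in `[0, 1]`.
#' @return List describing the workspace (paths, target, native, models,
#'   ensemble, bundle, decoy rungs).
#' @export
make_workspace <- function(dir, grammar = "H15-C5-E8-C3-E8", seed = 42L,
                           perturbations = c(0, 0.5, 1, 1.5, 2, 3, 4.5, 6),
                           per_rung = 2L, ensemble_size = 20L,
                           ensemble_noise = c(1.0, 2.5), fidelity = 0.85) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nat <- make_native(grammar, seed = seed)
  target <- nat$target
  L <- length(target)
  fasta <- file.path(dir, paste0(target$id, ".fasta"))
  write_fasta(target, fasta)
  native_path <- file.path(dir, "native.pdb")
  write_pdb(nat$native, native_path)

  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  decoys <- make_decoys(nat$native, target, perturbations,
                        per_rung = per_rung, seed = seed + 1L)
  for (id in names(decoys)) {
    write_pdb(decoys[[id]], file.path(mdir, paste0(id, ".pdb")))
  }

  rdir <- file.path(dir, "refs")
  dir.create(rdir, showWarnings = FALSE)
  set.seed(seed + 2L)
  ref_scales <- stats::runif(ensemble_size, ensemble_noise[1], ensemble_noise[2])
  refs <- list()
  for (k in seq_len(ensemble_size)) {
    rk <- make_decoys(nat$native, target, ref_scales[k], per_rung = 1L,
                      seed = seed + 100L + k)[[1]]
    rk$model_id <- sprintf("ref_%02d", k)
    refs[[rk$model_id]] <- rk
    write_pdb(rk, file.path(rdir, paste0(rk$model_id, ".pdb")))
  }

  bundle <- make_predictions(nat$native, target, dir, fidelity = fidelity,
                             seed = seed + 3L)

  pdir <- file.path(dir, "proq2")
  dir.create(pdir, showWarnings = FALSE)
  set.seed(seed + 4L)
  for (id in names(decoys)) {
    obs <- observed_local_similarity(decoys[[id]], nat$native, L)$similarity
    s <- pmin(pmax(fidelity * obs +
                     (1 - fidelity) * stats::runif(length(obs)), 0), 1)
    writeLines(sprintf("%d %.4f", as.integer(names(obs)), s),
               file.path(pdir, paste0(id, ".local")))
  }

  list(dir = dir, seed = seed, target = target, native = nat$native,
       ss_types = nat$ss_types, fasta = fasta, native_path = native_path,
       models = decoys, model_dir = mdir,
       ensemble = reference_ensemble(refs), ref_dir = rdir,
       bundle = bundle, prediction_paths = attr(bundle, "paths"),
       proq2_dir = pdir, rungs = attr(decoys, "rung"),
       perturbations = perturbations)
}

#' Build a combiner training set from a fixture workspace
#'
#' Scores every decoy of the workspace with the six component methods,
#' featurizes each covered position with the size-5 sliding window and pairs
#' it with the observed similarity of that residue against the native.
#'
#' @param ws a workspace from [make_workspace()].
#' @param models subset of model ids (default all).
#' @return List with `features` (`N x 30`), `targets` (length `N`),
#'   `model_id` and `position` vectors, and `component_scores` (`N x 6`, the
#'   window-center component values with `NA` imputed to 0.5, for baseline
#'   comparisons).
#' @export
build_training_set <- function(ws, models = names(ws$models)) {
  L <- length(ws$target)
  feats <- list(); targs <- list(); mid <- list(); posl <- list()
  comp <- list()
  for (id in models) {
    model <- ws$models[[id]]
    ext <- read_local_scores(file.path(ws$proq2_dir, paste0(id, ".local")), L)
    tab <- local_score_table(model, ws$bundle, ws$ensemble,
                             external_local = ext)
    obs <- observed_local_similarity(model, ws$native, L)$similarity
    pos <- intersect(attr(tab, "covered"), as.integer(names(obs)))
    X <- featurize(tab, pos)
    feats[[id]] <- X
    targs[[id]] <- unname(obs[as.character(pos)])
    mid[[id]] <- rep(id, length(pos))
    posl[[id]] <- pos
    cc <- tab[pos, , drop = FALSE]
    cc[is.na(cc)] <- 0.5
    comp[[id]] <- cc
  }
  list(features = do.call(rbind, feats),
       targets = unlist(targs, use.names = FALSE),
       model_id = unlist(mid, use.names = FALSE),
       position = unlist(posl, use.names = FALSE),
       component_scores = do.call(rbind, comp))
}
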