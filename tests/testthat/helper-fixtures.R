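# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small workspace: 8 rungs x 2 decoys, 6 references -- fast enough for unit
# tests; acceptance tests build their own at the stated scale
ws_small <- function() {
  cached("ws_small", {
    make_workspace(file.path(tempdir(), "modqa6_ws_small"), seed = 42,
                   per_rung = 2L, ensemble_size = 6L)
  })
}

frozen_net <- function() cached("frozen_net", read_weights(default_weights_path()))

# hand-rolled PDB ATOM line (fixed columns) for toy models
pdb_atom_line <- function(serial, name, res3, resseq, x, y, z,
                          occ = 1.00, bfac = 0.00, altloc = " ",
                          chain = "A", record = "ATOM  ") {
  sprintf("%s%5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, formatC(paste0(" ", name), width = -4), altloc,
          res3, chain, resseq, x, y, z, occ, bfac)
}

# toy CA-trace PDB text: one CA per residue at the given coords
toy_pdb <- function(res3, resseq, coords) {
  lines <- vapply(seq_along(res3), function(i) {
    pdb_atom_line(i, "CA", res3[i], resseq[i],
                  coords[i, 1], coords[i, 2], coords[i, 3])
  }, "")
  c(lines, "TER", "END")
}

# random rigid transform applied to every coordinate block of a model
rigid_transform_model <- function(model, seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- stats::rnorm(3, 0, 20)
  for (nm in c("ca", "cb", "n", "c", "o")) {
    if (!is.null(model[[nm]])) {
      model[[nm]] <- sweep(model[[nm]] %*% t(R), 2, t, "+")
    }
  }
  model
}

# independent RMSD oracle: Horn's quaternion characteristic-polynomial method
quaternion_rmsd <- function(P, Q) {
  P <- scale(P, scale = FALSE); Q <- scale(Q, scale = FALSE)
  M <- crossprod(P, Q)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
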