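NN_METHODS <- c("CDA", "SSA", "ProQ2", "DBA", "MF5s", "MFcQs")
NN_OFFSETS <- -2:2
NN_FEATURE_ORDER <- paste0(paste(NN_METHODS, collapse = ","), "|w",
                           min(NN_OFFSETS), "..", max(NN_OFFSETS))
NN_INPUTS <- length(NN_METHODS) * length(NN_OFFSETS)  # 30
NN_HIDDEN <- 15L

#' Construct a combiner network
#'
#' The consensus combiner is a fixed-architecture multilayer perceptron with
#' 30 inputs (a size-5 sliding window over the six component score tracks),
#' 15 hidden units and 1 output, logistic sigmoid activations throughout.
#'
#' @param weights_in `30 x 15` input-to-hidden weight matrix.
#' @param bias_hidden length-15 hidden bias.
#' @param weights_out length-15 hidden-to-output weights.
#' @param bias_out scalar output bias.
#' @return Object of class `combiner_network`.
#' @export
combiner_network <- function(weights_in, bias_hidden, weights_out, bias_out) {
  weights_in <- matrix(as.numeric(weights_in), NN_INPUTS, NN_HIDDEN)
  stopifnot(length(bias_hidden) == NN_HIDDEN,
            length(weights_out) == NN_HIDDEN, length(bias_out) == 1L)
  structure(list(weights_in = weights_in,
                 bias_hidden = as.numeric(bias_hidden),
                 weights_out = as.numeric(weights_out),
                 bias_out = as.numeric(bias_out),
                 feature_order = NN_FEATURE_ORDER),
            class = "combiner_network")
}

#' @export
print.combiner_network <- function(x, ...) {
  cat(sprintf("<combiner_network> %d-%d-1 logistic MLP (%s)\n",
              NN_INPUTS, NN_HIDDEN, x$feature_order))
  invisible(x)
}

random_network <- function(seed = 1L, scale = 0.5) {
  set.seed(seed)
  combiner_network(
    weights_in = matrix(stats::runif(NN_INPUTS * NN_HIDDEN, -scale, scale),
                        NN_INPUTS, NN_HIDDEN),
    bias_hidden = stats::runif(NN_HIDDEN, -scale, scale),
    weights_out = stats::runif(NN_HIDDEN, -scale, scale),
    bias_out = stats::runif(1, -scale, scale))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sliding-window feature vector for one position
#'
#' Collects the six component scores over window offsets -2..+2 around a
#' target position, method-major (all five offsets of CDA, then SSA, ...).
#' Entries that fall off the chain, off the model or are undefined are
#' imputed with the sigmoid-neutral constant 0.5.
#'
#' @param table a [local_score_table()].
#' @param positions target positions to featurize (default: all covered).
#' @return `length(positions) x 30` feature matrix.
#' @export
featurize <- function(table, positions = attr(table, "covered")) {
  L <- nrow(table)
  covered <- attr(table, "covered")
  feats <- matrix(0.5, length(positions), NN_INPUTS)
  col0 <- 0L
  for (m in seq_along(NN_METHODS)) {
    for (k in seq_along(NN_OFFSETS)) {
      p <- positions + NN_OFFSETS[k]
      ok <- p >= 1L & p <= L & p %in% covered
      v <- rep(NA_real_, length(positions))
      v[ok] <- table[p[ok], NN_METHODS[m]]
      v[is.na(v)] <- 0.5
      feats[, col0 + k] <- v
    }
    col0 <- col0 + length(NN_OFFSETS)
  }
  rownames(feats) <- positions
  feats
}

nn_forward <- function(network, X) {
  H <- sigmoid(sweep(X %*% network$weights_in, 2, network$bias_hidden, "+"))
  as.numeric(sigmoid(H %*% network$weights_out + network$bias_out))
}

#' Consensus per-residue similarity from the combiner network
#'
#' Deterministic forward pass of the trained combiner over every model-covered
#' position of the score table.
#'
#' @param network a trained [combiner_network()].
#' @param table a [local_score_table()].
#' @return Named numeric vector in `(0, 1)` over covered positions.
#' @export
predict_local <- function(network, table) {
  positions <- attr(table, "covered")
  X <- featurize(table, positions)
  out <- nn_forward(network, X)
  names(out) <- positions
  out
}

#' Train the combiner network
#'
#' Standard mini-batch backpropagation with momentum on squared error
#' (logistic activations on hidden and output layers).  With a fixed seed the
#' returned weights are bit-reproducible: initialization, example shuffling
#' and batching all derive from `seed`.
#'
#' @param features `N x 30` matrix of training inputs in `[0, 1]` (already
#'   imputed).
#' @param targets length-`N` vector of observed per-residue similarities in
#'   `[0, 1]`.
#' @param seed RNG seed.
#' @param epochs training epochs (default 500).
#' @param lr learning rate (default 0.05).
#' @param momentum momentum coefficient (default 0.9).
#' @param batch mini-batch size (default 32).
#' @return A `combiner_network` with attribute `train_rmse` (final epoch
#'   root-mean-square training error).
#' @export
train_combiner <- function(features, targets, seed = 1L, epochs = 500L,
                           lr = 0.05, momentum = 0.9, batch = 32L) {
  features <- as.matrix(features)
  N <- nrow(features)
  if (N < 100L) stop("need at least 100 training examples, got ", N)
  if (length(targets) != N) stop("features/targets length mismatch")
  set.seed(seed)
  W1 <- matrix(stats::runif(NN_INPUTS * NN_HIDDEN, -0.5, 0.5), NN_INPUTS, NN_HIDDEN)
  b1 <- stats::runif(NN_HIDDEN, -0.5, 0.5)
  W2 <- stats::runif(NN_HIDDEN, -0.5, 0.5)
  b2 <- stats::runif(1, -0.5, 0.5)
  vW1 <- matrix(0, NN_INPUTS, NN_HIDDEN); vb1 <- rep(0, NN_HIDDEN)
  vW2 <- rep(0, NN_HIDDEN); vb2 <- 0
  rmse <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    sse <- 0
    for (s in seq(1L, N, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, N)]
      X <- features[idx, , drop = FALSE]
      t <- targets[idx]
      Hl <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
      y <- as.numeric(sigmoid(Hl %*% W2 + b2))
      err <- y - t
      sse <- sse + sum(err^2)
      dy <- err * y * (1 - y)                      # dE/dz_out (per example)
      gW2 <- as.numeric(crossprod(Hl, dy)) / length(idx)
      gb2 <- mean(dy)
      dh <- (dy %o% W2) * Hl * (1 - Hl)            # back to hidden layer
      gW1 <- crossprod(X, dh) / length(idx)
      gb1 <- colMeans(dh)
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    }
    rmse <- sqrt(sse / N)
    if (!is.finite(rmse)) {
      stop("training diverged (non-finite loss); try a smaller learning rate")
    }
  }
  net <- combiner_network(W1, b1, W2, b2)
  attr(net, "train_rmse") <- rmse
  net
}

#' Convert a similarity score to a predicted error distance
#'
#' Inverts the similarity transform `S_r = 1 / (1 + (d / 3.9)^2)`:
#' `d = 3.9 * sqrt(1/s - 1)` Angstroms.  Similarities are floored at
#' `floor` (default 0.01) before inversion, capping the reported local error
#' at `3.9 * sqrt(99) ~ 38.8` A; non-positive similarities are a domain error.
#'
#' @param s similarity values in `(0, 1]`.
#' @param floor minimum similarity used in the inversion.
#' @return Distances in Angstroms.
#' @export
similarity_to_distance <- function(s, floor = 0.01) {
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("similarity must be in (0, 1]")
  }
  s <- pmax(pmin(s, 1), floor)
  3.9 * sqrt(1 / s - 1)
}

#' Convert an error distance to a similarity score
#'
#' The forward transform `S_r = 1 / (1 + (d / 3.9)^2)`.
#'
#' @param d distances in Angstroms (non-negative; `NA` passes through).
#' @return Similarities in `(0, 1]`.
#' @export
distance_to_similarity <- function(d) {
  1 / (1 + (d / 3.9)^2)
}

#' Write combiner weights to a portable text file
#'
#' Plain-text, diffable format: a version line, the feature order, the layer
#' dimensions, then the weight matrices row by row at full precision.
#'
#' @param network a `combiner_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(network, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "modqa6-combiner 1",
    paste("feature_order", network$feature_order),
    paste("dims", NN_INPUTS, NN_HIDDEN, 1),
    vapply(seq_len(NN_INPUTS), function(i) fmt(network$weights_in[i, ]), ""),
    fmt(network$bias_hidden),
    fmt(network$weights_out),
    fmt(network$bias_out))
  writeLines(lines, path)
  invisible(path)
}

#' Read combiner weights written by [write_weights()]
#'
#' @param path path to a weight file.
#' @return A `combiner_network`.
#' @export
read_weights <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "modqa6-combiner")) {
    stop("not a combiner weight file: ", path)
  }
  forder <- sub("^feature_order ", "", lines[2])
  if (forder != NN_FEATURE_ORDER) {
    stop("weight file feature order '", forder,
         "' does not match this build ('", NN_FEATURE_ORDER, "')")
  }
  dims <- as.integer(strsplit(lines[3], " ")[[1]][-1])
  if (!identical(dims, c(NN_INPUTS, NN_HIDDEN, 1L))) {
    stop("weight file dimensions ", paste(dims, collapse = "x"),
         " do not match the fixed 30-15-1 architecture")
  }
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  W1 <- t(vapply(lines[3 + seq_len(NN_INPUTS)], num, numeric(NN_HIDDEN)))
  b1 <- num(lines[4 + NN_INPUTS])
  W2 <- num(lines[5 + NN_INPUTS])
  b2 <- num(lines[6 + NN_INPUTS])
  combiner_network(W1, b1, W2, b2)
}

#' Path to the frozen fixture-trained combiner weights
#'
#' The package ships one weight file trained on the synthetic fixture
#' benchmark (see the methods vignette for the exact command); it is intended
#' for reproducible scoring of fixture workspaces, not as a reproduction of
#' any server's production weights.
#'
#' @return File path of the bundled weight file.
#' @export
default_weights_path <- function() {
  system.file("extdata", "combiner_weights.txt", package = "modqa6",
              mustWork = TRUE)
}
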