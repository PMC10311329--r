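# Siamese contrastive embedding network.
#
# Two hidden blocks, each affine -> batch normalization -> leaky ReLU ->
# dropout, followed by an affine head into R^100. Both arms of the siamese
# pair share all parameters. The contrastive loss drives must-link pairs
# toward distance 0 and cannot-link pairs beyond the margin:
#
#   L = mean over pairs of [ y * d^2 + (1 - y) * max(margin - d, 0)^2 ]
#
# with d the Euclidean distance between the two embeddings and y = 1 for
# must-links, 0 for cannot-links. Optimized with Adam. Implemented directly
# in base R matrix algebra; the backward pass is verified against central
# finite differences in the test suite.

EMBEDDING_DIM <- 100L
MODEL_FORMAT_VERSION <- 1L

#' Create an untrained siamese embedding model
#'
#' @param input_dim Number of input features (136 tetramer classes +
#'   abundance columns).
#' @param hidden Integer vector of the two hidden-layer widths.
#' @param out_dim Embedding dimension (default 100).
#' @param dropout Dropout rate in `[0, 1)` applied after each hidden block.
#' @param leaky_slope Negative-part slope of the leaky rectifier.
#' @param seed Seed for weight initialization.
#' @return Object of class `siamese_model`.
#' @export
new_siamese_model <- function(input_dim, hidden = c(512L, 512L),
                              out_dim = EMBEDDING_DIM, dropout = 0.2,
                              leaky_slope = 0.01, seed = 0L) {
  stopifnot(input_dim >= 1, length(hidden) == 2L, all(hidden >= 1),
            dropout >= 0, dropout < 1)
  dims <- c(input_dim, hidden, out_dim)
  params <- with_seed(seed, {
    p <- list()
    for (l in 1:3) {
      fan_in <- dims[l]
      p[[paste0("W", l)]] <- matrix(
        rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / fan_in)),
        dims[l], dims[l + 1]
      )
      p[[paste0("b", l)]] <- numeric(dims[l + 1])
    }
    for (l in 1:2) {
      p[[paste0("gamma", l)]] <- rep(1, dims[l + 1])
      p[[paste0("beta", l)]] <- numeric(dims[l + 1])
    }
    p
  })
  structure(
    list(
      input_dim = input_dim, hidden = hidden, out_dim = out_dim,
      dropout = dropout, leaky_slope = leaky_slope,
      bn_eps = 1e-5, bn_momentum = 0.1,
      params = params,
      running = list(mean1 = numeric(hidden[1]), var1 = rep(1, hidden[1]),
                     mean2 = numeric(hidden[2]), var2 = rep(1, hidden[2])),
      trained = FALSE,
      format_version = MODEL_FORMAT_VERSION
    ),
    class = "siamese_model"
  )
}

#' @export
print.siamese_model <- function(x, ...) {
  cat("siamese embedding model: ", x$input_dim, " -> ",
      paste(x$hidden, collapse = " -> "), " -> ", x$out_dim,
      if (x$trained) " (trained)\n" else " (untrained)\n", sep = "")
  invisible(x)
}

# Forward pass.
# training = TRUE uses batch statistics, samples dropout masks (caller must
# manage the RNG), updates running statistics, and returns a cache for
# backward(). Inference uses running statistics and no dropout, so it is
# deterministic.
forward_pass <- function(model, X, training = FALSE) {
  if (ncol(X) != model$input_dim) {
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         model$input_dim)
  }
  p <- model$params
  eps <- model$bn_eps
  cache <- list(X = X)
  A <- X
  for (l in 1:2) {
    Z <- sweep(A %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
      mom <- model$bn_momentum
      model$running[[paste0("mean", l)]] <-
        (1 - mom) * model$running[[paste0("mean", l)]] + mom * mu
      model$running[[paste0("var", l)]] <-
        (1 - mom) * model$running[[paste0("var", l)]] + mom * v
    } else {
      mu <- model$running[[paste0("mean", l)]]
      v <- model$running[[paste0("var", l)]]
    }
    inv <- 1 / sqrt(v + eps)
    Zhat <- sweep(sweep(Z, 2, mu), 2, inv, "*")
    Y <- sweep(sweep(Zhat, 2, p[[paste0("gamma", l)]], "*"), 2,
               p[[paste0("beta", l)]], "+")
    A <- ifelse(Y > 0, Y, model$leaky_slope * Y)
    if (training && model$dropout > 0) {
      mask <- matrix(
        (runif(length(A)) >= model$dropout) / (1 - model$dropout),
        nrow(A), ncol(A)
      )
      cache[[paste0("mask", l)]] <- mask
      A <- A * mask
    }
    cache[[paste0("Ain", l)]] <- cache$X
    cache[[paste0("Zhat", l)]] <- Zhat
    cache[[paste0("inv", l)]] <- inv
    cache[[paste0("Y", l)]] <- Y
    cache$X <- A
  }
  out <- sweep(A %*% p$W3, 2, p$b3, "+")
  cache$Ain3 <- A
  list(out = out, cache = cache, model = model)
}

#' Embed feature rows (inference mode)
#'
#' Deterministic forward pass: dropout disabled, batch normalization uses the
#' running statistics accumulated during training.
#'
#' @param model A `siamese_model`.
#' @param X Feature matrix (rows = contigs).
#' @return Embedding matrix with `model$out_dim` columns, rownames preserved.
#' @export
model_forward <- function(model, X) {
  X <- as.matrix(X)
  out <- forward_pass(model, X, training = FALSE)$out
  rownames(out) <- rownames(X)
  out
}

# Backward pass through the network given d(loss)/d(out); returns gradients
# for every parameter. Uses the standard batch-norm backward identity
#   dZ = inv/n * (n dZhat - sum(dZhat) - Zhat * sum(dZhat * Zhat)).
backward_pass <- function(model, cache, dOut) {
  p <- model$params
  g <- list()
  g$W3 <- crossprod(cache$Ain3, dOut)
  g$b3 <- colSums(dOut)
  dA <- tcrossprod(dOut, p$W3)
  for (l in 2:1) {
    if (!is.null(cache[[paste0("mask", l)]])) {
      dA <- dA * cache[[paste0("mask", l)]]
    }
    Y <- cache[[paste0("Y", l)]]
    dY <- dA * ifelse(Y > 0, 1, model$leaky_slope)
    Zhat <- cache[[paste0("Zhat", l)]]
    g[[paste0("gamma", l)]] <- colSums(dY * Zhat)
    g[[paste0("beta", l)]] <- colSums(dY)
    dZhat <- sweep(dY, 2, p[[paste0("gamma", l)]], "*")
    n <- nrow(dZhat)
    s1 <- colSums(dZhat)
    s2 <- colSums(dZhat * Zhat)
    dZ <- sweep(
      dZhat - matrix(s1 / n, n, length(s1), byrow = TRUE) -
        sweep(Zhat, 2, s2 / n, "*"),
      2, cache[[paste0("inv", l)]], "*"
    )
    g[[paste0("W", l)]] <- crossprod(cache[[paste0("Ain", l)]], dZ)
    g[[paste0("b", l)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, p[[paste0("W", l)]])
  }
  g
}

#' Contrastive pair loss
#'
#' `y = 1` (must-link) pairs contribute the squared Euclidean distance;
#' `y = 0` (cannot-link) pairs contribute the squared hinge
#' `max(margin - d, 0)^2`. The batch value is the mean over pairs.
#'
#' @param e1,e2 Embedding matrices (one row per pair member).
#' @param y Vector of labels in `{0, 1}`.
#' @param margin Hinge margin (default 1).
#' @return Mean loss (a nonnegative scalar).
#' @export
contrastive_loss <- function(e1, e2, y, margin = 1) {
  e1 <- rbind(e1); e2 <- rbind(e2)
  stopifnot(identical(dim(e1), dim(e2)), length(y) == nrow(e1),
            margin > 0)
  d <- sqrt(rowSums((e1 - e2)^2))
  mean(y * d^2 + (1 - y) * pmax(margin - d, 0)^2)
}

#' Gradient of the contrastive loss with respect to the embeddings
#'
#' Analytic gradient of [contrastive_loss()] (mean over pairs). At d = 0 the
#' hinge term is non-differentiable; the zero subgradient is used.
#'
#' @inheritParams contrastive_loss
#' @return List with matrices `g1`, `g2` of `d(loss)/d(e1)` and `d(loss)/d(e2)`.
#' @export
contrastive_loss_grad <- function(e1, e2, y, margin = 1) {
  e1 <- rbind(e1); e2 <- rbind(e2)
  n <- nrow(e1)
  diff <- e1 - e2
  d <- sqrt(rowSums(diff^2))
  # y = 1: dL/de1 = 2 * diff ; y = 0, d < margin: -2 (margin - d)/d * diff
  coef <- ifelse(y == 1, 2,
                 ifelse(d > 0 & d < margin, -2 * (margin - d) / d, 0))
  g1 <- diff * (coef / n)
  list(g1 = g1, g2 = -g1)
}

#' Training configuration
#'
#' @param epochs Number of passes over the constraint pairs.
#' @param batch_size Pairs per mini-batch.
#' @param learning_rate Adam step size.
#' @param margin Contrastive hinge margin.
#' @param seed RNG seed covering shuffling and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 30L, batch_size = 256L,
                            learning_rate = 1e-3, margin = 1, seed = 0L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, margin > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, margin = margin,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train the siamese model on a constraint set
#'
#' Mini-batch Adam optimization of the contrastive loss. Must-link and
#' cannot-link pairs are dealt into each batch proportionally to their
#' overall ratio so gradients stay balanced. Fully deterministic given
#' `config$seed`.
#'
#' @param model A `siamese_model`.
#' @param features Feature matrix with contig ids as rownames.
#' @param constraints A `constraint_set`.
#' @param config A [training_config()].
#' @return List with `model` (trained) and `loss_trace` (mean loss per
#'   epoch).
#' @export
train_siamese <- function(model, features, constraints,
                          config = training_config()) {
  features <- as.matrix(features)
  ids <- rownames(features)
  if (is.null(ids)) stop("features must have contig ids as rownames")
  ml <- constraints$must_links
  cl <- constraints$cannot_links
  endpoints <- unique(c(ml$a, ml$b, cl$a, cl$b))
  unknown <- setdiff(endpoints, ids)
  if (length(unknown) > 0L) {
    stop("constraint references contig(s) with no feature row: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  if (config$epochs == 0L || (nrow(ml) + nrow(cl)) == 0L) {
    return(list(model = model, loss_trace = numeric(0)))
  }
  i1 <- c(match(ml$a, ids), match(cl$a, ids))
  i2 <- c(match(ml$b, ids), match(cl$b, ids))
  y <- c(rep(1, nrow(ml)), rep(0, nrow(cl)))
  n_pairs <- length(y)
  n_batches <- max(1L, ceiling(n_pairs / config$batch_size))

  adam <- list(
    m = lapply(model$params, function(x) x * 0),
    v = lapply(model$params, function(x) x * 0),
    t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
  loss_trace <- numeric(config$epochs)
  is_must <- y == 1

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      # deal shuffled must- and cannot-links round-robin over batches so each
      # batch keeps the global label ratio
      batch_of <- integer(n_pairs)
      batch_of[is_must] <- rep_len(seq_len(n_batches), sum(is_must))[
        order(sample.int(sum(is_must)))]
      batch_of[!is_must] <- rep_len(seq_len(n_batches), sum(!is_must))[
        order(sample.int(sum(!is_must)))]
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        sel <- which(batch_of == bi)
        if (length(sel) == 0L) next
        B <- length(sel)
        X <- features[c(i1[sel], i2[sel]), , drop = FALSE]
        fw <- forward_pass(model, X, training = TRUE)
        model <- fw$model
        e1 <- fw$out[seq_len(B), , drop = FALSE]
        e2 <- fw$out[B + seq_len(B), , drop = FALSE]
        loss <- contrastive_loss(e1, e2, y[sel], config$margin)
        gr <- contrastive_loss_grad(e1, e2, y[sel], config$margin)
        grads <- backward_pass(model, fw$cache, rbind(gr$g1, gr$g2))
        adam$t <- adam$t + 1L
        bc1 <- 1 - adam$beta1^adam$t
        bc2 <- 1 - adam$beta2^adam$t
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          adam$m[[nm]] <- adam$beta1 * adam$m[[nm]] + (1 - adam$beta1) * g
          adam$v[[nm]] <- adam$beta2 * adam$v[[nm]] + (1 - adam$beta2) * g^2
          model$params[[nm]] <- model$params[[nm]] -
            config$learning_rate * (adam$m[[nm]] / bc1) /
              (sqrt(adam$v[[nm]] / bc2) + adam$eps)
        }
        epoch_loss <- epoch_loss + loss * B
      }
      loss_trace[epoch] <- epoch_loss / n_pairs
    }
  })
  model$trained <- TRUE
  list(model = model, loss_trace = loss_trace)
}

#' Save / load a trained model
#'
#' The checkpoint is a single self-describing file carrying a format version,
#' layer widths, parameters and batch-normalization running statistics;
#' loading a checkpoint reproduces inference outputs exactly.
#'
#' @param model A `siamese_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "siamese_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("failed to read model checkpoint '", path,
         "' (truncated or not a checkpoint): ", conditionMessage(e))
  })
  if (!is.list(model) || is.null(model$format_version)) {
    stop("file '", path, "' is not a model checkpoint")
  }
  if (model$format_version != MODEL_FORMAT_VERSION) {
    stop("checkpoint format version ", model$format_version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  }
  model
}
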