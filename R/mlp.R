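#' Training configuration for the pose MLP
#'
#' Defaults follow the study protocol: up to 1000 Levenberg-Marquardt epochs,
#' 10-fold cross-validation, 50 repeated train/test simulations. The damping
#' schedule matches the classic LM recipe: start at \code{lambda0}, divide by
#' \code{lambda_down} after an accepted step, multiply by \code{lambda_up}
#' after a rejected one, abort above \code{lambda_max}.
#'
#' @param max_epochs maximum accepted LM iterations over the training set.
#' @param k_folds folds for cross-validation.
#' @param n_simulations repeated train/test simulations.
#' @param seed master seed.
#' @param lambda0,lambda_up,lambda_down,lambda_max LM damping schedule
#'   (multiplicative: \code{lambda_up > 1}, \code{lambda_down < 1}).
#' @param grad_tol stop when the loss-gradient infinity norm falls below
#'   this.
#' @param loss \code{"sse"} (sum of squared errors on one-hot targets, the
#'   native LM pairing) or \code{"xent"} (cross-entropy, trained by
#'   full-batch gradient descent with momentum; cheaper for very large n).
#' @param hidden hidden layer widths.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(max_epochs = 1000L, k_folds = 10L,
                         n_simulations = 50L, seed = 1L,
                         lambda0 = 1e-3, lambda_up = 10, lambda_down = 0.1,
                         lambda_max = 1e10, grad_tol = 1e-7,
                         loss = c("sse", "xent"), hidden = c(10L, 6L)) {
  loss <- match.arg(loss)
  stopifnot(max_epochs >= 1L, k_folds >= 2L, lambda0 > 0, lambda_up > 1,
            lambda_down > 0, lambda_down < 1, length(hidden) == 2L)
  structure(list(max_epochs = as.integer(max_epochs),
                 k_folds = as.integer(k_folds),
                 n_simulations = as.integer(n_simulations),
                 seed = as.integer(seed), lambda0 = lambda0,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 lambda_max = lambda_max, grad_tol = grad_tol,
                 loss = loss, hidden = as.integer(hidden)),
            class = "train_config")
}

#' Initialize the 10-10-6-4 multilayer perceptron
#'
#' Two tanh hidden layers (widths 10 and 6 by default, the first matching
#' the number of selected attributes) and a 4-unit softmax output giving the
#' class membership probabilities. Weights are drawn uniform on
#' [-0.5, 0.5] / sqrt(fan-in); biases start at zero.
#'
#' @param n_in number of input features.
#' @param hidden hidden layer widths (length 2).
#' @param n_out number of classes.
#' @param seed integer seed.
#' @return list of class \code{mlp_model} with weight matrices \code{W1}
#'   (hidden1 x n_in), \code{W2}, \code{W3} and bias vectors \code{b1},
#'   \code{b2}, \code{b3}.
#' @export
mlp_init <- function(n_in = 10L, hidden = c(10L, 6L), n_out = 4L,
                     seed = 1L) {
  set.seed(as.integer(seed))
  mk <- function(nout, nin)
    matrix(stats::runif(nout * nin, -0.5, 0.5) / sqrt(nin), nout, nin)
  structure(list(
    W1 = mk(hidden[1], n_in), b1 = numeric(hidden[1]),
    W2 = mk(hidden[2], hidden[1]), b2 = numeric(hidden[2]),
    W3 = mk(n_out, hidden[2]), b3 = numeric(n_out),
    sizes = c(n_in, hidden, n_out)
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("mlp_model:", paste(x$sizes, collapse = "-"),
      "(tanh, tanh, softmax);", length(pack_weights(x)), "parameters\n")
  invisible(x)
}

pack_weights <- function(model)
  c(as.vector(model$W1), model$b1, as.vector(model$W2), model$b2,
    as.vector(model$W3), model$b3)

unpack_weights <- function(model, w) {
  s <- model$sizes
  take <- function(k) {
    v <- w[seq_len(k)]
    w <<- w[-seq_len(k)]
    v
  }
  model$W1 <- matrix(take(s[2] * s[1]), s[2], s[1])
  model$b1 <- take(s[2])
  model$W2 <- matrix(take(s[3] * s[2]), s[3], s[2])
  model$b2 <- take(s[3])
  model$W3 <- matrix(take(s[4] * s[3]), s[4], s[3])
  model$b3 <- take(s[4])
  model
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass keeping layer activations (rows = samples)
mlp_forward_full <- function(model, X) {
  X <- rbind(X)
  A1 <- tanh(sweep(X %*% t(model$W1), 2L, model$b1, "+"))
  A2 <- tanh(sweep(A1 %*% t(model$W2), 2L, model$b2, "+"))
  Z3 <- sweep(A2 %*% t(model$W3), 2L, model$b3, "+")
  list(X = X, A1 = A1, A2 = A2, Z3 = Z3, P = softmax_rows(Z3))
}

#' Class membership probabilities for feature vectors
#'
#' @param model an \code{mlp_model}.
#' @param x a feature vector or an n x p matrix (one row per frame).
#'   Sentinel rows (all 999) are rejected: untracked frames are never
#'   force-classified.
#' @return n x 4 matrix of probabilities; each row sums to 1.
#' @export
mlp_forward <- function(model, x) {
  x <- rbind(x)
  if (any(!is.finite(x))) stop("non-finite input to mlp_forward")
  if (any(apply(x == SENTINEL, 1L, all)))
    stop("untracked (sentinel) input: no class probabilities are defined")
  mlp_forward_full(model, x)$P
}

#' Predicted class labels
#'
#' Argmax of the class probabilities; exact ties resolve to the lowest class
#' index.
#'
#' @inheritParams mlp_forward
#' @return integer labels in 1..4.
#' @export
mlp_predict <- function(model, x) {
  max.col(mlp_forward(model, x), ties.method = "first")
}

one_hot <- function(y, n_classes = 4L) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# Jacobian of the stacked output probabilities w.r.t. the packed weights.
# Returns P (n x C) and J (nC x n_par), rows ordered column-major like
# as.vector(P): all samples for class 1, then class 2, ...
mlp_jacobian <- function(model, X) {
  fw <- mlp_forward_full(model, X)
  n <- nrow(fw$X); C <- model$sizes[4]
  n_par <- length(pack_weights(model))
  J <- matrix(0, n * C, n_par)
  D1 <- 1 - fw$A1^2
  D2 <- 1 - fw$A2^2
  for (i in seq_len(C)) {
    # dP[, i] / dZ3 = P_i * (delta_ik - P_k)
    G3 <- -fw$P * fw$P[, i]
    G3[, i] <- G3[, i] + fw$P[, i]
    G2 <- (G3 %*% model$W3) * D2
    G1 <- (G2 %*% model$W2) * D1
    blocks <- cbind(
      G1[, rep(seq_len(ncol(G1)), ncol(fw$X))] *
        fw$X[, rep(seq_len(ncol(fw$X)), each = ncol(G1))],
      G1,
      G2[, rep(seq_len(ncol(G2)), ncol(fw$A1))] *
        fw$A1[, rep(seq_len(ncol(fw$A1)), each = ncol(G2))],
      G2,
      G3[, rep(seq_len(ncol(G3)), ncol(fw$A2))] *
        fw$A2[, rep(seq_len(ncol(fw$A2)), each = ncol(G3))],
      G3)
    J[(i - 1L) * n + seq_len(n), ] <- blocks
  }
  list(P = fw$P, J = J)
}

#' Train the MLP by Levenberg-Marquardt backpropagation
#'
#' Minimizes the sum of squared errors between the softmax outputs and the
#' one-hot targets with damped Gauss-Newton steps
#' \eqn{(J^\top J + \lambda I)\,\Delta w = J^\top e}. A step is accepted only
#' if it lowers the loss (so the accepted-loss history is non-increasing);
#' otherwise the damping grows and the step is retried. Training stops at
#' \code{max_epochs} accepted steps, when the damping exceeds
#' \code{lambda_max}, or when the gradient norm falls under \code{grad_tol}.
#'
#' @param model an \code{mlp_model}.
#' @param X n x p feature matrix (finite; sentinel rows excluded upstream).
#' @param y integer class labels 1..4 (at least 2 classes present), or an
#'   n x 4 one-hot matrix.
#' @param config a \code{\link{train_config}}.
#' @return list: \code{model} (trained), \code{loss} (accepted per-epoch SSE
#'   history, element 1 = initial loss), \code{converged}, \code{reason}.
#'   If the damping saturates the last model is still returned with
#'   \code{converged = FALSE}.
#' @export
train_lm <- function(model, X, y, config = train_config()) {
  X <- as.matrix(X)
  Y <- if (is.matrix(y)) y else one_hot(as.integer(y), model$sizes[4])
  if (nrow(X) != nrow(Y)) stop("X and y disagree on the number of rows")
  if (!is.matrix(y) && length(unique(y)) < 2L)
    stop("training requires at least 2 classes")
  if (any(!is.finite(X))) stop("non-finite training inputs")
  if (config$loss == "xent") return(train_gd(model, X, Y, config))

  w <- pack_weights(model)
  lambda <- config$lambda0
  jac <- mlp_jacobian(model, X)
  e <- as.vector(Y - jac$P)
  loss <- sum(e^2)
  history <- loss
  reason <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    g <- crossprod(jac$J, e)  # half the negative loss gradient
    if (max(abs(2 * g)) < config$grad_tol) {
      reason <- "grad_tol"
      break
    }
    A <- crossprod(jac$J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(A + diag(lambda, nrow(A)), g),
        error = function(err) NULL)
      if (!is.null(step)) {
        cand <- unpack_weights(model, w + as.vector(step))
        P2 <- mlp_forward_full(cand, X)$P
        e2 <- as.vector(Y - P2)
        loss2 <- sum(e2^2)
        if (is.finite(loss2) && loss2 < loss) {
          model <- cand
          w <- w + as.vector(step)
          loss <- loss2
          e <- e2
          lambda <- max(lambda * config$lambda_down, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * config$lambda_up
        if (lambda > config$lambda_max) break
      }
    }
    if (!accepted) {
      reason <- "lambda_max"
      break
    }
    history <- c(history, loss)
    jac <- mlp_jacobian(model, X)
  }
  list(model = model, loss = history,
       converged = reason %in% c("grad_tol", "max_epochs"),
       reason = reason)
}

# cross-entropy alternative: full-batch gradient descent with momentum
train_gd <- function(model, X, Y, config, lr = 0.05, momentum = 0.9) {
  n <- nrow(X)
  w <- pack_weights(model)
  vel <- numeric(length(w))
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    fw <- mlp_forward_full(model, X)
    loss <- -sum(log(pmax(fw$P[cbind(seq_len(n), max.col(Y))], 1e-300))) / n
    history <- c(history, loss)
    G3 <- (fw$P - Y) / n
    G2 <- (G3 %*% model$W3) * (1 - fw$A2^2)
    G1 <- (G2 %*% model$W2) * (1 - fw$A1^2)
    # gradient blocks in pack order: dL/dWl = t(Gl) %*% (layer input)
    grad <- c(as.vector(crossprod(G1, fw$X)), colSums(G1),
              as.vector(crossprod(G2, fw$A1)), colSums(G2),
              as.vector(crossprod(G3, fw$A2)), colSums(G3))
    vel <- momentum * vel - lr * grad
    w <- w + vel
    model <- unpack_weights(model, w)
    if (max(abs(grad)) < config$grad_tol) break
  }
  list(model = model, loss = history, converged = TRUE, reason = "gd")
}

# stratified fold assignment: within each class, deal shuffled rows
# round-robin, continuing the rotation across classes so overall fold sizes
# differ by at most one (exactly n/k when k divides n)
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  start <- 0L
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  fold
}

#' k-fold cross-validation of the pose MLP
#'
#' Stratified folds (the lying class is the rarest, ~14% of frames); each row
#' is validated exactly once. After the folds, a final model is retrained on
#' the whole training set.
#'
#' @param X,y training features and labels.
#' @param config a \code{\link{train_config}}.
#' @return list: \code{folds} (per-fold \code{\link{eval_report}}s),
#'   \code{fold_assignment}, \code{model} (retrained on all rows).
#' @export
cross_validate <- function(X, y, config = train_config()) {
  X <- as.matrix(X); y <- as.integer(y)
  if (nrow(X) < config$k_folds)
    stop("need at least k_folds = ", config$k_folds, " rows")
  fold <- stratified_folds(y, config$k_folds, config$seed)
  reports <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds)) {
    tr <- fold != f
    missing_cl <- setdiff(unique(y), unique(y[tr]))
    if (length(missing_cl) > 0L)
      warning("fold ", f, ": class(es) ", paste(missing_cl, collapse = ", "),
              " absent from training side; fold metrics mask them")
    fit <- train_lm(mlp_init(ncol(X), config$hidden, seed = config$seed + f),
                    X[tr, , drop = FALSE], y[tr], config)
    probs <- mlp_forward(fit$model, X[!tr, , drop = FALSE])
    reports[[f]] <- eval_report(y[!tr],
                                max.col(probs, ties.method = "first"),
                                probs)
  }
  final <- train_lm(mlp_init(ncol(X), config$hidden, seed = config$seed),
                    X, y, config)
  list(folds = reports, fold_assignment = fold, model = final$model)
}

#' Repeated train/test simulations
#'
#' Re-initializes and retrains the network \code{n_simulations} times
#' (seeds \code{seed + 1 .. seed + n}) on the full training set, each time
#' scoring the fixed held-out test set, to study classification robustness
#' against the random initialization. Training failures are recorded, not
#' fatal.
#'
#' @param train,test \code{pose_dataset}s (or lists with \code{X}, \code{y});
#'   their subjects must be disjoint when subject ids are present.
#' @param config a \code{\link{train_config}}.
#' @return list of class \code{simulation_set}: \code{reports} (one
#'   \code{\link{eval_report}} per successful simulation), \code{failures}
#'   (character), \code{models}.
#' @export
repeated_simulations <- function(train, test, config = train_config()) {
  if (!is.null(train$subject_id) && !is.null(test$subject_id)) {
    overlap <- intersect(unique(train$subject_id), unique(test$subject_id))
    if (length(overlap) > 0L)
      stop("train and test share subject(s): ",
           paste(overlap, collapse = ", "))
  }
  reports <- list(); models <- list(); failures <- character(0)
  for (i in seq_len(config$n_simulations)) {
    res <- tryCatch({
      fit <- train_lm(mlp_init(ncol(train$X), config$hidden,
                               seed = config$seed + i),
                      train$X, train$y, config)
      probs <- mlp_forward(fit$model, test$X)
      list(report = eval_report(test$y,
                                max.col(probs, ties.method = "first"),
                                probs),
           model = fit$model)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("simulation %d: %s", i,
                                      conditionMessage(res)))
    } else {
      reports[[length(reports) + 1L]] <- res$report
      models[[length(models) + 1L]] <- res$model
    }
  }
  structure(list(reports = reports, failures = failures, models = models),
            class = "simulation_set")
}

#' @export
print.simulation_set <- function(x, ...) {
  cat("simulation_set:", length(x$reports), "simulation(s),",
      length(x$failures), "failure(s)\n")
  if (length(x$reports) > 0) {
    acc <- vapply(x$reports, function(r) r$total_accuracy, 0)
    cat(sprintf("  mean total accuracy %.4f (SD %.4f)\n",
                mean(acc), stats::sd(acc)))
  }
  invisible(x)
}
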