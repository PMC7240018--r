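# Independent oracles and fixture builders used across the suite.

pack_weights_test <- function(model) skelpose:::pack_weights(model)

# random proper rotation via QR of a Gaussian matrix, sign-fixed to det +1
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_rigid <- function() {
  rigid_transform(random_rotation(), runif(3, -3, 3))
}

# brute-force per-frame counting oracle for one-vs-rest binary metrics
count_metrics_oracle <- function(y_true, y_pred, cl) {
  tp <- sum(y_pred == cl & y_true == cl)
  fp <- sum(y_pred == cl & y_true != cl)
  fn <- sum(y_pred != cl & y_true == cl)
  tn <- sum(y_pred != cl & y_true != cl)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       accuracy = (tp + tn) / length(y_true),
       sensitivity = sens,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
       precision = prec,
       f_score = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0)
}

# Mann-Whitney AUC oracle: P(score_pos > score_neg) + 0.5 P(tie)
auc_mw_oracle <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct loop transcription of the multi-class ReliefF update rule
# (Manhattan/range diff, m = all rows in order, k nearest hits/misses)
relieff_oracle <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  prior <- table(y) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) sum(abs(X[i, ] - X[j, ]) / rng))
    for (cl in names(prior)) {
      members <- which(y == cl)
      if (cl == as.character(y[i])) members <- setdiff(members, i)
      nb <- members[order(d[members])[seq_len(k)]]
      for (f in seq_len(p)) {
        diffs <- sum(abs(X[i, f] - X[nb, f]) / rng[f])
        if (cl == as.character(y[i])) {
          W[f] <- W[f] - diffs / (n * k)
        } else {
          W[f] <- W[f] +
            (prior[[cl]] / (1 - prior[[as.character(y[i])]])) * diffs / (n * k)
        }
      }
    }
  }
  W
}

# a small tracked frame table of jittered standing/sitting skeletons
sample_frame_table <- function(n = 10, height = 1.75, seed = 42) {
  set.seed(seed)
  a <- anthropometry(height)
  joints <- array(0, dim = c(n, N_JOINTS, 3))
  for (i in seq_len(n)) {
    p <- sample_pose_params(sample(1:4, 1), a)
    joints[i, , ] <- do.call(build_skeleton,
                             c(list(anthro = a, location = runif(2, 0, 4),
                                    heading = runif(1, 0, 360)), p))
  }
  make_frames(joints, timestamp = seq_len(n) / 30, subject_id = "S01")
}
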