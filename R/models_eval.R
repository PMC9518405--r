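#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Features sampled per split. \code{NULL} (default) applies the
#'   study's rule at fit time: 12 for a 184-column input, 20 for a
#'   500-column input, otherwise \code{floor(sqrt(p))}.
#' @param seed Seed for the tree-growing randomness.
#' @return An object of class \code{rf_config}.
#' @export
rf_config <- function(n_trees = 500L, mtry = NULL, seed = 1L) {
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_config")
}

default_mtry <- function(p) {
  if (p == 184L) 12L else if (p == 500L) 20L else max(1L, floor(sqrt(p)))
}

#' Train a random-forest wellness classifier
#'
#' Bagged decision trees with per-split feature subsampling and
#' majority-vote prediction (via \pkg{randomForest}).
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Binary 0/1 labels (0 = Better, 1 = Worse).
#' @param cfg An [rf_config()].
#' @return An object of class \code{wellness_rf}.
#' @export
train_rf <- function(features, labels, cfg = rf_config()) {
  stopifnot(inherits(cfg, "rf_config"))
  features <- as.matrix(features)
  y <- factor(labels, levels = c(0L, 1L))
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  p <- ncol(features)
  mtry <- if (is.null(cfg$mtry)) default_mtry(p) else as.integer(cfg$mtry)
  if (mtry < 1L || mtry > p)
    stop(sprintf("mtry = %d outside 1..%d", mtry, p), call. = FALSE)
  fit <- with_seed(cfg$seed,
                   randomForest::randomForest(x = features, y = y,
                                              ntree = cfg$n_trees,
                                              mtry = mtry))
  structure(list(fit = fit, mtry = mtry, cfg = cfg), class = "wellness_rf")
}

#' @export
predict.wellness_rf <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$fit, as.matrix(newdata))))
}

#' Particle swarm optimization configuration
#'
#' Defaults follow the study protocol: swarm of 20 particles, at most 200
#' iterations, termination tolerance 1e-3, acceleration factors c1 = 1.5 and
#' c2 = 1.7, and a search box of \[0.1, 100\] per dimension. The inertia
#' weight decreases linearly from 0.9 to 0.4 over the run.
#'
#' @param n_particles Swarm size.
#' @param max_iters Maximum iterations.
#' @param tol Termination tolerance: stop when the global best improves by
#'   less than this over \code{patience} consecutive iterations.
#' @param c1,c2 Cognitive and social acceleration factors.
#' @param bounds Length-2 numeric \code{c(min, max)} applied to every
#'   dimension, or a d x 2 matrix of per-dimension bounds.
#' @param inertia Length-2 start/end inertia weights.
#' @param patience Improvement window for the tolerance test.
#' @param seed Seed for initialization and the r1/r2 draws.
#' @return An object of class \code{pso_config}.
#' @export
pso_config <- function(n_particles = 20L, max_iters = 200L, tol = 1e-3,
                       c1 = 1.5, c2 = 1.7, bounds = c(0.1, 100),
                       inertia = c(0.9, 0.4), patience = 20L, seed = 1L) {
  stopifnot(n_particles >= 1L, max_iters >= 1L, c1 > 0, c2 > 0)
  if (is.matrix(bounds)) {
    if (any(bounds[, 1L] >= bounds[, 2L]))
      stop("bounds must satisfy min < max", call. = FALSE)
  } else if (bounds[1L] >= bounds[2L]) {
    stop("bounds must satisfy min < max", call. = FALSE)
  }
  structure(list(n_particles = as.integer(n_particles),
                 max_iters = as.integer(max_iters), tol = tol,
                 c1 = c1, c2 = c2, bounds = bounds, inertia = inertia,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "pso_config")
}

#' Global-best particle swarm minimization over a box
#'
#' Canonical PSO: velocity update
#' \code{v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)} with positions
#' clipped to the box and velocities clipped to the box width. The returned
#' global-best trace is non-increasing by construction.
#'
#' @param objective Function mapping a numeric vector of length \code{d} to
#'   a finite scalar.
#' @param d Number of dimensions.
#' @param cfg A [pso_config()].
#' @param init Optional n_particles x d matrix of initial positions
#'   (default: uniform over the box). Initial velocities are zero when
#'   \code{init} is supplied.
#' @return List with \code{par} (best position), \code{value} (best
#'   objective), and \code{trace} (global best per iteration).
#' @export
pso_minimize <- function(objective, d, cfg = pso_config(), init = NULL) {
  stopifnot(inherits(cfg, "pso_config"))
  b <- if (is.matrix(cfg$bounds)) cfg$bounds
       else matrix(rep(cfg$bounds, each = d), d, 2L)
  lo <- b[, 1L]; hi <- b[, 2L]
  vmax <- hi - lo
  np <- cfg$n_particles
  check <- function(val, x) {
    if (!is.finite(val))
      stop(sprintf("objective returned non-finite value at (%s)",
                   paste(signif(x, 6), collapse = ", ")), call. = FALSE)
    val
  }
  with_seed(cfg$seed, {
    if (is.null(init)) {
      X <- matrix(runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                  np, d)
      V <- matrix(runif(np * d, -1, 1), np, d) *
        matrix(rep(vmax, each = np), np, d) * 0.1
    } else {
      X <- matrix(init, np, d)
      V <- matrix(0, np, d)
    }
    fX <- apply(X, 1L, function(x) check(objective(x), x))
    P <- X; fP <- fX
    gi <- which.min(fP)
    g <- P[gi, ]; fg <- fP[gi]
    trace <- numeric(0)
    stall_ref <- fg; stall <- 0L
    for (it in seq_len(cfg$max_iters)) {
      w <- cfg$inertia[1L] +
        (cfg$inertia[2L] - cfg$inertia[1L]) *
          (it - 1L) / max(1L, cfg$max_iters - 1L)
      r1 <- matrix(runif(np * d), np, d)
      r2 <- matrix(runif(np * d), np, d)
      V <- w * V + cfg$c1 * r1 * (P - X) +
        cfg$c2 * r2 * (matrix(g, np, d, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(rep(-vmax, each = np), np, d)),
                matrix(rep(vmax, each = np), np, d))
      X <- pmin(pmax(X + V, matrix(rep(lo, each = np), np, d)),
                matrix(rep(hi, each = np), np, d))
      fX <- apply(X, 1L, function(x) check(objective(x), x))
      better <- fX < fP
      P[better, ] <- X[better, , drop = FALSE]
      fP[better] <- fX[better]
      gi <- which.min(fP)
      if (fP[gi] < fg) { fg <- fP[gi]; g <- P[gi, ] }
      trace <- c(trace, fg)
      # termination: no material global-best improvement over the window
      if (stall_ref - fg < cfg$tol) stall <- stall + 1L
      else { stall <- 0L; stall_ref <- fg }
      if (stall >= cfg$patience) break
    }
    list(par = g, value = fg, trace = trace)
  })
}

#' Train an RBF-SVM with PSO-selected hyperparameters
#'
#' PSO searches (C, gamma) over the configured box (default \[0.1, 100\]^2)
#' maximizing k-fold cross-validated accuracy on the training data; the
#' final SVM is refit on the full training set with the chosen pair. The
#' fold assignment is fixed once per call, so the search is deterministic
#' under the config seed.
#'
#' @inheritParams train_rf
#' @param pso_cfg A [pso_config()].
#' @param cv_folds Folds of the inner tuning cross-validation (default 5).
#' @return An object of class \code{wellness_pso_svm} with elements
#'   \code{fit}, \code{C}, \code{gamma}, \code{cv_accuracy}, \code{trace}.
#' @export
train_pso_svm <- function(features, labels, pso_cfg = pso_config(),
                          cv_folds = 5L) {
  stopifnot(inherits(pso_cfg, "pso_config"))
  features <- as.matrix(features)
  y <- factor(labels, levels = c(0L, 1L))
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  n <- nrow(features)
  folds <- with_seed(pso_cfg$seed + 1L,
                     sample(rep_len(seq_len(cv_folds), n)))
  objective <- function(par) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2L) next
      fit <- e1071::svm(features[tr, , drop = FALSE], y[tr],
                        kernel = "radial", cost = par[1L], gamma = par[2L],
                        scale = FALSE)
      pred <- predict(fit, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    1 - correct / n  # minimize CV error
  }
  opt <- pso_minimize(objective, d = 2L, cfg = pso_cfg)
  fit <- e1071::svm(features, y, kernel = "radial", cost = opt$par[1L],
                    gamma = opt$par[2L], scale = FALSE)
  structure(list(fit = fit, C = opt$par[1L], gamma = opt$par[2L],
                 cv_accuracy = 1 - opt$value, trace = opt$trace),
            class = "wellness_pso_svm")
}

#' @export
predict.wellness_pso_svm <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$fit, as.matrix(newdata))))
}

#' Confusion matrix and the four evaluation metrics
#'
#' Exact integer confusion counts and recall \code{TP/(TP+FN)}, precision
#' \code{TP/(TP+FP)}, F-score \code{2*REC*PRE/(REC+PRE)}, and accuracy
#' \code{100*(TP+TN)/total} (as a percentage). The positive class defaults
#' to label 1 ("Worse"): detecting deterioration is the clinical aim.
#' Metrics with a zero denominator are reported as 0 and flagged.
#'
#' @param predicted,actual Equal-length binary 0/1 vectors.
#' @param positive The label treated as positive (default 1).
#' @return An object of class \code{metrics_report}: list with
#'   \code{confusion} (TP, FP, FN, TN) and \code{metrics} (REC, PRE,
#'   F_score, ACC_percent), plus \code{degenerate} flags.
#' @export
evaluate <- function(predicted, actual, positive = 1L) {
  if (length(predicted) != length(actual))
    stop("`predicted` and `actual` lengths differ", call. = FALSE)
  pp <- predicted == positive
  ap <- actual == positive
  TP <- sum(pp & ap); FP <- sum(pp & !ap)
  FN <- sum(!pp & ap); TN <- sum(!pp & !ap)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  REC <- safe(TP, TP + FN, "REC")
  PRE <- safe(TP, TP + FP, "PRE")
  F_score <- safe(2 * REC * PRE, REC + PRE, "F_score")
  ACC <- 100 * (TP + TN) / (TP + FP + FN + TN)
  structure(
    list(confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
         metrics = c(REC = REC, PRE = PRE, F_score = F_score,
                     ACC_percent = ACC),
         positive = positive, degenerate = degenerate),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<metrics_report> TP=%d FP=%d FN=%d TN=%d (positive = %d)\n",
              cm["TP"], cm["FP"], cm["FN"], cm["TN"], x$positive))
  m <- x$metrics
  cat(sprintf("  REC = %.4f  PRE = %.4f  F-score = %.4f  ACC = %.2f%%\n",
              m["REC"], m["PRE"], m["F_score"], m["ACC_percent"]))
  if (length(x$degenerate))
    cat("  zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified hold-out split
#'
#' Per-class random split: \code{round(train_frac * n_class)} samples of
#' each class go to training, the remainder to testing.
#'
#' @param labels Binary label vector.
#' @param train_frac Training fraction (default 0.70).
#' @param seed Seed.
#' @return List with integer index vectors \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
split_holdout <- function(labels, train_frac = 0.70, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 samples", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      n_tr <- round(train_frac * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Repeated stratified split cross-validation
#'
#' \code{n_rounds} seeded stratified train/test resampling rounds at
#' \code{train_frac} (default three rounds at 67/33), with the metric
#' vector averaged arithmetically across rounds. Classical disjoint k-fold
#' partitioning is available with \code{scheme = "kfold"}.
#'
#' @param features Numeric matrix.
#' @param labels Binary 0/1 labels.
#' @param fit Function \code{(features, labels) -> model}.
#' @param predict_fn Function \code{(model, features) -> predicted labels};
#'   defaults to \code{predict()}.
#' @param n_rounds Number of rounds / folds (default 3).
#' @param train_frac Training fraction per round (resampling scheme only).
#' @param scheme \code{"resample"} (default) or \code{"kfold"}.
#' @param positive Positive class for the metrics.
#' @param seed Seed.
#' @return List with \code{mean} (averaged REC/PRE/F_score/ACC_percent) and
#'   \code{rounds} (per-round \code{metrics_report}s).
#' @export
cross_validate <- function(features, labels, fit, predict_fn = predict,
                           n_rounds = 3L, train_frac = 0.67,
                           scheme = c("resample", "kfold"), positive = 1L,
                           seed = 1L) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  seeds <- spawn_seeds(seed, n_rounds)
  fold_id <- if (scheme == "kfold")
    with_seed(seed, sample(rep_len(seq_len(n_rounds), length(labels))))
  rounds <- vector("list", n_rounds)
  for (rd in seq_len(n_rounds)) {
    idx <- if (scheme == "resample")
      split_holdout(labels, train_frac, seeds[rd])
    else
      list(train = which(fold_id != rd), test = which(fold_id == rd))
    model <- fit(features[idx$train, , drop = FALSE], labels[idx$train])
    pred <- predict_fn(model, features[idx$test, , drop = FALSE])
    rounds[[rd]] <- evaluate(pred, labels[idx$test], positive)
  }
  mean_metrics <- Reduce(`+`, lapply(rounds, `[[`, "metrics")) / n_rounds
  list(mean = mean_metrics, rounds = rounds)
}
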