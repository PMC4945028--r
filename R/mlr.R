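# Sequence + DNA-shape feature encoding and L2-regularised linear models
# compared by cross-validated R^2.

#' Feature specification for sequence models
#'
#' @param use_1mer,use_2mer,use_3mer include mono-/di-/trinucleotide
#'   indicator features.
#' @param use_shape include the four pentamer-derived shape features (minor
#'   groove width, propeller twist, roll, helix twist) per eligible
#'   position.
#' @param shape_normalization `"zscore"` (per feature column) or `"none"`.
#' @return list of class `feature_spec`.
#' @export
feature_spec <- function(use_1mer = TRUE, use_2mer = FALSE,
                         use_3mer = FALSE, use_shape = FALSE,
                         shape_normalization = c("zscore", "none")) {
  if (!any(use_1mer, use_2mer, use_3mer, use_shape)) {
    stop("at least one feature family must be enabled")
  }
  structure(list(use_1mer = use_1mer, use_2mer = use_2mer,
                 use_3mer = use_3mer, use_shape = use_shape,
                 shape_normalization = match.arg(shape_normalization)),
            class = "feature_spec")
}

#' Encode aligned sequences as a feature matrix
#'
#' For sequences of common length L: 1mer features are 4 indicator columns
#' per position (4L), 2mer 16 per adjacent pair (16(L-1)), 3mer 64 per
#' triple (64(L-2)). Shape features are 4 columns per eligible position
#' (positions 3..L-2, from the pentamer centered there: MGW and ProT are
#' properties of the central base, Roll and HelT of the central step),
#' optionally z-scored per column. Edge positions without pentamer context
#' are dropped, not padded.
#'
#' @param aligned_seqs character vector of equal-length A/C/G/T sequences.
#' @param spec a [feature_spec()].
#' @param shape_table a `shape_table` (required iff `spec$use_shape`).
#' @return numeric matrix with named columns (attribute `feature_names`
#'   mirrors `colnames`).
#' @export
encode_features <- function(aligned_seqs, spec, shape_table = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  aligned_seqs <- toupper(aligned_seqs)
  lens <- nchar(aligned_seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal lengths")
  validate_dna(aligned_seqs, allow_n = FALSE, what = "aligned sequence")
  L <- lens[1]
  n <- length(aligned_seqs)
  codes <- matrix(unlist(lapply(aligned_seqs, encode_seq)), nrow = n,
                  byrow = TRUE)
  blocks <- list()
  if (spec$use_1mer) blocks$k1 <- kmer_block(codes, 1L)
  if (spec$use_2mer) blocks$k2 <- kmer_block(codes, 2L)
  if (spec$use_3mer) blocks$k3 <- kmer_block(codes, 3L)
  if (spec$use_shape) {
    if (is.null(shape_table)) stop("shape features require a shape table")
    if (L < 5L) stop("shape features require sequence length >= 5")
    cols <- lapply(3:(L - 2L), function(p) {
      pent <- substr(aligned_seqs, p - 2L, p + 2L)
      m <- shape_lookup(shape_table, pent)
      colnames(m) <- sprintf("shape_%s_p%d", c("MGW", "ProT", "Roll", "HelT"), p)
      m
    })
    sh <- do.call(cbind, cols)
    if (spec$shape_normalization == "zscore") {
      mu <- colMeans(sh)
      sdv <- apply(sh, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      sh <- sweep(sweep(sh, 2L, mu, "-"), 2L, sdv, "/")
    }
    blocks$shape <- sh
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  attr(X, "feature_names") <- colnames(X)
  X
}

# indicator block for k-mers at every start position
#' @noRd
kmer_block <- function(codes, k) {
  n <- nrow(codes); L <- ncol(codes)
  n_pos <- L - k + 1L
  kmers <- apply(expand.grid(rep(list(.BASES), k))[, k:1, drop = FALSE],
                 1L, paste, collapse = "")
  out <- matrix(0, n, n_pos * 4^k)
  nm <- character(n_pos * 4^k)
  for (p in seq_len(n_pos)) {
    idx <- codes[, p]
    if (k > 1L) {
      for (j in 2:k) idx <- (idx - 1L) * 4L + codes[, p + j - 1L]
    }
    col0 <- (p - 1L) * 4^k
    out[cbind(seq_len(n), col0 + idx)] <- 1
    nm[col0 + seq_len(4^k)] <- sprintf("k%d_p%d_%s", k, p, kmers)
  }
  colnames(out) <- nm
  out
}

#' Fit an L2-regularised linear model (ridge regression)
#'
#' Minimises `||y - X w - w0||^2 + lambda ||w||^2` with an unpenalised
#' intercept, solved deterministically by the normal equations on centered
#' data.
#'
#' @param X numeric feature matrix.
#' @param y numeric response, `length(y) == nrow(X) >= 2`.
#' @param lambda ridge penalty, `>= 0`.
#' @return list of class `ridge_model`: `weights`, `intercept`, `lambda`,
#'   `feature_names`.
#' @export
fit_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single value >= 0")
  }
  mx <- colMeans(X)
  my <- mean(y)
  Xc <- sweep(X, 2L, mx, "-")
  yc <- y - my
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  w <- tryCatch(solve(A, crossprod(Xc, yc)),
                error = function(e) {
                  if (lambda == 0) {
                    stop("design matrix is singular with lambda = 0; ",
                         "use a positive penalty", call. = FALSE)
                  }
                  stop(e)
                })
  w <- drop(w)
  structure(list(weights = w, intercept = my - sum(mx * w), lambda = lambda,
                 feature_names = colnames(X)),
            class = "ridge_model")
}

#' Predict from a ridge model
#' @param object a `ridge_model`.
#' @param newdata feature matrix with the same columns as at fit time.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' @noRd
default_lambda_grid <- function() 10^seq(-4, 4, length.out = 17L)

# pick lambda on (X, y) by inner k-fold CV over a log grid
#' @noRd
select_lambda <- function(X, y, folds = 5L, grid = default_lambda_grid(),
                          seed = 1L) {
  set.seed(seed)
  n <- length(y)
  fold <- sample(rep_len(seq_len(folds), n))
  score <- vapply(grid, function(lam) {
    r2 <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_ridge(X[tr, , drop = FALSE], y[tr], lam)
      pred <- predict(m, X[!tr, , drop = FALSE])
      pearson_r2(pred, y[!tr])
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  grid[which.max(score)]
}

#' @noRd
pearson_r2 <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(pred, obs)^2
}

#' Cross-validated R-squared of a ridge model
#'
#' Fold assignment is a seeded shuffle. Within each training split, lambda
#' is chosen by inner 5-fold cross-validation over a logarithmic grid
#' (10^-4..10^4, 17 points) unless a fixed `lambda` is given. R^2 is the
#' squared Pearson correlation between the held-out predictions and
#' responses (`r2 = "ss"` switches to `1 - SS_res/SS_tot`).
#'
#' @param X feature matrix.
#' @param y numeric response.
#' @param folds number of folds (default 10).
#' @param lambda fixed ridge penalty, or `NULL` for inner-CV selection.
#' @param seed integer seed for the fold shuffle.
#' @param r2 `"pearson"` (default) or `"ss"`.
#' @return list of class `cv_result`: `per_fold_r2`, `mean_r2`,
#'   `fold_assignment_seed`, `fold` (the assignment itself), `lambdas`
#'   (per-fold choice).
#' @export
crossval_r2 <- function(X, y, folds = 10L, lambda = NULL, seed = 1L,
                        r2 = c("pearson", "ss")) {
  r2 <- match.arg(r2)
  n <- length(y)
  if (n < folds) stop("need at least `folds` observations")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  cv_with_folds(X, y, fold, lambda, seed, r2, fold_seed = seed)
}

#' @noRd
cv_with_folds <- function(X, y, fold, lambda, seed, r2 = "pearson",
                          fold_seed = NA_integer_) {
  folds <- max(fold)
  per <- numeric(folds)
  lams <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    lam <- if (is.null(lambda)) {
      select_lambda(X[tr, , drop = FALSE], y[tr], seed = seed + f)
    } else lambda
    lams[f] <- lam
    m <- fit_ridge(X[tr, , drop = FALSE], y[tr], lam)
    pred <- predict(m, X[!tr, , drop = FALSE])
    per[f] <- if (r2 == "pearson") {
      pearson_r2(pred, y[!tr])
    } else {
      1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[!tr]))^2)
    }
  }
  structure(list(per_fold_r2 = per, mean_r2 = mean(per),
                 fold_assignment_seed = fold_seed, fold = fold,
                 lambdas = lams),
            class = "cv_result")
}

#' Compare feature encodings by shared-fold cross-validation
#'
#' Fits each encoding on the same fold assignment and compares per-fold
#' R^2 with paired t and Wilcoxon signed-rank tests. Relative gains are
#' reported as `(R2_b - R2_a) / R2_a` in percent.
#'
#' @param encodings named list of [feature_spec()] objects.
#' @param aligned_seqs equal-length sequence block.
#' @param y numeric response (log2 intensity by convention).
#' @param folds number of folds (default 10).
#' @param seed integer seed shared by all models.
#' @param lambda fixed penalty or `NULL` for inner-CV selection.
#' @param shape_table `shape_table`, needed when any spec uses shape.
#' @return list of class `model_comparison`: `results` (data frame: name,
#'   mean_r2), `per_fold` (folds x models matrix), `pairwise` (data frame
#'   of paired tests and relative gain in percent).
#' @export
compare_models <- function(encodings, aligned_seqs, y, folds = 10L,
                           seed = 1L, lambda = NULL, shape_table = NULL) {
  if (is.null(names(encodings)) || any(names(encodings) == "")) {
    stop("encodings must be a named list")
  }
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  cvs <- lapply(encodings, function(sp) {
    X <- encode_features(aligned_seqs, sp, shape_table)
    cv_with_folds(X, y, fold, lambda, seed, fold_seed = seed)
  })
  per_fold <- vapply(cvs, function(cv) cv$per_fold_r2, numeric(folds))
  results <- data.frame(name = names(encodings),
                        mean_r2 = colMeans(per_fold),
                        stringsAsFactors = FALSE)
  pairs <- utils::combn(names(encodings), 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- per_fold[, pr[1]]; b <- per_fold[, pr[2]]
    d <- b - a
    if (all(d == 0)) {
      tt <- 1; wt <- 1   # identical models: no evidence of a difference
    } else {
      tt <- stats::t.test(b, a, paired = TRUE)$p.value
      wt <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE)$p.value)
    }
    data.frame(model_a = pr[1], model_b = pr[2],
               mean_diff = mean(d),
               gain_pct = 100 * (mean(b) - mean(a)) / mean(a),
               p_t = tt, p_wilcoxon = wt, stringsAsFactors = FALSE)
  }))
  structure(list(results = results, per_fold = per_fold,
                 pairwise = pairwise, fold_assignment_seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("cross-validated model comparison (shared folds)\n")
  print(transform(x$results, mean_r2 = round(mean_r2, 4)), row.names = FALSE)
  cat("pairwise:\n")
  print(transform(x$pairwise, mean_diff = signif(mean_diff, 3),
                  gain_pct = round(gain_pct, 2), p_t = signif(p_t, 3),
                  p_wilcoxon = signif(p_wilcoxon, 3)), row.names = FALSE)
  invisible(x)
}
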