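#' Ridge regression from hard-tissue to soft-tissue shape scores
#'
#' Solves `M = argmin ||hard %*% t(M) - soft||^2 + eta^2 ||M||^2` in closed
#' form (normal equations), mapping hard-tissue PC scores to soft-tissue PC
#' scores. With `eta = 0` and more specimens than hard dimensions this is
#' ordinary least squares; as `eta` grows predictions shrink toward the mean
#' shape.
#'
#' @param hard_scores `n x d_hard` matrix of hard-tissue PC scores.
#' @param soft_scores `n x d_soft` matrix of soft-tissue PC scores.
#' @param eta non-negative ridge weight.
#' @return `d_soft x d_hard` coefficient matrix `M`.
#' @export
fit_organ_regression <- function(hard_scores, soft_scores, eta = 0) {
  X <- as.matrix(hard_scores)
  Y <- as.matrix(soft_scores)
  if (nrow(X) != nrow(Y)) stop("specimen counts differ between blocks")
  if (eta < 0) stop("eta must be >= 0")
  G <- crossprod(X) + diag(eta^2, ncol(X))
  if (eta == 0 && rcond(G) < 1e-12)
    stop("singular system with eta = 0; use eta > 0")
  t(solve(G, crossprod(X, Y)))
}

#' Train a full organ (nose/mouth) hard-to-soft shape model
#'
#' GPA + shape PCA on each tissue block, then ridge regression between the
#' retained PC scores. When `eta` is NULL it is chosen by leave-one-out
#' cross-validation over the grid `{0, 0.01, 0.1, 1, 10}`.
#'
#' @param hard_configs,soft_configs lists of `k x 3` configurations, same
#'   specimens in the same order.
#' @param eta ridge weight, or NULL for LOOCV selection.
#' @param cumulative_threshold variance threshold for both shape spaces.
#' @param with_scaling remove size in the GPA of both blocks (default);
#'   FALSE keeps millimetre form coordinates, under which an exactly linear
#'   cohort is recovered exactly.
#' @return object of class `cf_organ_model`: `hard_space`, `soft_space`
#'   ([pca_shapes()] results), `M`, `eta`, `with_scaling`.
#' @export
fit_organ_model <- function(hard_configs, soft_configs, eta = NULL,
                            cumulative_threshold = 0.95,
                            with_scaling = TRUE) {
  n <- length(hard_configs)
  if (length(soft_configs) != n) stop("specimen counts differ")
  if (n < 3) stop("need at least 3 specimens")
  gh <- gpa(hard_configs, with_scaling = with_scaling)
  gs <- gpa(soft_configs, with_scaling = with_scaling)
  hs <- pca_shapes(gh, cumulative_threshold)
  ss <- pca_shapes(gs, cumulative_threshold)
  X <- hs$scores[, seq_len(hs$d), drop = FALSE]
  Y <- ss$scores[, seq_len(ss$d), drop = FALSE]
  if (is.null(eta)) eta <- select_eta(X, Y)
  M <- fit_organ_regression(X, Y, eta)
  structure(list(hard_space = hs, soft_space = ss, M = M, eta = eta,
                 with_scaling = with_scaling),
            class = "cf_organ_model")
}

select_eta <- function(X, Y, grid = c(0, 0.01, 0.1, 1, 10)) {
  n <- nrow(X)
  press <- vapply(grid, function(e) {
    err <- 0
    for (i in seq_len(n)) {
      M <- tryCatch(fit_organ_regression(X[-i, , drop = FALSE],
                                         Y[-i, , drop = FALSE], e),
                    error = function(cnd) NULL)
      if (is.null(M)) return(Inf)
      err <- err + sum((as.vector(M %*% X[i, ]) - Y[i, ])^2)
    }
    err
  }, 0)
  grid[which.min(press)]
}

#' Predict an organ's soft-tissue shape from its hard-tissue configuration
#'
#' Aligns the hard configuration into the model's hard shape space, projects
#' to PC scores, maps them through the regression matrix, and reconstructs
#' the soft shape as the mean soft shape plus the predicted linear
#' combination of soft PCs. The result is a shape-space configuration (unit
#' centroid size, alignment-free); metric placement is done downstream.
#'
#' @param model a [fit_organ_model()] result.
#' @param hard_config `k x 3` hard-tissue configuration.
#' @return predicted soft [cf_config()].
#' @export
predict_organ <- function(model, hard_config) {
  p <- config_points(hard_config)
  if (nrow(p) != nrow(model$hard_space$mean))
    stop("hard configuration has ", nrow(p), " points; model expects ",
         nrow(model$hard_space$mean))
  aligned <- align_to_mean(p, model$hard_space$mean,
                           with_scaling = isTRUE(model$with_scaling %||% TRUE))
  bh <- shape_scores(model$hard_space, aligned)
  bs <- as.vector(model$M %*% bh)
  cf_config(shape_from_scores(model$soft_space, bs))
}

#' Leave-one-out cross-validation of organ shape prediction
#'
#' For each specimen, refits shape spaces and regression on the remaining
#' specimens, predicts the held-out soft shape from its hard configuration,
#' and records the Procrustes distance to the true soft shape. Distances are
#' contextualized as ratios against the average distance between individuals
#' and the mean shape.
#'
#' @inheritParams fit_organ_model
#' @return list: `distances` (per specimen), `ratios`, `mean`, `sd`,
#'   `max_ratio`, `min_ratio`, `baseline` (the normalizing average
#'   individual-to-mean distance).
#' @export
organ_loocv <- function(hard_configs, soft_configs, eta = 0,
                        cumulative_threshold = 0.95, with_scaling = TRUE) {
  n <- length(hard_configs)
  if (n < 3) stop("cohort must have at least 3 specimens")
  dists <- numeric(n)
  for (i in seq_len(n)) {
    model <- fit_organ_model(hard_configs[-i], soft_configs[-i], eta = eta,
                             cumulative_threshold = cumulative_threshold,
                             with_scaling = with_scaling)
    pred <- predict_organ(model, hard_configs[[i]])
    dists[i] <- procrustes_distance(pred, soft_configs[[i]],
                                    with_scaling = with_scaling)
  }
  gs <- gpa(soft_configs, with_scaling = with_scaling)
  baseline <- mean(gs$distances)
  ratios <- dists / baseline
  list(distances = dists, ratios = ratios, mean = mean(dists),
       sd = stats::sd(dists), max_ratio = max(ratios),
       min_ratio = min(ratios), baseline = baseline)
}
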