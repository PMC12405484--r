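#' Fit Markov-blanket regressions on reference samples
#'
#' For every variable in the reference pDAG, each of its encoded columns
#' (one for a continuous variable, `k - 1` indicators for a discrete one) is
#' regressed by ordinary least squares, with intercept, on the encoded
#' columns of the variable's Markov blanket. A target with an empty Markov
#' blanket keeps only its intercept (the reference mean). A collinear design
#' falls back to the minimum-norm solution (with a message naming the
#' target).
#'
#' @param pdag A `reference_pdag` from [fges()].
#' @param ref_enc The `encoded_table` of the reference samples used to learn
#'   the pDAG.
#' @return An `mb_models` object: per-target coefficient sets, the Markov
#'   blanket column ids, training residual standard deviations, and hashes
#'   of the source pDAG and training data.
#' @export
fit_mb_regressions <- function(pdag, ref_enc) {
  stopifnot(inherits(pdag, "reference_pdag"), inherits(ref_enc, "encoded_table"))
  missing <- setdiff(pdag$nodes, ref_enc$variables)
  if (length(missing)) {
    stop(sprintf("reference data lacks pDAG variable(s): %s",
                 paste(missing, collapse = ", ")))
  }
  T <- ref_enc$T
  n <- nrow(T)
  targets <- list()
  for (v in pdag$nodes) {
    mb_vars <- markov_blanket(pdag, v)
    mb_cols <- unlist(ref_enc$column_map[mb_vars], use.names = FALSE)
    mb_names <- colnames(T)[mb_cols]
    X <- cbind(`(Intercept)` = 1, T[, mb_cols, drop = FALSE])
    Y <- T[, ref_enc$column_map[[v]], drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      message(sprintf("collinear Markov-blanket design for '%s'; using minimum-norm fit", v))
      B <- pinv_solve(X, Y)
    } else {
      B <- qr.coef(qrX, Y)
    }
    fitted <- X %*% B
    res <- Y - fitted
    for (j in seq_len(ncol(Y))) {
      tn <- colnames(Y)[j]
      targets[[tn]] <- list(
        target = tn, variable = v, mb_variables = mb_vars,
        mb_columns = mb_names,
        intercept = B[1L, j],
        coefficients = stats::setNames(B[-1L, j], mb_names),
        residual_sd = sqrt(mean(res[, j]^2))
      )
    }
  }
  structure(
    list(
      targets = targets,
      variables = pdag$nodes,
      n_ref = n,
      ref_sample_ids = ref_enc$sample_ids,
      pd = pdag$pd,
      pdag_hash = rlang::hash(list(pdag$dir, pdag$und)),
      encoding = ref_enc[c("column_map", "kinds", "levels", "ref_level", "variables")]
    ),
    class = "mb_models"
  )
}

#' @export
print.mb_models <- function(x, ...) {
  cat(sprintf(
    "<mb_models> %d regression targets over %d variables (n_ref = %d, pd = %g)\n",
    length(x$targets), length(x$variables), x$n_ref, x$pd
  ))
  invisible(x)
}

#' Predict pseudo-control outcomes for treatment samples
#'
#' Applies each reference Markov-blanket regression to the treatment
#' samples' Markov-blanket values: the prediction is the value the target
#' would take in the reference regime given the sample's blanket, the
#' point-estimate pseudo-control outcome (the noise term contributes zero).
#'
#' @param models An `mb_models` object.
#' @param treat_enc Treatment samples encoded with the reference scheme
#'   ([encode_with()]).
#' @return Numeric matrix, targets x treatment samples.
#' @export
predict_pseudo_control <- function(models, treat_enc) {
  stopifnot(inherits(models, "mb_models"), inherits(treat_enc, "encoded_table"))
  T <- treat_enc$T
  out <- matrix(
    NA_real_, length(models$targets), nrow(T),
    dimnames = list(names(models$targets), treat_enc$sample_ids)
  )
  for (tn in names(models$targets)) {
    m <- models$targets[[tn]]
    missing <- setdiff(m$mb_columns, colnames(T))
    if (length(missing)) {
      stop(sprintf("treatment data lacks Markov-blanket column(s): %s",
                   paste(missing, collapse = ", ")))
    }
    pred <- rep(m$intercept, nrow(T))
    if (length(m$mb_columns)) {
      pred <- pred + drop(T[, m$mb_columns, drop = FALSE] %*% m$coefficients)
    }
    out[tn, ] <- pred
  }
  out
}

#' Divergence scores: observed minus pseudo-control
#'
#' `D[i, j]` is the observed encoded value of target `i` in treatment sample
#' `j` minus its pseudo-control prediction. Rows corresponding to gene
#' programs measure per-sample program dysregulation; rows for discrete
#' indicators measure shifts in category propensity.
#'
#' @param treat_enc Treatment samples encoded with the reference scheme.
#' @param models An `mb_models` object.
#' @return A `divergence_matrix`: list with `D` (targets x samples),
#'   `target_ids`, `sample_ids` and metadata (`pd`, model hash).
#' @export
divergence_scores <- function(treat_enc, models) {
  pred <- predict_pseudo_control(models, treat_enc)
  obs <- t(treat_enc$T[, names(models$targets), drop = FALSE])
  D <- obs - pred
  structure(
    list(
      D = D,
      target_ids = rownames(D),
      sample_ids = colnames(D),
      pd = models$pd,
      model_hash = rlang::hash(models$targets)
    ),
    class = "divergence_matrix"
  )
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf(
    "<divergence_matrix> %d targets x %d samples (pd = %g)\n",
    nrow(x$D), ncol(x$D), x$pd
  ))
  invisible(x)
}

#' Select the FGES penalty discount by k-fold cross-validation
#'
#' Splits the reference samples into `k` folds. For each candidate penalty,
#' the reference pDAG and Markov-blanket regressions are learned on `k - 1`
#' folds and the mean squared divergence of the held-out fold is recorded;
#' the penalty minimizing the average held-out MSE is returned, giving the
#' most predictive ("most informative") reference network.
#'
#' @param ref_data Reference samples: a data frame (encoded internally; pass
#'   `kinds` through the `kinds` attribute or factors) or an
#'   `encoded_table`.
#' @param pd_grid Numeric vector of candidate penalty discounts.
#' @param k Number of folds (default 5, must be >= 2).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `pd` (the selected value) and `cv_trace`, a tibble of
#'   per-fold held-out MSEs.
#' @export
select_penalty_cv <- function(ref_data, pd_grid, k = 5, seed = 1) {
  if (length(pd_grid) == 0L) stop("pd_grid is empty")
  if (k < 2L) stop("k must be at least 2")
  enc <- if (inherits(ref_data, "encoded_table")) ref_data else one_hot_encode(ref_data)
  n <- nrow(enc$T)
  if (n / k < 20) stop(sprintf("each fold needs at least 20 samples (n = %d, k = %d)", n, k))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  trace <- list()
  for (pd in pd_grid) {
    for (f in seq_len(k)) {
      train <- subset_encoded(enc, fold != f)
      test <- subset_encoded(enc, fold == f)
      pdag <- fges(train, pd = pd)
      models <- fit_mb_regressions(pdag, train)
      D <- divergence_scores(test, models)$D
      trace[[length(trace) + 1L]] <- tibble::tibble(pd = pd, fold = f, mse = mean(D^2))
    }
  }
  trace <- dplyr::bind_rows(trace)
  by_pd <- dplyr::summarise(
    dplyr::group_by(trace, .data$pd),
    mse = mean(.data$mse), .groups = "drop"
  )
  list(pd = by_pd$pd[which.min(by_pd$mse)], cv_trace = trace)
}

# Row-subset of an encoded table (scheme shared, data restricted).
subset_encoded <- function(enc, rows) {
  out <- enc
  out$T <- enc$T[rows, , drop = FALSE]
  out$sample_ids <- enc$sample_ids[rows]
  out
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.divergence_matrix <- function(x, ...) {
  tibble::tibble(
    target = rep(x$target_ids, times = ncol(x$D)),
    sample_id = rep(x$sample_ids, each = nrow(x$D)),
    divergence = as.vector(x$D)
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.divergence_matrix <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$D),
    n_samples = ncol(x$D),
    pd = x$pd,
    mean_abs = mean(abs(x$D))
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.mb_models <- function(x, ...) {
  purrr::map_dfr(x$targets, function(m) {
    tibble::tibble(
      target = m$target,
      variable = m$variable,
      term = c("(Intercept)", m$mb_columns),
      estimate = c(m$intercept, unname(m$coefficients)),
      residual_sd = m$residual_sd
    )
  })
}

#' Heatmap of a divergence matrix
#'
#' @param object A `divergence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.divergence_matrix <- function(object, ...) {
  df <- tidy.divergence_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$target, fill = .data$divergence
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      axis.ticks.x = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = "sample", y = "target", fill = "divergence")
}
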