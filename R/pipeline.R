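#' End-to-end divergence analysis of a reference/treatment study
#'
#' Runs the full workflow on user data: latent gene-program discovery on the
#' reference expression ([fit_love()]), projection of treatment samples onto
#' the reference loadings, reference-network learning over programs and
#' optional clinical variables ([fges()]), Markov-blanket regression and
#' pseudo-control prediction, divergence scoring of the treatment samples,
#' and graph-based clustering of the divergence profiles under the
#' minimal-resolution rule.
#'
#' @param ref_expr,treat_expr Expression matrices (genes x samples) for the
#'   reference and treatment groups; gene sets must match. Pass `NULL` for
#'   both to analyze `ref_clinical`/`treat_clinical` alone (observed-variable
#'   mode, no factor discovery).
#' @param ref_clinical,treat_clinical Optional samples x variables data
#'   frames of clinical/mixed variables (kinds taken from the `kinds`
#'   attribute, else inferred).
#' @param pd Penalty discount for [fges()]; ignored when `pd_grid` is given.
#' @param pd_grid Optional grid for [select_penalty_cv()] on the reference.
#' @param folds Folds for the penalty cross-validation.
#' @param delta_grid Grid for [fit_love()] (`NULL` = its default).
#' @param n_pcs,resolutions,k Clustering parameters.
#' @param seed Integer seed controlling every stochastic stage.
#' @return A list with elements `factors` (`love_fit` or `NULL`), `pdag`,
#'   `models`, `divergence` (a `divergence_matrix`), `clusters` (a
#'   `cluster_result`, or `NULL` when there are no treatment samples) and
#'   `pd`.
#' @export
fit_and_score <- function(ref_expr = NULL, treat_expr = NULL,
                          ref_clinical = NULL, treat_clinical = NULL,
                          pd = 1, pd_grid = NULL, folds = 5,
                          delta_grid = NULL, n_pcs = 20,
                          resolutions = seq(0.1, 2, by = 0.1), k = 20,
                          seed = 1) {
  if (is.null(ref_expr) && is.null(ref_clinical)) {
    stop("provide reference expression and/or clinical data")
  }
  fit <- NULL
  ref_parts <- list()
  treat_parts <- list()
  kinds <- character(0)
  if (!is.null(ref_expr)) {
    ref_expr <- as.matrix(ref_expr)
    if (ncol(ref_expr) < 2L) stop("need at least 2 reference samples")
    fit <- fit_love(ref_expr, delta_grid = delta_grid)
    z_ref <- t(fit$Z_ref)
    colnames(z_ref) <- rownames(fit$Z_ref)
    ref_parts$factors <- as.data.frame(z_ref)
    kinds <- c(kinds, stats::setNames(
      rep("continuous", ncol(z_ref)), colnames(z_ref)
    ))
    if (!is.null(treat_expr) && ncol(as.matrix(treat_expr)) > 0L) {
      z_treat <- t(project_factors(fit, treat_expr)$Z)
      treat_parts$factors <- as.data.frame(z_treat)
    } else {
      treat_parts$factors <- ref_parts$factors[0, , drop = FALSE]
    }
  }
  if (!is.null(ref_clinical)) {
    rc <- as.data.frame(ref_clinical)
    ck <- attr(ref_clinical, "kinds")
    rc_kinds <- if (!is.null(ck)) {
      ck[setdiff(names(rc), "sample_id")]
    } else {
      vapply(rc[setdiff(names(rc), "sample_id")], function(v) {
        if (is.numeric(v)) "continuous" else "discrete"
      }, character(1))
    }
    rc$sample_id <- NULL
    ref_parts$clinical <- rc
    kinds <- c(kinds, rc_kinds)
    tc <- as.data.frame(treat_clinical)
    tc$sample_id <- NULL
    treat_parts$clinical <- tc
  }
  ref_df <- do.call(cbind, unname(ref_parts))
  treat_df <- do.call(cbind, unname(treat_parts))
  enc_ref <- one_hot_encode(ref_df, kinds = kinds)

  if (!is.null(pd_grid)) {
    sel <- select_penalty_cv(enc_ref, pd_grid, k = folds, seed = derive_seed(seed, 3))
    pd <- sel$pd
  }
  pdag <- fges(enc_ref, pd = pd)
  models <- fit_mb_regressions(pdag, enc_ref)
  enc_treat <- encode_with(enc_ref, treat_df)
  div <- divergence_scores(enc_treat, models)
  clusters <- NULL
  if (ncol(div$D) == 0L) {
    warning("no treatment samples; skipping clustering")
  } else {
    clusters <- cluster_with_rule(
      div, resolutions = resolutions, n_pcs = n_pcs, k = k,
      seed = derive_seed(seed, 4)
    )
  }
  list(factors = fit, pdag = pdag, models = models, divergence = div,
       clusters = clusters, pd = pd)
}

#' Run the synthetic benchmark and report clustering agreement
#'
#' Generates `n_datasets` labelled studies with [build_benchmark()] and, for
#' each, clusters the treatment samples under several feature sets, scoring
#' agreement with the generating-network labels by ARI and AMI:
#'
#' * `raw` — the observed continuous variables directly (low-dimensional
#'   variant: the network's continuous nodes; high-dimensional variant: the
#'   expanded genes);
#' * `lagrace_cont` — divergence scores from a reference network over
#'   continuous variables only (low-dimensional) or recovered latent factors
#'   only (high-dimensional);
#' * `lagrace_mixed` — divergence scores with the discrete variables
#'   included alongside;
#' * `lagrace_truth`, `lagrace_truth_mixed` (high-dimensional only, when
#'   `include_truth = TRUE`) — divergence computed from the ground-truth
#'   factor scores instead of the recovered ones.
#'
#' @param n_datasets Number of independently simulated studies.
#' @param variant `"lowdim"` or `"highdim"`.
#' @param include_truth Also run the ground-truth-factor arms (high-dim).
#' @param pd Penalty discount for the reference-network learning.
#' @param delta_grid Grid for [fit_love()] (`NULL` = its default).
#' @param n_pcs,resolutions,k Clustering parameters.
#' @param seed Master seed.
#' @inheritParams build_benchmark
#' @return A tibble with one row per dataset x arm: `dataset`, `arm`, `ari`,
#'   `ami`, `n_clusters`, `resolution`.
#' @export
run_benchmark <- function(n_datasets = 1, variant = c("lowdim", "highdim"),
                          include_truth = FALSE,
                          p_cont = 50, p_disc = 25, mean_degree = 2,
                          n_perturbed = 3, edge_change_fraction = 0.15,
                          n_ref = 1000, n_per_net = 1000,
                          n_genes = 2500, sparsity = 0.01, noise_sd = 1,
                          pd = 1, delta_grid = NULL, n_pcs = 20,
                          resolutions = seq(0.1, 2, by = 0.1), k = 20,
                          seed = 1) {
  variant <- match.arg(variant)
  rows <- list()
  for (d in seq_len(n_datasets)) {
    bench <- build_benchmark(
      p_cont = p_cont, p_disc = p_disc, mean_degree = mean_degree,
      n_perturbed = n_perturbed, edge_change_fraction = edge_change_fraction,
      n_ref = n_ref, n_per_net = n_per_net,
      highdim = (variant == "highdim"), n_genes = n_genes,
      sparsity = sparsity, noise_sd = noise_sd,
      seed = derive_seed(seed, 1000 + d)
    )
    arms <- benchmark_arms(bench, variant, include_truth,
                           pd = pd, delta_grid = delta_grid, n_pcs = n_pcs,
                           resolutions = resolutions, k = k,
                           seed = derive_seed(seed, 2000 + d))
    for (a in names(arms)) {
      cl <- arms[[a]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset = d, arm = a,
        ari = adjusted_rand_index(cl$labels, bench$treatment_labels),
        ami = adjusted_mutual_information(cl$labels, bench$treatment_labels),
        n_clusters = cl$n_clusters, resolution = cl$resolution
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Cluster the treatment samples of one benchmark dataset under each arm.
benchmark_arms <- function(bench, variant, include_truth, pd, delta_grid,
                           n_pcs, resolutions, k, seed) {
  kinds <- attr(bench$reference, "kinds")
  cont_ids <- names(kinds)[kinds == "continuous"]
  disc_ids <- names(kinds)[kinds == "discrete"]
  cl_args <- list(resolutions = resolutions, n_pcs = n_pcs, k = k)
  run_cluster <- function(features, s_off) {
    do.call(cluster_with_rule, c(list(features, seed = derive_seed(seed, s_off)), cl_args))
  }
  run_div <- function(ref_df, treat_df, kinds_used, s_off) {
    enc_ref <- one_hot_encode(ref_df, kinds = kinds_used)
    pdag <- fges(enc_ref, pd = pd)
    models <- fit_mb_regressions(pdag, enc_ref)
    div <- divergence_scores(encode_with(enc_ref, treat_df), models)
    run_cluster(div, s_off)
  }
  arms <- list()
  if (variant == "lowdim") {
    arms$raw <- run_cluster(bench$treatment[, cont_ids], 1)
    arms$lagrace_cont <- run_div(
      bench$reference[, c("sample_id", cont_ids)],
      bench$treatment[, c("sample_id", cont_ids)],
      kinds[cont_ids], 2
    )
    arms$lagrace_mixed <- run_div(
      bench$reference, bench$treatment, kinds, 3
    )
  } else {
    arms$raw <- run_cluster(t(bench$treat_expression), 1)
    fit <- fit_love(bench$ref_expression, delta_grid = delta_grid)
    z_ref <- as.data.frame(t(fit$Z_ref))
    z_treat <- as.data.frame(t(project_factors(fit, bench$treat_expression)$Z))
    z_ref$sample_id <- bench$reference$sample_id
    z_treat$sample_id <- bench$treatment$sample_id
    fk <- stats::setNames(rep("continuous", nrow(fit$Z_ref)), rownames(fit$Z_ref))
    arms$lagrace_cont <- run_div(z_ref, z_treat, fk, 2)
    arms$lagrace_mixed <- run_div(
      cbind(z_ref[setdiff(names(z_ref), "sample_id")],
            bench$reference[, c(disc_ids, "sample_id")]),
      cbind(z_treat[setdiff(names(z_treat), "sample_id")],
            bench$treatment[, c(disc_ids, "sample_id")]),
      c(fk, kinds[disc_ids]), 3
    )
    if (include_truth) {
      zt_ref <- as.data.frame(t(bench$Z_ref))
      zt_treat <- as.data.frame(t(bench$Z_treat))
      tk <- stats::setNames(rep("continuous", nrow(bench$Z_ref)), rownames(bench$Z_ref))
      arms$lagrace_truth <- run_div(zt_ref, zt_treat, tk, 4)
      arms$lagrace_truth_mixed <- run_div(
        cbind(zt_ref, bench$reference[, disc_ids]),
        cbind(zt_treat, bench$treatment[, disc_ids]),
        c(tk, kinds[disc_ids]), 5
      )
    }
  }
  arms
}
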