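# Plain-text serializers for fitted objects: TSV for matrices, JSON for
# metadata, so that every artifact of a run can be inspected or consumed
# outside R.

#' Write a fitted factor model to TSV + JSON
#'
#' `A.tsv` (genes x factors) and `Z.tsv` (factors x samples) with row/column
#' ids, plus `model.json` holding the pure sets, the selected `delta`, the
#' AIC trace and the reference standardization.
#'
#' @param fit A [fit_love()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_love_model <- function(fit, dir) {
  stopifnot(inherits(fit, "love_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(fit$A, file.path(dir, "A.tsv"), "gene")
  write_matrix_tsv(fit$Z_ref, file.path(dir, "Z.tsv"), "factor")
  jsonlite::write_json(
    list(
      pure_sets = fit$pure_sets,
      delta = fit$delta,
      aic = fit$aic,
      trace = fit$trace,
      center = as.list(stats::setNames(fit$center, fit$gene_ids)),
      scale = as.list(stats::setNames(fit$scale, fit$gene_ids))
    ),
    file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Write a divergence matrix to TSV with a JSON metadata sidecar
#'
#' @param div A `divergence_matrix`.
#' @param path Output TSV path (targets x samples); metadata goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_divergence_tsv <- function(div, path) {
  stopifnot(inherits(div, "divergence_matrix"))
  write_matrix_tsv(div$D, path, "target")
  jsonlite::write_json(
    list(pd = div$pd, model_hash = div$model_hash,
         n_targets = nrow(div$D), n_samples = ncol(div$D)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Serialize Markov-blanket regression models as JSON
#'
#' @param models An `mb_models` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mb_models_json <- function(models, path) {
  stopifnot(inherits(models, "mb_models"))
  jsonlite::write_json(
    list(
      pd = models$pd,
      n_ref = models$n_ref,
      pdag_hash = models$pdag_hash,
      targets = lapply(models$targets, function(m) {
        list(variable = m$variable, mb_columns = m$mb_columns,
             intercept = m$intercept,
             coefficients = as.list(m$coefficients),
             residual_sd = m$residual_sd)
      })
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write cluster labels (and the 2-D embedding) to TSV
#'
#' @param cl A `cluster_result`.
#' @param path Output TSV path (`sample_id`, `cluster`); the embedding is
#'   written to `paste0(path, ".embedding.tsv")`.
#' @return `path`, invisibly.
#' @export
write_cluster_labels <- function(cl, path) {
  stopifnot(inherits(cl, "cluster_result"))
  utils::write.table(tidy.cluster_result(cl), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emb <- data.frame(sample_id = cl$sample_ids, cl$embedding)
  utils::write.table(emb, paste0(path, ".embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(M, path, id_name) {
  df <- data.frame(rownames(M) %||% seq_len(nrow(M)), M, check.names = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
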