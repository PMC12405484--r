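#' One-hot encode a mixed continuous/discrete table
#'
#' Continuous variables pass through unchanged (block width 1). A discrete
#' variable with `k` observed levels becomes `k - 1` binary indicators: the
#' reference level — the most frequent level, ties broken toward the lowest
#' level value — is dropped. The mapping from each original variable to its
#' contiguous block of encoded columns is recorded so that treatment data can
#' be encoded identically ([encode_with()]).
#'
#' @param data A data frame or tibble, samples in rows. A `sample_id` column,
#'   if present, is used for sample identifiers and excluded from encoding.
#' @param kinds Named character vector mapping variable names to
#'   `"continuous"` or `"discrete"`. Defaults to the `kinds` attribute of
#'   `data` (as produced by [sample_mixed()]), else factors/characters are
#'   discrete and numerics continuous.
#' @return An `encoded_table`: list with `T` (n x q numeric matrix),
#'   `column_map` (variable -> column indices of `T`), `kinds`, `levels`
#'   (observed levels per discrete variable), `ref_level`, and `sample_ids`.
#' @examples
#' d <- data.frame(x = rnorm(6), g = c(1, 1, 1, 2, 2, 3))
#' one_hot_encode(d, kinds = c(x = "continuous", g = "discrete"))$T
#' @export
one_hot_encode <- function(data, kinds = NULL) {
  data <- as.data.frame(data)
  sample_ids <- if ("sample_id" %in% names(data)) {
    as.character(data$sample_id)
  } else {
    rownames(data) %||% paste0("s", seq_len(nrow(data)))
  }
  data$sample_id <- NULL
  if (is.null(kinds)) kinds <- attr(data, "kinds")
  if (is.null(kinds)) {
    kinds <- vapply(data, function(v) {
      if (is.factor(v) || is.character(v) || is.logical(v)) "discrete" else "continuous"
    }, character(1))
  }
  kinds <- kinds[names(data)]
  if (anyNA(kinds)) stop("kinds missing for some variables")

  spec <- list()
  for (v in names(data)) {
    if (kinds[[v]] == "discrete") {
      vals <- as.character(data[[v]])
      tab <- table(vals)
      lv <- names(tab)
      if (length(lv) < 2L) stop(sprintf("discrete variable '%s' has fewer than 2 observed levels", v))
      # reference = modal level; ties toward the lowest (sorted first) level
      lv_sorted <- sort(lv)
      freq <- as.integer(tab[lv_sorted])
      ref <- lv_sorted[which.max(freq)]
      spec[[v]] <- list(levels = lv_sorted, ref = ref)
    } else {
      spec[[v]] <- list(levels = NULL, ref = NULL)
    }
  }
  enc <- structure(
    list(
      column_map = NULL, kinds = kinds,
      levels = lapply(spec, `[[`, "levels"),
      ref_level = lapply(spec, `[[`, "ref"),
      variables = names(data)
    ),
    class = "encoded_table"
  )
  build_encoding(enc, data, sample_ids)
}

# Shared worker: materialize the encoded matrix for `data` under the scheme
# held in `enc`; also fills column_map on first use.
build_encoding <- function(enc, data, sample_ids) {
  blocks <- list()
  column_map <- list()
  q <- 0L
  for (v in enc$variables) {
    if (enc$kinds[[v]] == "continuous") {
      B <- matrix(as.numeric(data[[v]]), ncol = 1L, dimnames = list(NULL, v))
    } else {
      vals <- as.character(data[[v]])
      lv <- enc$levels[[v]]
      unseen <- setdiff(unique(vals), lv)
      if (length(unseen)) {
        stop(sprintf("variable '%s': unseen level '%s'", v, unseen[1L]))
      }
      keep <- setdiff(lv, enc$ref_level[[v]])
      B <- vapply(keep, function(l) as.numeric(vals == l), numeric(length(vals)))
      B <- matrix(B, ncol = length(keep),
                  dimnames = list(NULL, paste0(v, ".", keep)))
    }
    blocks[[v]] <- B
    column_map[[v]] <- q + seq_len(ncol(B))
    q <- q + ncol(B)
  }
  enc$T <- do.call(cbind, blocks)
  rownames(enc$T) <- sample_ids
  enc$column_map <- column_map
  enc$sample_ids <- sample_ids
  enc
}

#' Encode new data with an existing encoding scheme
#'
#' Applies the variable kinds, level sets and reference levels recorded by
#' [one_hot_encode()] on the reference data to `newdata`. A level not seen in
#' the reference is an error naming the variable and level.
#'
#' @param enc An `encoded_table` from [one_hot_encode()].
#' @param newdata Data frame with the same variables.
#' @return An `encoded_table` for `newdata`.
#' @export
encode_with <- function(enc, newdata) {
  stopifnot(inherits(enc, "encoded_table"))
  newdata <- as.data.frame(newdata)
  sample_ids <- if ("sample_id" %in% names(newdata)) {
    as.character(newdata$sample_id)
  } else {
    rownames(newdata) %||% paste0("s", seq_len(nrow(newdata)))
  }
  newdata$sample_id <- NULL
  missing <- setdiff(enc$variables, names(newdata))
  if (length(missing)) {
    stop(sprintf("newdata is missing variable(s): %s", paste(missing, collapse = ", ")))
  }
  build_encoding(enc, newdata, sample_ids)
}

#' @export
print.encoded_table <- function(x, ...) {
  cat(sprintf(
    "<encoded_table> %d samples x %d encoded columns (%d variables)\n",
    nrow(x$T), ncol(x$T), length(x$variables)
  ))
  invisible(x)
}
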