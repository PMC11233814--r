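#' Ensemble of per-measure regressors
#'
#' Combines predictors trained independently on different microstructure
#' measures (e.g., FA, MD, NoS) of the same subjects. The ensemble prediction
#' is the unweighted arithmetic mean of the member predictions, which lets
#' complementary measures contribute equally.
#'
#' @param ... Fitted models ([scr_fit()], [mlp_fit()], or anything with a
#'   `predict(object, newdata)` method returning a numeric vector), or a
#'   single list of such models.
#' @return An object of class `scr_ensemble`.
#' @export
scr_ensemble <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      is.null(attr(members[[1]], "class"))) {
    members <- members[[1]] # a bare list of models was supplied
  }
  if (length(members) < 1L) abort("an ensemble needs at least one member")
  nm <- vapply(seq_along(members), function(i) {
    members[[i]]$measure_name %||% paste0("member", i)
  }, character(1))
  names(members) <- nm
  structure(list(members = members), class = "scr_ensemble")
}

#' Predict from an ensemble
#'
#' @param object An [scr_ensemble()].
#' @param newdata A list of feature tables, one per member and in member
#'   order (or named by measure). All tables must cover the same subjects in
#'   the same order.
#' @param ... Unused.
#' @return A named numeric vector: the elementwise mean of member predictions.
#' @export
predict.scr_ensemble <- function(object, newdata, ...) {
  members <- object$members
  if (inherits(newdata, "data.frame")) newdata <- list(newdata)
  if (length(newdata) != length(members)) {
    abort("need exactly one feature table per ensemble member")
  }
  if (!is.null(names(newdata)) && all(names(newdata) != "") &&
      all(names(members) %in% names(newdata))) {
    newdata <- newdata[names(members)]
  }
  ids <- lapply(newdata, function(t) {
    if (is.matrix(t)) rownames(t) else t$subject_id
  })
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[i]], ids[[1]])) {
      abort("feature tables are not aligned on the same subjects")
    }
  }
  preds <- mapply(
    function(m, tbl) as.numeric(predict(m, tbl)),
    members, newdata, SIMPLIFY = TRUE
  )
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  setNames(rowMeans(preds), ids[[1]])
}

#' @export
print.scr_ensemble <- function(x, ...) {
  cat(sprintf(
    "<scr_ensemble> %d member(s): %s\n",
    length(x$members), paste(names(x$members), collapse = ", ")
  ))
  invisible(x)
}
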