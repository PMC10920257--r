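## Set-algebra combination of residue-level predictions from several
## methods.  Residue numbering must refer to the same antigen structure; a
## warning is issued when two inputs share no residues at all.

.pred_keys <- function(x) {
  k <- if (inherits(x, "mimotree")) x$residues
       else if (is.data.frame(x)) x$key
       else x
  unique(as.character(k))
}

.check_overlap <- function(sets) {
  ns <- names(sets)
  if (is.null(ns)) ns <- paste0("prediction ", seq_along(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j && length(sets[[i]]) && length(sets[[j]]) &&
        !length(intersect(sets[[i]], sets[[j]])))
      warning(ns[i], " and ", ns[j], " share no residues; check that both ",
              "use the same structure and numbering")
  }
}

#' Union of method predictions
#'
#' @param preds List of two or more predictions (`mimotree` fits, prediction
#'   data frames, or character key vectors).
#' @return Sorted character vector of residue keys.
#' @export
combine_union <- function(preds) {
  if (length(preds) < 2) stop("need at least 2 predictions")
  sets <- lapply(preds, .pred_keys)
  .check_overlap(sets)
  sort(unique(unlist(sets, use.names = FALSE)))
}

#' Intersection of method predictions
#'
#' @inheritParams combine_union
#' @export
combine_intersection <- function(preds) {
  if (length(preds) < 2) stop("need at least 2 predictions")
  sets <- lapply(preds, .pred_keys)
  .check_overlap(sets)
  sort(Reduce(intersect, sets))
}

#' Majority vote over exactly three method predictions
#'
#' A residue is retained when it appears in at least two of the three
#' predictions.
#'
#' @param preds List of exactly three predictions.
#' @export
combine_majority <- function(preds) {
  if (length(preds) != 3) stop("majority vote needs exactly 3 predictions")
  sets <- lapply(preds, .pred_keys)
  .check_overlap(sets)
  all <- unique(unlist(sets, use.names = FALSE))
  votes <- vapply(all, function(k)
    sum(vapply(sets, function(s) k %in% s, NA)), 0L)
  sort(all[votes >= 2])
}

#' Base-plus-intersection ensemble
#'
#' `base` union (`a` intersect `b`): the base method's full prediction
#' augmented by residues on which the two other methods agree.
#'
#' @param base,a,b Predictions (`mimotree` fits, data frames or key
#'   vectors).
#' @export
combine_core <- function(base, a, b) {
  sets <- list(base = .pred_keys(base), a = .pred_keys(a), b = .pred_keys(b))
  .check_overlap(sets)
  sort(unique(c(sets$base, intersect(sets$a, sets$b))))
}
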