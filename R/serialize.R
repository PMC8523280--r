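#' Save / load a trained multilabel ensemble
#'
#' An ensemble is stored as a directory: a human-readable `manifest.json`
#' with the ensemble structure (scheme, label subsets, threshold, base
#' classifier spec, seeds) plus one serialized artifact per base model.
#' Reloading restores an object usable with `predict()`.
#'
#' @param object A fitted [rakel()] or [br()] ensemble.
#' @param dir Target directory (created; must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing ensemble directory.
#' @return `save_ensemble()` returns `dir` invisibly; `load_ensemble()`
#'   returns the ensemble object.
#' @export
save_ensemble <- function(object, dir, overwrite = FALSE) {
  if (!inherits(object, c("rakel", "br")))
    stop("object must be a rakel or br ensemble")
  if (dir.exists(dir) && length(dir(dir)) > 0L && !overwrite)
    stop("directory ", dir, " is not empty (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- class(object)[1]
  manifest <- list(
    scheme = scheme, l = object$l, label_names = object$label_names,
    p = object$p, base = unclass(object$base),
    n_models = length(object$models))
  if (scheme == "rakel")
    manifest <- c(manifest, list(k = object$k, m_subsets = object$m_subsets,
                                 threshold = object$threshold,
                                 seed = object$seed,
                                 subsets = object$subsets))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (j in seq_along(object$models))
    saveRDS(object$models[[j]], file.path(dir, sprintf("model_%03d.rds", j)))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  models <- lapply(seq_len(manifest$n_models), function(j)
    readRDS(file.path(dir, sprintf("model_%03d.rds", j))))
  base <- do.call(base_spec, manifest$base[c("algorithm", "trees", "cost",
                                             "exponent", "gamma", "seed")])
  if (manifest$scheme == "rakel") {
    subsets <- if (is.matrix(manifest$subsets))
      lapply(seq_len(nrow(manifest$subsets)), function(i)
        as.integer(manifest$subsets[i, ]))
    else lapply(manifest$subsets, as.integer)
    structure(list(subsets = subsets, models = models, l = manifest$l,
                   label_names = manifest$label_names, k = manifest$k,
                   m_subsets = manifest$m_subsets,
                   threshold = manifest$threshold, base = base,
                   seed = manifest$seed, p = manifest$p,
                   call = quote(load_ensemble())),
              class = "rakel")
  } else {
    structure(list(models = models, l = manifest$l,
                   label_names = manifest$label_names, base = base,
                   p = manifest$p, call = quote(load_ensemble())),
              class = "br")
  }
}
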