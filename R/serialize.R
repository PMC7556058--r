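#' Write an FCM model to a structured config file
#'
#' Serialises concepts, the signed edge list and transfer parameters to
#' YAML, so a map can be versioned, edited and reloaded.
#'
#' @param model An [fcm_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcm_config <- function(model, path) {
  stopifnot(inherits(model, "fcm_model"))
  nz <- which(model$weights != 0, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(nz)), function(k) list(
    source = rownames(model$weights)[nz[k, 1]],
    target = colnames(model$weights)[nz[k, 2]],
    weight = unname(model$weights[nz[k, 1], nz[k, 2]])
  ))
  cfg <- list(
    concepts = lapply(seq_len(nrow(model$concepts)), function(i)
      as.list(model$concepts[i, c("id", "name", "category", "role")])),
    edges = edges,
    transfer = list(kind = "sigmoid", lambda = model$lambda),
    clamp_inputs = model$clamp_inputs
  )
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' Read an FCM model from a structured config file
#'
#' @param path A YAML file written by [write_fcm_config()] (or hand-edited
#'   in the same schema).
#' @return An [fcm_model()].
#' @export
read_fcm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  concepts <- do.call(rbind, lapply(cfg$concepts, function(cc)
    data.frame(id = cc$id, name = cc$name, category = cc$category,
               role = cc$role, stringsAsFactors = FALSE)))
  n <- nrow(concepts)
  W <- matrix(0, n, n, dimnames = list(concepts$id, concepts$id))
  for (e in cfg$edges) W[e$source, e$target] <- e$weight
  fcm_model(concepts, W,
            lambda = cfg$transfer$lambda %||% 1,
            clamp_inputs = isTRUE(cfg$clamp_inputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
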