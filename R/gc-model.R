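#' @keywords internal
risk_levels <- function() c("low", "medium", "high")

#' Gastric cancer feature dictionary
#'
#' Loads the 27-feature data dictionary of the gastric cancer risk model from
#' a structured YAML config. Each feature carries its concept id (C1..C27),
#' label, category (personal, diet_food, systemic_condition,
#' stomach_condition), ordered category levels, observed cohort counts, and
#' the level-to-activation encoding. Levels are ordered by increasing
#' intensity of the factor itself and encoded equally spaced on \[0, 1\]
#' (a two-level feature maps to 0/1, a k-level feature to 0, 1/(k-1), ..., 1);
#' the *direction* of the risk effect is carried by the sign of the feature's
#' edge into the GC concept, not by the level order.
#'
#' @param path Path to a dictionary YAML; defaults to the packaged config.
#' @return A list of class `"gc_dictionary"`, one element per feature, each a
#'   list with `id`, `name`, `category`, `levels`, `counts`, `encoding`.
#' @export
gc_dictionary <- function(path = system.file("extdata", "gc_dictionary.yaml",
                                             package = "fcmrisk")) {
  raw <- yaml::read_yaml(path)
  feats <- lapply(raw$features, function(f) {
    k <- length(f$levels)
    if (k < 2L)
      stop("feature ", f$id, " must have at least two levels", call. = FALSE)
    if (length(f$counts) != k)
      stop("feature ", f$id, ": counts/levels length mismatch", call. = FALSE)
    enc <- seq(0, 1, length.out = k)
    names(enc) <- f$levels
    list(id = f$id, name = f$name, category = f$category,
         levels = as.character(f$levels), counts = as.numeric(f$counts),
         encoding = enc)
  })
  names(feats) <- vapply(feats, `[[`, character(1), "id")
  if (anyDuplicated(names(feats)))
    stop("duplicate feature ids in dictionary", call. = FALSE)
  structure(feats, class = "gc_dictionary")
}

#' @export
print.gc_dictionary <- function(x, ...) {
  cat("Gastric cancer feature dictionary:", length(x), "features\n")
  for (f in x)
    cat(sprintf("  %-4s %-24s [%s] %s\n", f$id, f$name, f$category,
                paste(f$levels, collapse = " < ")))
  invisible(x)
}

#' Encode patient records as FCM activation states
#'
#' Maps each record's categorical feature values to concept activations via
#' the dictionary's level encodings and appends the output (GC) concept
#' initialised at 0.
#'
#' @param records A data.frame with one column per feature id (extra columns
#'   such as `risk_label` are ignored), or a single named character vector.
#' @param dictionary A [gc_dictionary()].
#' @param output_id Id of the output concept appended to the state.
#' @return A numeric matrix, one row per record, one column per concept
#'   (features in dictionary order, then the output concept).
#' @export
encode_records <- function(records, dictionary = gc_dictionary(),
                           output_id = "GC") {
  if (is.vector(records) && !is.list(records))
    records <- as.data.frame(as.list(records), stringsAsFactors = FALSE)
  ids <- names(dictionary)
  missing_f <- setdiff(ids, names(records))
  if (length(missing_f))
    stop("record is missing feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  A <- matrix(0, nrow = n, ncol = length(ids) + 1L,
              dimnames = list(NULL, c(ids, output_id)))
  for (id in ids) {
    f <- dictionary[[id]]
    vals <- as.character(records[[id]])
    bad <- !(vals %in% f$levels)
    if (any(bad))
      stop("feature ", id, " (", f$name, "): undeclared level(s) ",
           paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
    A[, id] <- f$encoding[vals]
  }
  A
}

#' Decode an activation state back to category levels
#'
#' Inverse of [encode_records()] for activations that sit exactly on encoded
#' level values; used to round-trip the dictionary.
#'
#' @param state Numeric activation vector named by concept ids.
#' @param dictionary A [gc_dictionary()].
#' @return Named character vector of levels, one per feature.
#' @export
decode_state <- function(state, dictionary = gc_dictionary()) {
  out <- character(length(dictionary))
  names(out) <- names(dictionary)
  for (id in names(dictionary)) {
    f <- dictionary[[id]]
    i <- which(abs(f$encoding - state[[id]]) < 1e-9)
    if (length(i) != 1L)
      stop("activation for ", id, " does not match a declared level",
           call. = FALSE)
    out[[id]] <- f$levels[i]
  }
  out
}

#' Bundle an FCM with its feature dictionary and risk thresholds
#'
#' @param model An [fcm_model()] whose input concepts are the dictionary's
#'   feature ids plus one output concept.
#' @param dictionary A [gc_dictionary()].
#' @param thresholds Two increasing cutoffs in (0, 1) splitting the output
#'   activation into low/medium/high risk.
#' @return An object of class `"fcm_bundle"`.
#' @export
fcm_bundle <- function(model, dictionary, thresholds = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(model, "fcm_model"))
  if (length(thresholds) != 2L || thresholds[1] <= 0 ||
      thresholds[2] >= 1 || thresholds[1] >= thresholds[2])
    stop("`thresholds` must satisfy 0 < t1 < t2 < 1", call. = FALSE)
  if (!all(names(dictionary) %in% model$concepts$id))
    stop("model is missing concepts for some dictionary features",
         call. = FALSE)
  structure(list(model = model, dictionary = dictionary,
                 thresholds = thresholds),
            class = "fcm_bundle")
}

#' @export
print.fcm_bundle <- function(x, ...) {
  cat("FCM risk-assessment bundle\n")
  print(x$model)
  cat("  features:", length(x$dictionary),
      " risk thresholds:", paste(format(x$thresholds, digits = 4),
                                 collapse = " / "), "\n")
  invisible(x)
}

#' The default 28-concept gastric cancer map
#'
#' Builds the shipped gastric cancer bundle: 27 risk-factor concepts plus the
#' central GC output concept, connected by 38 signed edges whose weights are
#' derived from a packaged *synthetic* expert-opinion table (three synthetic
#' experts, linguistic terms) through SUM aggregation and centroid
#' defuzzification. The edge signs follow the documented risk directions
#' (e.g. negative for vegetable, fruit, milk, allergy history and
#' cardiovascular history; positive for smoking, salt, infection history).
#' This fixture is a plausible, documented configuration artifact — it is not
#' a matrix learned from patient data.
#'
#' Input concepts are clamped during inference: risk factors are exogenous
#' patient attributes, so only the GC concept (and, in unclamped variants,
#' downstream stomach-condition concepts) evolves.
#'
#' @param opinions_path CSV of expert opinions; defaults to the packaged
#'   synthetic table.
#' @param dictionary A [gc_dictionary()].
#' @param lambda Sigmoid steepness of the transfer function.
#' @param thresholds Risk classification cutoffs, see [fcm_bundle()].
#' @param clamp_inputs Hold risk-factor concepts fixed during inference.
#' @return An `"fcm_bundle"`.
#' @export
gc_bundle <- function(opinions_path = system.file(
                        "extdata", "gc_expert_opinions_synthetic.csv",
                        package = "fcmrisk"),
                      dictionary = gc_dictionary(),
                      lambda = 1,
                      thresholds = c(1 / 3, 2 / 3),
                      clamp_inputs = TRUE) {
  opinions <- utils::read.csv(opinions_path, stringsAsFactors = FALSE)
  ids <- c(names(dictionary), "GC")
  W <- weights_from_opinions(opinions, ids)
  concepts <- data.frame(
    id = ids,
    name = c(vapply(dictionary, `[[`, character(1), "name"), "gastric cancer"),
    category = c(vapply(dictionary, `[[`, character(1), "category"), "output"),
    role = c(rep("input", length(dictionary)), "output"),
    stringsAsFactors = FALSE
  )
  model <- fcm_model(concepts, W, lambda = lambda, clamp_inputs = clamp_inputs)
  fcm_bundle(model, dictionary, thresholds)
}

#' Threshold an output activation into a risk class
#'
#' Left-closed convention: `low` if `oc < t1`, `medium` if `t1 <= oc < t2`,
#' `high` otherwise.
#'
#' @param oc Numeric vector of output-concept activations in \[0, 1\].
#' @param thresholds Increasing pair `(t1, t2)` inside (0, 1).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_risk <- function(oc, thresholds = c(1 / 3, 2 / 3)) {
  if (anyNA(oc) || any(oc < 0) || any(oc > 1))
    stop("output activations must lie in [0, 1]", call. = FALSE)
  if (thresholds[1] <= 0 || thresholds[2] >= 1 ||
      thresholds[1] >= thresholds[2])
    stop("`thresholds` must satisfy 0 < t1 < t2 < 1", call. = FALSE)
  cls <- ifelse(oc < thresholds[1], "low",
                ifelse(oc < thresholds[2], "medium", "high"))
  factor(cls, levels = risk_levels())
}

#' Per-class output-concept target ranges
#'
#' The classification thresholds double as the class target ranges used by
#' the training termination criterion: class `low` targets
#' \[0, t1\], `medium` \[t1, t2\], `high` \[t2, 1\], each summarised by its
#' midpoint.
#'
#' @param thresholds Increasing pair `(t1, t2)` inside (0, 1).
#' @return data.frame with columns `class`, `t_min`, `t_max`, `t_mid`.
#' @export
risk_targets <- function(thresholds = c(1 / 3, 2 / 3)) {
  t_min <- c(0, thresholds[1], thresholds[2])
  t_max <- c(thresholds[1], thresholds[2], 1)
  data.frame(class = risk_levels(), t_min = t_min, t_max = t_max,
             t_mid = vapply(seq_along(t_min), function(i)
               target_midpoint(t_min[i], t_max[i]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Assess gastric cancer risk for patient records
#'
#' Encodes each record, iterates the map to a steady state, reads off the
#' converged GC activation and classifies it. Non-convergence within
#' `max_iter` steps is flagged, not fatal: the last state is still
#' classified.
#'
#' @param records data.frame of patient records (see [encode_records()]).
#' @param bundle An [fcm_bundle()], e.g. [gc_bundle()].
#' @param max_iter,eps Passed to [fcm_run()].
#' @return data.frame with columns `risk` (factor low/medium/high),
#'   `oc_value` and `converged`.
#' @export
assess_risk <- function(records, bundle = gc_bundle(), max_iter = 100,
                        eps = 0.002) {
  A <- encode_records(records, bundle$dictionary,
                      output_id = bundle$model$output[1])
  oc_col <- bundle$model$output[1]
  n <- nrow(A)
  oc <- numeric(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    run <- fcm_run(bundle$model, A[i, ], max_iter = max_iter, eps = eps)
    oc[i] <- run$trajectory[nrow(run$trajectory), oc_col]
    conv[i] <- run$converged
  }
  if (!all(conv))
    warning(sum(!conv), " record(s) did not converge within ", max_iter,
            " iterations; last state used", call. = FALSE)
  data.frame(risk = classify_risk(oc, bundle$thresholds),
             oc_value = oc, converged = conv)
}
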