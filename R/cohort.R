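#' Marginal level frequencies of the reference cohort
#'
#' Per-feature level probabilities derived from the dictionary's reported
#' counts (count / cohort size). These marginals drive the synthetic cohort
#' sampler.
#'
#' @param dictionary A [gc_dictionary()].
#' @return A list of class `"gc_marginals"`: per feature, a list with
#'   `levels` and `prob` (summing to 1).
#' @export
gc_marginals <- function(dictionary = gc_dictionary()) {
  m <- lapply(dictionary, function(f) {
    total <- sum(f$counts)
    if (total <= 0)
      stop("feature ", f$id, " has no probability mass", call. = FALSE)
    list(levels = f$levels, prob = f$counts / total)
  })
  structure(m, class = "gc_marginals")
}

#' Sample a synthetic patient cohort
#'
#' Draws each feature independently from its marginal level distribution.
#' Only marginal frequencies of the reference cohort are published, so no
#' between-feature dependence is modelled; `dependence` is a hook for a
#' user-supplied sampler of joint records and ships empty.
#'
#' @param n Number of records (>= 1).
#' @param marginals A [gc_marginals()] (or compatible list).
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @param dependence Optional function `(records, marginals)` returning a
#'   modified data.frame, applied after independent sampling.
#' @return data.frame of `n` records, one character column per feature id.
#' @export
sample_cohort <- function(n, marginals = gc_marginals(), seed = 1,
                          dependence = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  for (id in names(marginals)) {
    m <- marginals[[id]]
    if (abs(sum(m$prob) - 1) > 1e-9)
      stop("marginal probabilities for ", id, " do not sum to 1",
           call. = FALSE)
    if (all(m$prob <= 0))
      stop("feature ", id, " has only zero-probability levels", call. = FALSE)
  }
  records <- with_local_seed(seed,
    as.data.frame(
      lapply(marginals, function(m)
        sample(m$levels, n, replace = TRUE, prob = m$prob)),
      stringsAsFactors = FALSE, col.names = names(marginals)
    )
  )
  if (!is.null(dependence)) records <- dependence(records, marginals)
  records
}

#' Label records with a ground-truth bundle
#'
#' Runs [assess_risk()] on every record and attaches the resulting class as
#' `risk_label`. Deterministic: the label depends only on the record and the
#' bundle.
#'
#' @param records data.frame of patient records.
#' @param bundle An [fcm_bundle()].
#' @param ... Passed to [assess_risk()].
#' @return `records` with an added factor column `risk_label`.
#' @export
label_cohort <- function(records, bundle = gc_bundle(), ...) {
  records$risk_label <- assess_risk(records, bundle, ...)$risk
  records
}

#' Train/test split of a cohort
#'
#' Disjoint, exhaustive partition with `round(fraction * n)` training
#' records. Stratified mode splits each class separately so class
#' proportions are preserved to within one record per class.
#'
#' @param records data.frame; stratified mode requires a `risk_label` column.
#' @param fraction Training fraction in (0, 1); the study protocol default is
#'   0.7 (560 records give a 392/168 split).
#' @param seed Integer seed for the random assignment.
#' @param stratified Preserve class proportions (default `TRUE` when a
#'   `risk_label` column is present).
#' @return list with data.frames `train` and `test`.
#' @export
split_cohort <- function(records, fraction = 0.7, seed = 1,
                         stratified = "risk_label" %in% names(records)) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(records)
  n_train <- round(fraction * n)
  idx <- with_local_seed(seed, {
    if (isTRUE(stratified)) {
      if (!"risk_label" %in% names(records))
        stop("stratified split requires a `risk_label` column", call. = FALSE)
      lab <- as.character(records$risk_label)
      classes <- unique(lab)
      sizes <- table(lab)[classes]
      if (any(sizes < 2))
        warning("class(es) with fewer than 2 records: ",
                paste(names(sizes)[sizes < 2], collapse = ", "),
                call. = FALSE)
      base <- floor(fraction * sizes)
      frac_part <- fraction * sizes - base
      extra <- n_train - sum(base)
      take <- base
      if (extra > 0) {
        ord <- order(frac_part, decreasing = TRUE)
        take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
      } else if (extra < 0) {
        ord <- order(frac_part)
        take[ord[seq_len(-extra)]] <- take[ord[seq_len(-extra)]] - 1
      }
      unlist(lapply(seq_along(classes), function(i) {
        members <- which(lab == classes[i])
        sample(members, take[i])
      }), use.names = FALSE)
    } else {
      sample(n, n_train)
    }
  })
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Marginal summary of a cohort
#'
#' Per feature and level: count and percentage of records. Percentages are
#' truncated (floored), not rounded, to the reporting precision, matching
#' the printed arithmetic of the reference cohort tables (85/560 reports as
#' 15.17, not 15.18).
#'
#' @param records data.frame of patient records.
#' @param dictionary A [gc_dictionary()] declaring features and level order.
#' @param digits Reporting precision of the percentage column.
#' @return data.frame with columns `feature`, `level`, `count`, `percent`.
#' @export
summarize_cohort <- function(records, dictionary = gc_dictionary(),
                             digits = 2) {
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(records)
  rows <- lapply(names(dictionary), function(id) {
    f <- dictionary[[id]]
    cnt <- vapply(f$levels, function(lv) sum(records[[id]] == lv), numeric(1))
    data.frame(feature = id, level = f$levels, count = as.integer(cnt),
               percent = trunc_digits(100 * cnt / n, digits),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

# Truncate (floor) to `digits` decimal places; a tiny nudge guards against
# values like 37.5 landing at 37.499999... in binary floating point.
trunc_digits <- function(x, digits = 2) {
  floor(x * 10^digits + 1e-9) / 10^digits
}
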