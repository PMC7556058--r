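#' Training control parameters for Nonlinear Hebbian Learning
#'
#' Collects and validates the NHL hyperparameters. The learning rate must
#' satisfy `0 < eta < 0.1` and the weight decay `0.9 < gamma < 1`; values
#' outside these ranges destabilise the weights and are rejected.
#'
#' @param eta Learning rate \eqn{\eta}, in (0, 0.1). Default 0.045.
#' @param gamma Weight decay \eqn{\gamma}, in (0.9, 1). Default 0.98.
#' @param e Termination tolerance on the change of output concepts between
#'   consecutive iterations (strict `<`). Default 0.002.
#' @param max_epochs Maximum number of passes over the training records.
#' @param record_cap Per-record cap on interleaved update iterations.
#' @param f1_tol,f1_patience Training stops when the epoch-mean squared
#'   distance of output concepts from their class targets fails to improve
#'   by more than `f1_tol` for `f1_patience` consecutive epochs.
#' @param seed Integer seed controlling the per-epoch record shuffle.
#' @return A list of class `"nhl_control"`.
#' @export
nhl_control <- function(eta = 0.045, gamma = 0.98, e = 0.002,
                        max_epochs = 20L, record_cap = 100L,
                        f1_tol = 1e-6, f1_patience = 3L, seed = 1L) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 0.1)
    stop("`eta` = ", format(eta),
         " rejected: the learning rate must lie in (0, 0.1)", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0.9 || gamma >= 1)
    stop("`gamma` = ", format(gamma),
         " rejected: the weight decay must lie in (0.9, 1)", call. = FALSE)
  if (!is.numeric(e) || length(e) != 1L || e <= 0)
    stop("`e` must be > 0", call. = FALSE)
  if (max_epochs < 1L || record_cap < 1L)
    stop("`max_epochs` and `record_cap` must be >= 1", call. = FALSE)
  structure(list(eta = eta, gamma = gamma, e = e,
                 max_epochs = as.integer(max_epochs),
                 record_cap = as.integer(record_cap),
                 f1_tol = f1_tol, f1_patience = as.integer(f1_patience),
                 seed = as.integer(seed)),
            class = "nhl_control")
}

#' Midpoint of an output-concept target range
#'
#' A risk class targets an interval \eqn{[T_{min}, T_{max}]} of the output
#' activation; its training target is the interval's midpoint
#' \eqn{T = (T_{min} + T_{max}) / 2}.
#'
#' @param t_min,t_max Interval endpoints, `t_min <= t_max`.
#' @return The midpoint.
#' @export
target_midpoint <- function(t_min, t_max) {
  if (any(t_min > t_max))
    stop("`t_min` must not exceed `t_max`", call. = FALSE)
  (t_min + t_max) / 2
}

#' Single Nonlinear Hebbian weight update
#'
#' The NHL recurrence for one expert-declared (nonzero) edge from concept
#' \eqn{j} to concept \eqn{i}:
#' \deqn{w' = \gamma w + \eta A_i (A_j - \mathrm{sgn}(w)\, w\, A_i),}
#' clipped to \[-1, 1\]. Co-activation of source and target strengthens the
#' link; the decay term forgets, and the sign-aware correction keeps the
#' update bounded. Only nonzero weights may be updated — the rule never
#' creates an edge the experts did not declare.
#'
#' @param w Current weight(s), nonzero, in \[-1, 1\].
#' @param a_i Activation of the target concept.
#' @param a_j Activation of the source concept.
#' @param eta Learning rate.
#' @param gamma Weight decay.
#' @return Updated weight(s), clipped to \[-1, 1\].
#' @export
nhl_update <- function(w, a_i, a_j, eta, gamma) {
  if (any(w == 0))
    stop("nhl_update applies only to nonzero (expert-declared) weights",
         call. = FALSE)
  out <- gamma * w + eta * a_i * (a_j - sign(w) * w * a_i)
  pmin(1, pmax(-1, out))
}

#' Squared distance of output concepts from their targets (F1)
#'
#' \eqn{F_1 = \sum_j (OC_j - T_j)^2} over the model's output concepts; zero
#' exactly when every output sits on its class-target midpoint.
#'
#' @param oc_values Output-concept activations.
#' @param targets Matching target midpoints.
#' @return Non-negative scalar.
#' @export
f1_criterion <- function(oc_values, targets) {
  if (length(oc_values) != length(targets))
    stop("`oc_values` and `targets` must have equal length", call. = FALSE)
  sum((oc_values - targets)^2)
}

#' Consecutive-iteration stability of output concepts (F2)
#'
#' `TRUE` iff every output concept changed by strictly less than `e` between
#' two consecutive iterations: \eqn{\max_j |OC_j(t+1) - OC_j(t)| < e}. The
#' inequality is strict, so a change of exactly `e` does not terminate.
#'
#' @param oc_next,oc_prev Output-concept activations at consecutive
#'   iterations.
#' @param e Positive tolerance; default 0.002.
#' @return Logical scalar.
#' @export
f2_criterion <- function(oc_next, oc_prev, e = 0.002) {
  if (length(oc_next) != length(oc_prev))
    stop("`oc_next` and `oc_prev` must have equal length", call. = FALSE)
  if (e <= 0) stop("`e` must be > 0", call. = FALSE)
  max(abs(oc_next - oc_prev)) < e
}

#' Fit FCM weights by Nonlinear Hebbian Learning
#'
#' Refines the expert weight matrix of a risk-assessment bundle on a labeled
#' cohort. Records are shuffled each epoch; for each record the activation
#' state is initialised from the record's encoding, the target-range
#' midpoint of its class label is selected, and one synchronous state update
#' is alternated with one Hebbian sweep over all nonzero weights
#' ([nhl_update()] with the pre-step activations) until the output-concept
#' change drops below `control$e` ([f2_criterion()]) or `control$record_cap`
#' iterations are reached. A record's F1 ([f1_criterion()]) is measured at
#' its final state; an epoch's F1 is the mean over records.
#'
#' Training stops when every record of an epoch terminated via F2, when the
#' epoch F1 has stopped improving (by more than `control$f1_tol` for
#' `control$f1_patience` consecutive epochs), or at `control$max_epochs`.
#'
#' Structural contract: weights that are zero in the expert matrix stay
#' exactly zero, every weight stays inside \[-1, 1\], and each learned
#' weight keeps its expert-declared sign (an update that would cross zero is
#' floored at magnitude 1e-6 instead of flipping the causal direction).
#'
#' @param bundle An [fcm_bundle()] supplying the expert matrix, encodings
#'   and thresholds.
#' @param data data.frame with one column per feature plus a `risk_label`
#'   column (levels low/medium/high).
#' @param control An [nhl_control()].
#' @param targets Per-class output target ranges, as returned by
#'   [risk_targets()]; defaults to ranges induced by the bundle thresholds.
#' @return An object of class `"fcm_nhl"` with components `bundle` (learned
#'   weights), `initial_weights`, `f1` (per-epoch trajectory), `epochs`,
#'   `terminated_by` (`"F1"`, `"F2"` or `"max_epochs"`), `control`,
#'   `targets`, `data` and `call`. Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate`.
#' @seealso [fcm_nhl_grid()], [assess_risk()]
#' @export
fcm_nhl <- function(bundle, data, control = nhl_control(),
                    targets = risk_targets(bundle$thresholds)) {
  stopifnot(inherits(bundle, "fcm_bundle"))
  if (!inherits(control, "nhl_control")) control <- do.call(nhl_control, control)
  if (nrow(data) == 0L) stop("empty training dataset", call. = FALSE)
  if (!"risk_label" %in% names(data))
    stop("`data` must carry a `risk_label` column", call. = FALSE)
  lab <- as.character(data$risk_label)
  unknown <- setdiff(unique(lab), targets$class)
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  model <- bundle$model
  oc_id <- model$output[1]
  oc_idx <- match(oc_id, model$concepts$id)
  clamp_idx <- if (model$clamp_inputs)
    which(model$concepts$role == "input") else integer(0)

  A0 <- encode_records(data, bundle$dictionary, output_id = oc_id)
  t_mid <- targets$t_mid[match(lab, targets$class)]

  W <- model$weights
  nz <- which(W != 0)
  sg <- sign(W[nz])
  j_idx <- ((nz - 1L) %% nrow(W)) + 1L   # source (row)
  i_idx <- ((nz - 1L) %/% nrow(W)) + 1L  # target (column)
  lambda <- model$lambda
  n_rec <- nrow(A0)

  f1_hist <- numeric(0)
  terminated_by <- "max_epochs"
  stalled <- 0L
  epoch <- 0L

  with_local_seed(control$seed, {
    repeat {
      epoch <- epoch + 1L
      ord <- sample.int(n_rec)
      f2_all <- TRUE
      f1_sum <- 0
      for (r in ord) {
        A <- A0[r, ]
        hit_f2 <- FALSE
        for (k in seq_len(control$record_cap)) {
          A_prev <- A
          # Synchronous state update under the current weights
          drive <- A_prev + as.vector(crossprod(W, A_prev))
          A <- 1 / (1 + exp(-lambda * drive))
          if (length(clamp_idx)) A[clamp_idx] <- A_prev[clamp_idx]
          # Hebbian sweep using the pre-step activations
          w <- nhl_update(W[nz], A_prev[i_idx], A_prev[j_idx],
                          control$eta, control$gamma)
          flip <- sign(w) != sg
          if (any(flip)) w[flip] <- sg[flip] * 1e-6
          W[nz] <- w
          if (f2_criterion(A[oc_idx], A_prev[oc_idx], control$e)) {
            hit_f2 <- TRUE
            break
          }
        }
        if (!hit_f2) f2_all <- FALSE
        f1_sum <- f1_sum + f1_criterion(A[oc_idx], t_mid[r])
      }
      f1_hist <- c(f1_hist, f1_sum / n_rec)

      if (f2_all) {
        terminated_by <- "F2"
        break
      }
      if (epoch > 1L) {
        improved <- f1_hist[epoch - 1L] - f1_hist[epoch] > control$f1_tol
        stalled <- if (improved) 0L else stalled + 1L
        if (stalled >= control$f1_patience) {
          terminated_by <- "F1"
          break
        }
      }
      if (epoch >= control$max_epochs) {
        terminated_by <- "max_epochs"
        break
      }
    }
  })

  learned <- model
  learned$weights <- W
  out_bundle <- bundle
  out_bundle$model <- learned

  structure(
    list(bundle = out_bundle,
         initial_weights = model$weights,
         f1 = f1_hist,
         epochs = epoch,
         terminated_by = terminated_by,
         control = control,
         targets = targets,
         data = data,
         call = match.call()),
    class = "fcm_nhl"
  )
}

#' @export
print.fcm_nhl <- function(x, ...) {
  cat("FCM trained by Nonlinear Hebbian Learning\n")
  cat(sprintf("  eta = %g, gamma = %g, e = %g\n",
              x$control$eta, x$control$gamma, x$control$e))
  cat(sprintf("  %d training record(s), %d epoch(s), terminated by %s\n",
              nrow(x$data), x$epochs, x$terminated_by))
  cat(sprintf("  final epoch F1 = %.6f\n", x$f1[length(x$f1)]))
  invisible(x)
}

#' @export
coef.fcm_nhl <- function(object, ...) object$bundle$model$weights

#' @export
summary.fcm_nhl <- function(object, ...) {
  W0 <- object$initial_weights
  W1 <- coef(object)
  nz <- W0 != 0
  drift <- abs(W1[nz] - W0[nz])
  res <- list(
    control = object$control,
    epochs = object$epochs,
    terminated_by = object$terminated_by,
    f1 = object$f1,
    n_edges = sum(nz),
    weight_drift = summary(drift),
    sign_preserved = all(sign(W1[nz]) == sign(W0[nz])),
    class_counts = table(object$data$risk_label)
  )
  class(res) <- "summary.fcm_nhl"
  res
}

#' @export
print.summary.fcm_nhl <- function(x, ...) {
  cat("Nonlinear Hebbian Learning fit\n")
  cat(sprintf("  eta = %g, gamma = %g, e = %g, seed = %d\n",
              x$control$eta, x$control$gamma, x$control$e, x$control$seed))
  cat(sprintf("  epochs: %d (terminated by %s), edges updated: %d\n",
              x$epochs, x$terminated_by, x$n_edges))
  cat("  epoch F1 trajectory:", paste(sprintf("%.5f", x$f1), collapse = " "),
      "\n")
  cat("  absolute weight drift from the expert matrix:\n")
  print(x$weight_drift)
  cat("  expert sign pattern preserved:", x$sign_preserved, "\n")
  cat("  training class counts:\n")
  print(x$class_counts)
  invisible(x)
}

#' @export
predict.fcm_nhl <- function(object, newdata = NULL, max_iter = 100,
                            eps = 0.002, ...) {
  if (is.null(newdata)) newdata <- object$data
  assess_risk(newdata, object$bundle, max_iter = max_iter, eps = eps)
}

#' @export
fitted.fcm_nhl <- function(object, ...) predict(object)$oc_value

#' @export
residuals.fcm_nhl <- function(object, ...) {
  oc <- fitted(object)
  t_mid <- object$targets$t_mid[
    match(as.character(object$data$risk_label), object$targets$class)]
  oc - t_mid
}

#' @export
plot.fcm_nhl <- function(x, ...) {
  graphics::plot(seq_along(x$f1), x$f1, type = "b", pch = 19,
                 xlab = "epoch", ylab = "mean F1",
                 main = "NHL termination criterion F1", ...)
  invisible(x)
}

#' @export
simulate.fcm_nhl <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (is.null(n)) n <- nrow(object$data)
  if (is.null(seed)) seed <- object$control$seed
  marg <- gc_marginals(object$bundle$dictionary)
  lapply(seq_len(nsim), function(s)
    label_cohort(sample_cohort(n, marg, seed = seed + s - 1L),
                 object$bundle))
}

#' Grid search over NHL learning parameters
#'
#' Trains once per (eta, gamma) pair on the training split with a fixed
#' seed, classifies the test split with the learned weights, and tabulates
#' the held-out confusion matrix and accuracy for each pair.
#'
#' @param bundle An [fcm_bundle()].
#' @param train,test Labeled cohort splits (each with `risk_label`).
#' @param etas,gammas Numeric grids; every value must respect the
#'   [nhl_control()] bounds.
#' @param control Template [nhl_control()] supplying the remaining
#'   parameters.
#' @return data.frame of class `"fcm_nhl_grid"` with columns `eta`, `gamma`,
#'   `accuracy` (percent, truncated to 2 dp) and an attribute `confusion`,
#'   a list of 3x3 confusion matrices (rows predicted, columns actual).
#' @export
fcm_nhl_grid <- function(bundle, train, test, etas, gammas,
                         control = nhl_control()) {
  if (length(etas) == 0L || length(gammas) == 0L)
    stop("`etas` and `gammas` must be non-empty", call. = FALSE)
  grid <- expand.grid(eta = etas, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  confusions <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ctl <- nhl_control(eta = grid$eta[g], gamma = grid$gamma[g],
                       e = control$e, max_epochs = control$max_epochs,
                       record_cap = control$record_cap,
                       f1_tol = control$f1_tol,
                       f1_patience = control$f1_patience,
                       seed = control$seed)
    fit <- fcm_nhl(bundle, train, control = ctl)
    pred <- predict(fit, test)
    cm <- confusion_matrix3(pred$risk, test$risk_label)
    confusions[[g]] <- cm
    acc[g] <- accuracy_pct(cm)
  }
  grid$accuracy <- trunc_digits(acc, 2)
  attr(grid, "confusion") <- confusions
  class(grid) <- c("fcm_nhl_grid", class(grid))
  grid
}

#' @export
print.fcm_nhl_grid <- function(x, ...) {
  cat("NHL learning-parameter grid (held-out accuracy, %):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Perturb the nonzero weights of a matrix
#'
#' Adds independent uniform noise on \[-amount, amount\] to every nonzero
#' entry (zero entries — undeclared edges — are untouched), clipping the
#' result to \[-1, 1\]. Used to set up parameter-recovery experiments where
#' training starts from a noisy version of a known ground-truth matrix.
#'
#' @param weights Signed weight matrix.
#' @param amount Half-width of the uniform noise.
#' @param seed Integer seed; the global RNG state is preserved.
#' @return The perturbed matrix.
#' @export
perturb_weights <- function(weights, amount = 0.2, seed = 1) {
  nz <- which(weights != 0)
  noise <- with_local_seed(seed, stats::runif(length(nz), -amount, amount))
  weights[nz] <- pmin(1, pmax(-1, weights[nz] + noise))
  weights
}
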