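#' Sigmoid transfer function
#'
#' Squashes the weighted-sum drive of a concept into the open unit interval.
#' The logistic form \eqn{f(x) = 1 / (1 + e^{-\lambda x})} is strictly
#' increasing, maps 0 to 0.5, and keeps every activation in (0, 1), which the
#' concept-value scale of the map requires.
#'
#' @param x Numeric vector of drives.
#' @param lambda Positive steepness parameter \eqn{\lambda}.
#' @return Numeric vector of the same length as `x`, all values in (0, 1).
#' @examples
#' fcm_transfer(0)            # 0.5
#' fcm_transfer(0.5)          # 0.62246...
#' @export
fcm_transfer <- function(x, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)
  1 / (1 + exp(-lambda * x))
}

#' Construct a fuzzy cognitive map
#'
#' A fuzzy cognitive map (FCM) is a signed directed graph whose nodes
#' ("concepts") hold activations in \[0, 1\] and whose weighted edges encode
#' causal influence. `weights[j, i]` is the influence of concept `j` on
#' concept `i`; positive weights promote the target, negative weights inhibit
#' it. Self-loops are disallowed: a concept's update never includes its own
#' weighted term.
#'
#' @param concepts A data.frame with columns `id`, `name`, `category`, `role`
#'   (`role` is `"input"` or `"output"`), or a character vector of ids (then
#'   all concepts are inputs except those named in `output`).
#' @param weights Square numeric matrix, entries in \[-1, 1\], zero diagonal.
#'   Rows are edge sources, columns edge targets.
#' @param lambda Steepness of the sigmoid transfer function.
#' @param output Character vector of output-concept ids (ignored when
#'   `concepts` is a data.frame carrying roles). At least one output concept
#'   is required.
#' @param clamp_inputs If `TRUE`, input concepts are held at their initial
#'   activation during inference; only non-input concepts evolve. The default
#'   `FALSE` lets every concept evolve.
#' @return An object of class `"fcm_model"`.
#' @seealso [fcm_step()], [fcm_run()], [weights_from_opinions()]
#' @export
fcm_model <- function(concepts, weights, lambda = 1, output = NULL,
                      clamp_inputs = FALSE) {
  if (is.character(concepts)) {
    if (is.null(output))
      stop("`output` must name at least one output concept", call. = FALSE)
    concepts <- data.frame(
      id = concepts,
      name = concepts,
      category = "unspecified",
      role = ifelse(concepts %in% output, "output", "input"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(concepts))
  req <- c("id", "name", "category", "role")
  missing_cols <- setdiff(req, names(concepts))
  if (length(missing_cols))
    stop("`concepts` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(concepts$id))
    stop("concept ids must be unique", call. = FALSE)
  if (!all(concepts$role %in% c("input", "output")))
    stop("concept roles must be 'input' or 'output'", call. = FALSE)
  out_ids <- concepts$id[concepts$role == "output"]
  if (length(out_ids) == 0L)
    stop("the model must declare at least one output concept", call. = FALSE)

  n <- nrow(concepts)
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n)
    stop("`weights` must be a ", n, "x", n, " numeric matrix", call. = FALSE)
  if (anyNA(weights))
    stop("`weights` contains missing values", call. = FALSE)
  if (any(abs(weights) > 1))
    stop("edge weights must lie in [-1, 1]", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("self-weights are not allowed: the diagonal must be zero", call. = FALSE)
  dimnames(weights) <- list(concepts$id, concepts$id)

  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)

  structure(
    list(
      concepts = concepts,
      weights = weights,
      lambda = lambda,
      output = out_ids,
      clamp_inputs = isTRUE(clamp_inputs)
    ),
    class = "fcm_model"
  )
}

#' @export
print.fcm_model <- function(x, ...) {
  n_edges <- sum(x$weights != 0)
  cat("Fuzzy cognitive map\n")
  cat("  concepts:", nrow(x$concepts),
      " edges:", n_edges,
      " lambda:", format(x$lambda), "\n")
  cat("  output concept(s):", paste(x$output, collapse = ", "), "\n")
  if (x$clamp_inputs) cat("  input concepts clamped during inference\n")
  invisible(x)
}

fcm_check_state <- function(model, state) {
  n <- nrow(model$concepts)
  if (!is.numeric(state) || length(state) != n)
    stop("activation state must be a numeric vector of length ", n,
         call. = FALSE)
  if (anyNA(state) || any(state < 0) || any(state > 1))
    stop("activations must lie in [0, 1]", call. = FALSE)
  invisible(state)
}

#' One synchronous FCM update
#'
#' Applies the synchronous state update
#' \eqn{A_i(k+1) = f(A_i(k) + \sum_{j \ne i} w_{ji} A_j(k))}: every concept is
#' recomputed from the previous state in one sweep. If the model clamps its
#' inputs, input concepts retain their current value.
#'
#' @param model An [fcm_model()].
#' @param state Numeric activation vector in \[0, 1\], one entry per concept.
#' @return The next activation vector.
#' @export
fcm_step <- function(model, state) {
  fcm_check_state(model, state)
  drive <- state + as.vector(crossprod(model$weights, state))
  nxt <- fcm_transfer(drive, model$lambda)
  if (model$clamp_inputs) {
    keep <- model$concepts$role == "input"
    nxt[keep] <- state[keep]
  }
  nxt
}

#' Iterate an FCM to a steady state
#'
#' Repeats [fcm_step()] until the largest absolute change across the full
#' state vector falls below `eps`, or `max_iter` steps have been taken.
#'
#' @inheritParams fcm_step
#' @param initial Initial activation vector.
#' @param max_iter Maximum number of update steps (>= 1).
#' @param eps Convergence tolerance on the max-norm state change (> 0). The
#'   default 0.002 mirrors the termination tolerance used during training.
#' @return A list of class `"fcm_run"`:
#'   \describe{
#'     \item{trajectory}{matrix of activations, one row per iteration,
#'       including the initial state as row 1}
#'     \item{converged}{logical, whether the tolerance was met}
#'     \item{iterations}{number of steps actually taken}
#'   }
#' @export
fcm_run <- function(model, initial, max_iter = 100, eps = 0.002) {
  fcm_check_state(model, initial)
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1)
    stop("`max_iter` must be >= 1", call. = FALSE)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be > 0", call. = FALSE)
  max_iter <- as.integer(max_iter)

  traj <- matrix(NA_real_, nrow = max_iter + 1L, ncol = length(initial),
                 dimnames = list(NULL, model$concepts$id))
  traj[1L, ] <- initial
  state <- initial
  converged <- FALSE
  k <- 0L
  while (k < max_iter) {
    nxt <- fcm_step(model, state)
    k <- k + 1L
    traj[k + 1L, ] <- nxt
    if (max(abs(nxt - state)) < eps) {
      state <- nxt
      converged <- TRUE
      break
    }
    state <- nxt
  }
  structure(
    list(trajectory = traj[seq_len(k + 1L), , drop = FALSE],
         converged = converged,
         iterations = k),
    class = "fcm_run"
  )
}

#' @export
print.fcm_run <- function(x, ...) {
  cat("FCM run:", x$iterations, "iteration(s),",
      if (x$converged) "converged" else "not converged", "\n")
  cat("final state:\n")
  print(round(x$trajectory[nrow(x$trajectory), ], 4))
  invisible(x)
}
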