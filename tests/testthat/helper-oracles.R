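# Independent oracles and small fixtures shared across the suite. These
# deliberately avoid the package's own code paths: plain-sum trapezoid on a
# fine grid, direct triangle evaluation, uniroot for the 1-D fixed point.

# Triangle membership evaluated directly from its three knots.
oracle_triangle <- function(x, left, peak, right) {
  pmax(0, pmin((x - left) / (peak - left), (right - x) / (right - peak)))
}

# The default bank's knots, restated independently.
oracle_bank <- list(
  very_low  = c(-0.15, 0.10, 0.35),
  low       = c(0.05, 0.30, 0.55),
  medium    = c(0.25, 0.50, 0.75),
  high      = c(0.45, 0.70, 0.95),
  very_high = c(0.65, 0.90, 1.15)
)

# Plain-sum trapezoid on an equally spaced grid.
oracle_trapz <- function(x, y) {
  h <- x[2] - x[1]
  sum((y[-1] + y[-length(y)]) / 2) * h
}

# Centroid of a SUM-aggregated term list on a 1e-5 grid.
oracle_centroid <- function(terms, step = 1e-5) {
  x <- seq(0, 1, by = step)
  mu <- numeric(length(x))
  for (tm in terms) {
    k <- oracle_bank[[tm]]
    mu <- mu + oracle_triangle(x, k[1], k[2], k[3])
  }
  oracle_trapz(x, x * mu) / oracle_trapz(x, mu)
}

# Fixed point of the 1-D logistic map x = 1/(1 + exp(-lambda x)).
oracle_sigmoid_fixed_point <- function(lambda = 1) {
  stats::uniroot(function(z) 1 / (1 + exp(-lambda * z)) - z,
                 c(0.5, 1), tol = 1e-14)$root
}

# A two-concept toy bundle (one binary feature driving one output) for
# hand-steppable training checks.
toy_dictionary <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "features:",
    "  - id: F1",
    "    name: toy factor",
    "    category: personal",
    "    levels: ['absent', 'present']",
    "    counts: [50, 50]"
  ), path)
  gc_dictionary(path)
}

toy_bundle <- function(w = 0.5, lambda = 1, clamp_inputs = TRUE) {
  dict <- toy_dictionary()
  W <- matrix(c(0, w, 0, 0), 2, 2, byrow = TRUE)
  concepts <- data.frame(
    id = c("F1", "OUT"), name = c("toy factor", "outcome"),
    category = c("personal", "output"), role = c("input", "output"),
    stringsAsFactors = FALSE
  )
  model <- fcm_model(concepts, W, lambda = lambda,
                     clamp_inputs = clamp_inputs)
  fcm_bundle(model, dict)
}

# Random valid FCM for property checks.
random_model <- function(n, lambda = 1) {
  W <- matrix(stats::runif(n * n, -1, 1), n, n)
  diag(W) <- 0
  fcm_model(paste0("K", seq_len(n)), W, lambda = lambda, output = "K1")
}
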