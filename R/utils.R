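#' @keywords internal
"_PACKAGE"

# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gliofuse <- function(msg, class) {
  stop(structure(
    class = c(class, "gliofuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "gliofuse_contract_error") {
  if (!isTRUE(cond)) stop_gliofuse(msg, class)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic code in the package goes
# through this so global set.seed() calls and package internals never
# interfere.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range so the result is a valid set.seed() argument.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# Largest-remainder apportionment of n items to proportions p (sums to n
# exactly; deterministic, ties broken by first index).
largest_remainder <- function(n, p) {
  assert_that(abs(sum(p) - 1) < 1e-8, "proportions must sum to 1")
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    order_idx <- order(-frac, seq_along(p))
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x >= 0, x, slope * x)

elu <- function(x) ifelse(x >= 0, x, expm1(x))

# Row-wise numerically stable softmax of a matrix.
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# He-normal init: sd = sqrt(2 / fan_in). Returns an array of the given dims.
he_normal <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# Xavier-uniform init: limit = sqrt(6 / (fan_in + fan_out)).
xavier_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}
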