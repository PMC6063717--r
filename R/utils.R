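# Internal helpers: seeded evaluation, seed derivation, small assertions.

# Evaluate `code` under a temporary RNG state; the caller's stream is
# untouched. Seeds must stay below 2^31 (R integers).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable substream derivation: hash (master, key) into [1, 2^31 - 2].
# Used so each null sample / base run / pipeline stage owns an independent,
# reproducible seed regardless of evaluation order.
derive_seed <- function(master, key) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  chars <- utf8ToInt(paste0("#", as.character(key)))
  for (c in chars) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

random_seed <- function() {
  sample.int(2147483646L, 1L)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_dynet <- function(msg, class = "dynet_error", ...) {
  abort(msg, class = c(class, "dynet_error"), ...)
}

# Strict upper-triangle values of a square matrix, column-major order.
upper_tri_values <- function(m) {
  m[upper.tri(m)]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to score recovery of planted ensembles. Invariant to label permutation;
#' 1 for identical partitions, near 0 for independent ones.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop_dynet("`a` and `b` must have the same length.")
  }
  n <- length(a)
  if (n == 0L) {
    return(NA_real_)
  }
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_idx - expected)
}
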