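# Small internal helpers shared across modules.

#' Derive a child seed deterministically from a run seed
#'
#' Every stochastic operation takes an explicit seed; a run-level seed fans
#' out to per-target / per-stage seeds through this hash so that fixing the
#' run seed fixes the whole pipeline. Results stay below 2^31.
#'
#' @param seed integer run seed.
#' @param ... further integer or character stream labels.
#' @return A derived integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, ""))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

# evaluate expr with a local RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# all unordered index pairs i < j for n atoms, as a p x 2 integer matrix
atomPairs <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = as.integer(idx[, "row"]), j = as.integer(idx[, "col"]))
}

# squared Euclidean distances between rows of two coordinate matrices
crossDist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
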