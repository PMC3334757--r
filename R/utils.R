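`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of a pipeline (simulation, estimation, diagnostics) and
#' per-subject simulation streams use sub-seeds derived from one master
#' seed, so each stage is independently reproducible and results do not
#' depend on the order in which subjects are processed.
#'
#' @param seed master seed (non-negative integer).
#' @param stream integer stream index (>= 0).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- ((seed %% m) * 48271) %% m
  s <- (s + (stream %% m) * 69621 + 1) %% m
  as.integer(s + 1L)
}

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) by
# Golub-Welsch on the symmetric Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  h <- h %||% pmax(1e-4, 1e-4 * abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    for (j in i:p) {
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Read / write a flat parameter file
#'
#' Plain-text `key = value` serialization of a [population_parameters()]
#' set, one parameter per line; `#` starts a comment.
#'
#' @param theta a `acet_params` object.
#' @param path file path.
#' @return `read_params()` returns an `acet_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(theta, path) {
  stopifnot(inherits(theta, "acet_params"))
  keys <- names(unclass(theta))
  lines <- sprintf("%s = %.17g", keys, unlist(unclass(theta)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line: ", lines[which(bad)[1]])
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), 1.0)
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  do.call(population_parameters, as.list(vals))
}
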