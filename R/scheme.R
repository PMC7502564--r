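#' Multi-shell gradient scheme
#'
#' A gradient scheme is a tibble with one row per diffusion measurement and
#' columns `b` (diffusion weighting, s/mm^2), `gx`, `gy`, `gz` (unit gradient
#' direction; zero vector allowed for b = 0) and `shell` (integer shell id,
#' 0 = unweighted). Measurements are grouped into shells by b-value within
#' `shell_tolerance`.
#'
#' @param b Numeric vector of b-values (s/mm^2), all >= 0.
#' @param directions n x 3 matrix of gradient directions; rows with b > 0 must
#'   be unit-norm to 1e-6.
#' @param shell_tolerance b-values closer than this (s/mm^2) share a shell;
#'   b <= shell_tolerance counts as unweighted. Default 50.
#' @return A `gradient_scheme` tibble.
#' @export
#' @examples
#' sch <- gradient_scheme(c(0, 1000, 1000), rbind(c(0, 0, 0), diag(3)[1:2, ]))
gradient_scheme <- function(b, directions, shell_tolerance = 50) {
  b <- as.numeric(b)
  directions <- as.matrix(directions)
  if (any(b < 0)) abort("b-values must be non-negative.")
  if (nrow(directions) != length(b) || ncol(directions) != 3) {
    abort("`directions` must be an n x 3 matrix matching length(b).")
  }
  nrm <- sqrt(rowSums(directions^2))
  weighted <- b > shell_tolerance
  if (any(abs(nrm[weighted] - 1) > 1e-6)) {
    abort("Gradient directions for b > 0 must be unit norm (tolerance 1e-6).")
  }
  # group b-values into shells
  ub <- sort(unique(b[weighted]))
  shell_b <- numeric(0)
  for (bi in ub) {
    if (length(shell_b) == 0 || bi - shell_b[length(shell_b)] > shell_tolerance) {
      shell_b <- c(shell_b, bi)
    }
  }
  shell <- integer(length(b))
  for (i in seq_along(shell_b)) {
    shell[weighted & abs(b - shell_b[i]) <= shell_tolerance] <- i
  }
  out <- tibble(b = b, gx = directions[, 1], gy = directions[, 2],
                gz = directions[, 3], shell = shell)
  attr(out, "shell_tolerance") <- shell_tolerance
  class(out) <- c("gradient_scheme", class(out))
  out
}

#' Near-uniform unit directions by the spherical Fibonacci lattice
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(gx = r * cos(phi), gy = r * sin(phi), gz = z)
}

#' Default acquisition scheme: 3 shells x 60 directions + 5 b = 0
#'
#' Emulates a three-shell protocol at b = 1000, 2000 and 3000 s/mm^2 with 180
#' diffusion-encoding directions split evenly across shells (60 each, placed
#' on a spherical Fibonacci lattice rotated per shell) plus 5 unweighted
#' images.
#'
#' @param b_shells Non-zero shell b-values (s/mm^2).
#' @param n_per_shell Directions per shell.
#' @param n_b0 Number of b = 0 measurements.
#' @return A [gradient_scheme()] tibble with a `direction_scheme` attribute
#'   naming the point set used.
#' @export
default_scheme <- function(b_shells = c(1000, 2000, 3000), n_per_shell = 60,
                           n_b0 = 5) {
  dirs <- fibonacci_directions(n_per_shell)
  blocks <- lapply(seq_along(b_shells), function(i) {
    # rotate each shell's lattice about z to decorrelate shells
    th <- (i - 1) * pi / 7
    rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    list(b = rep(b_shells[i], n_per_shell), g = dirs %*% t(rot))
  })
  b <- c(rep(0, n_b0), unlist(lapply(blocks, `[[`, "b")))
  g <- rbind(matrix(0, n_b0, 3), do.call(rbind, lapply(blocks, `[[`, "g")))
  out <- gradient_scheme(b, g)
  attr(out, "direction_scheme") <- "spherical_fibonacci"
  out
}

#' Read / write FSL-dialect bval and bvec files
#'
#' `read_gradients()` builds a [gradient_scheme()] from a whitespace-separated
#' one-row `bval` file and three-row `bvec` file; `write_gradients()` is its
#' inverse.
#'
#' @param bval_file,bvec_file Paths to the text files.
#' @param scheme A `gradient_scheme`.
#' @param ... Passed to [gradient_scheme()].
#' @return `read_gradients()` a `gradient_scheme`; `write_gradients()` the
#'   file paths, invisibly.
#' @export
read_gradients <- function(bval_file, bvec_file, ...) {
  b <- scan(bval_file, quiet = TRUE)
  v <- matrix(scan(bvec_file, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(v) != length(b)) abort("bval and bvec lengths disagree.")
  gradient_scheme(b, t(v), ...)
}

#' @rdname read_gradients
#' @export
write_gradients <- function(scheme, bval_file, bvec_file) {
  writeLines(paste(format(scheme$b, trim = TRUE), collapse = " "), bval_file)
  g <- rbind(scheme$gx, scheme$gy, scheme$gz)
  writeLines(apply(g, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
             bvec_file)
  invisible(c(bval_file, bvec_file))
}

# b-values of the non-zero shells, in ascending order
shell_bvalues <- function(scheme) {
  sort(unique(scheme$b[scheme$shell > 0]))
}
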