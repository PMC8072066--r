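#' @keywords internal
new_trajectory <- function(times, n, l = NULL, f = NULL, topology) {
  colnames(n) <- topology$compartments
  if (!is.null(l)) colnames(l) <- topology$compartments
  if (!is.null(f)) colnames(f) <- topology$compartments
  structure(list(times = times, n = n, l = l, f = f, topology = topology),
            class = "hsc_trajectory")
}

#' @export
print.hsc_trajectory <- function(x, ...) {
  cat("hsc_trajectory:", length(x$times), "time points,",
      x$topology$K, "compartments (",
      paste(x$topology$compartments, collapse = ", "), ")\n")
  cat("components:", paste(c("n", "l", "f")[!vapply(x[c("n", "l", "f")],
                                                    is.null, logical(1))],
                           collapse = ", "), "\n")
  invisible(x)
}

#' Tidy trajectory export
#'
#' Long-format view of a model trajectory: one row per time point and
#' compartment, with expected counts `n`, labeled counts `l`, and labeled
#' frequency `f` (where available).
#'
#' @param x An `hsc_trajectory`.
#' @param ... Unused.
#' @return A `data.frame` with columns `time`, `compartment`, `n`, `l`, `f`.
#' @export
as.data.frame.hsc_trajectory <- function(x, ...) {
  K <- x$topology$K
  out <- data.frame(
    time = rep(x$times, times = K),
    compartment = rep(x$topology$compartments, each = length(x$times)),
    n = as.vector(x$n))
  out$l <- if (is.null(x$l)) NA_real_ else as.vector(x$l)
  out$f <- if (is.null(x$f)) NA_real_ else as.vector(x$f)
  out
}

#' Write a trajectory as delimited text
#'
#' @param traj An `hsc_trajectory`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_times <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)))
    stop("`times` must be finite")
  if (times[1] != 0)
    stop("`times` must start at 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  times
}
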